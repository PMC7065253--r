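# Independent oracles: deliberately naive loop/enumeration implementations
# of the published formulas, kept separate from the package's code paths.

# Weir & Cockerham (1984) variance components, scalar arithmetic, looping
# over loci, alleles and populations exactly as printed.
oracle_wc <- function(gt) {
  loci <- unique(gt$locus)
  pops <- unique(gt$pop)
  A_sum <- B_sum <- C_sum <- 0
  for (l in loci) {
    d <- gt[gt$locus == l & !is.na(gt$a1), ]
    n_all <- sapply(pops, function(p) sum(d$pop == p))
    pops_l <- pops[n_all > 0]
    n_i <- n_all[n_all > 0]
    r <- length(pops_l)
    if (r < 2) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in sort(unique(c(d$a1, d$a2)))) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        dd <- d[d$pop == pops_l[k], ]
        p_i[k] <- (sum(dd$a1 == al) + sum(dd$a2 == al)) / (2 * nrow(dd))
        h_i[k] <- mean(dd$a1 != dd$a2 & (dd$a1 == al | dd$a2 == al))
      }
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      aa <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      bb <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      A_sum <- A_sum + aa
      B_sum <- B_sum + bb
      C_sum <- C_sum + cc
    }
  }
  list(fst = A_sum / (A_sum + B_sum + C_sum),
       fis = 1 - C_sum / (B_sum + C_sum))
}

# Unbiased gene diversity from first principles (table() counting).
oracle_he <- function(gt, pop, locus) {
  d <- gt[gt$pop == pop & gt$locus == locus & !is.na(gt$a1), ]
  alleles <- c(d$a1, d$a2)
  n <- length(alleles)
  p <- as.vector(table(alleles)) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

# Brute-force likelihood grid search for a two-population mixture:
# maximises sum_i log(th * P_i1 + (1 - th) * P_i2) over th in {0, step, .., 1}.
oracle_grid_theta <- function(M, step = 0.001) {
  stopifnot(ncol(M) == 2)
  P <- exp(M - apply(M, 1, max))
  ths <- seq(0, 1, by = step)
  ll <- vapply(ths, function(th) sum(log(th * P[, 1] + (1 - th) * P[, 2])),
               numeric(1))
  ths[which.max(ll)]
}

# Kruskal-Wallis H from hand-computed ranks (no tie correction needed when
# values are distinct).
oracle_kw_h <- function(values, groups) {
  rk <- rank(values)
  N <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- rk[groups == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  12 / (N * (N + 1)) * h - 3 * (N + 1)
}
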