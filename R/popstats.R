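# Per-population, per-locus allele counts from the wide representation.
# Returns list(X = per-locus A x K count matrix, n = L x K gene-copy matrix,
# pops, loci, n_alleles).
counts_arrays <- function(w, pops = NULL) {
  pops <- pops %||% unique(w$pop)
  K <- length(pops)
  popidx <- match(w$pop, pops)
  L <- length(w$loci)
  nmat <- matrix(0L, L, K, dimnames = list(w$loci, pops))
  X <- vector("list", L)
  names(X) <- w$loci
  for (j in seq_len(L)) {
    A <- w$n_alleles[[j]]
    v <- which(!is.na(w$A1[, j]) & !is.na(popidx))
    idx <- (popidx[v] - 1L) * A
    cnt <- tabulate(c(idx + w$A1[v, j], idx + w$A2[v, j]), nbins = A * K)
    X[[j]] <- matrix(cnt, A, K, dimnames = list(NULL, pops))
    nmat[j, ] <- tabulate(popidx[v], nbins = K) * 2L
  }
  list(X = X, n = nmat, pops = pops, loci = w$loci, n_alleles = w$n_alleles)
}

#' Allele counts and frequencies per population and locus
#'
#' Missing genotypes at a locus reduce that locus's gene-copy total `n` by
#' two; alleles in the locus inventory but absent from the sample appear
#' with count 0.
#'
#' @param gt A genotype table.
#' @return Tibble with columns `pop`, `locus`, `allele`, `count`, `n`
#'   (gene copies) and `freq` (`count/n`, `NA` when `n = 0`).
#' @export
allele_counts <- function(gt) {
  w <- gt_wide(gt)
  ca <- counts_arrays(w)
  purrr::map_dfr(seq_along(ca$loci), function(j) {
    A <- nrow(ca$X[[j]])
    purrr::map_dfr(seq_along(ca$pops), function(k) {
      ncop <- ca$n[j, k]
      tibble::tibble(pop = ca$pops[k], locus = ca$loci[j], allele = seq_len(A),
                     count = ca$X[[j]][, k], n = ncop,
                     freq = if (ncop > 0) ca$X[[j]][, k] / ncop else NA_real_)
    })
  }) |>
    dplyr::arrange(match(.data$pop, ca$pops), match(.data$locus, ca$loci),
                   .data$allele)
}

#' Unbiased gene diversity (expected heterozygosity)
#'
#' Per locus, `H_e = n/(n-1) * (1 - sum p_a^2)` with `n` the number of gene
#' copies. Loci with fewer than two gene copies in a population are skipped
#' with a warning.
#'
#' @param gt A genotype table.
#' @return Tibble with columns `pop`, `locus`, `n_copies`, `n_alleles_obs`
#'   (alleles observed) and `he`.
#' @export
gene_diversity <- function(gt) {
  ac <- allele_counts(gt)
  skipped <- ac |>
    dplyr::distinct(.data$pop, .data$locus, .data$n) |>
    dplyr::filter(.data$n < 2)
  if (nrow(skipped) > 0) {
    warn(paste0(nrow(skipped),
                " population x locus cell(s) with < 2 gene copies skipped"))
  }
  ac |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(
      n_copies = .data$n[1],
      n_alleles_obs = sum(.data$count > 0),
      he = (.data$n[1] / (.data$n[1] - 1)) * (1 - sum(.data$freq^2)),
      .groups = "drop"
    )
}

# Weir & Cockerham (1984) variance components for one locus.
# x: A x r allele counts over the r populations with data; het: A x r counts
# of heterozygous individuals carrying each allele; n_i: individuals per pop.
# Returns per-allele components a, b, c (a is NA when r < 2).
wc_locus_components <- function(x, het, n_i) {
  r <- length(n_i)
  p <- sweep(x, 2, 2 * n_i, "/")
  h <- sweep(het, 2, n_i, "/")
  nbar <- mean(n_i)
  N <- sum(n_i)
  pbar <- as.vector(p %*% n_i) / N
  hbar <- as.vector(h %*% n_i) / N
  if (r >= 2) {
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    s2 <- as.vector((p - pbar)^2 %*% n_i) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  } else {
    a <- rep(NA_real_, nrow(x))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
  }
  list(a = a, b = b, c = hbar / 2)
}

# Summed variance components per locus, tibble-free (hot path shared by
# the estimators and the permutation tests). Returns a 4 x L matrix with
# rows a, b, c, r (a is NA where fewer than 2 populations have data).
wc_abc_wide <- function(A1, A2, popidx, n_alleles) {
  L <- ncol(A1)
  out <- matrix(NA_real_, 4L, L)
  for (j in seq_len(L)) {
    A <- n_alleles[[j]]
    a1 <- A1[, j]
    v <- which(!is.na(a1) & !is.na(popidx))
    if (length(v) == 0) {
      out[4L, j] <- 0
      next
    }
    a1 <- a1[v]
    a2 <- A2[v, j]
    pv <- popidx[v]
    present <- sort(unique(pv))
    pi2 <- match(pv, present)
    idx <- (pi2 - 1L) * A
    x <- matrix(tabulate(c(idx + a1, idx + a2), nbins = A * length(present)), A)
    hetv <- a1 != a2
    het <- matrix(tabulate(c(idx[hetv] + a1[hetv], idx[hetv] + a2[hetv]),
                           nbins = A * length(present)), A)
    n_i <- tabulate(pi2, nbins = length(present))
    cmp <- wc_locus_components(x, het, n_i)
    out[, j] <- c(sum(cmp$a), sum(cmp$b), sum(cmp$c), length(present))
  }
  out
}

wc_components_wide <- function(w, pops) {
  popidx <- match(w$pop, pops)
  m <- wc_abc_wide(w$A1, w$A2, popidx, w$n_alleles)
  tibble::tibble(locus = w$loci, a = m[1, ], b = m[2, ], c = m[3, ],
                 r = as.integer(m[4, ]))
}

# Multi-locus F_ST over the loci with data in >= 2 populations; NA when
# there are none.
fst_from_abc <- function(m) {
  ok <- which(m[4, ] >= 2)
  if (length(ok) == 0) return(NA_real_)
  sum(m[1, ok]) / sum(m[1, ok] + m[2, ok] + m[3, ok])
}

fis_from_abc <- function(m) {
  ok <- which(m[4, ] >= 1)
  denom <- sum(m[2, ok] + m[3, ok])
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  1 - sum(m[3, ok]) / denom
}

#' Weir-Cockerham F-statistics
#'
#' Variance-components estimators of F_ST and F_IS (Weir & Cockerham 1984),
#' with components summed over alleles and loci before forming ratios.
#' Negative estimates are reported as computed, not truncated at zero. Loci
#' with data in fewer than two populations are excluded from F_ST (with a
#' warning) but still contribute to F_IS.
#'
#' @param gt A genotype table with one or more population samples.
#' @param pops Optional subset/order of populations to analyse.
#' @return Object of class `wc_fstat`; see [tidy.wc_fstat()] for per-locus
#'   components and [glance.wc_fstat()] for the overall estimates.
#' @export
weir_cockerham <- function(gt, pops = NULL) {
  w <- gt_wide(gt)
  pops <- pops %||% unique(w$pop)
  comp <- wc_components_wide(w, pops)
  if (length(pops) >= 2 && any(comp$r == 1)) {
    warn("locus with data in a single population excluded from F_ST")
  }
  fst_comp <- comp |> dplyr::filter(.data$r >= 2)
  fst <- if (nrow(fst_comp) > 0) {
    sum(fst_comp$a) / sum(fst_comp$a + fst_comp$b + fst_comp$c)
  } else NA_real_
  within <- comp |> dplyr::filter(.data$r >= 1)
  denom <- sum(within$b + within$c, na.rm = TRUE)
  fis <- if (denom > 0) 1 - sum(within$c, na.rm = TRUE) / denom else NA_real_
  structure(list(fst = fst, fis = fis, components = comp, pops = pops),
            class = "wc_fstat")
}

#' @export
print.wc_fstat <- function(x, ...) {
  cat("Weir-Cockerham F-statistics (", length(x$pops), " samples)\n",
      "  F_ST = ", format(x$fst, digits = 4),
      "   F_IS = ", format(x$fis, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy per-locus Weir-Cockerham variance components
#'
#' @param x A `wc_fstat` object.
#' @param ... Unused.
#' @return Tibble with per-locus summed components `a`, `b`, `c`.
#' @method tidy wc_fstat
#' @export
tidy.wc_fstat <- function(x, ...) x$components

#' One-row summary of a Weir-Cockerham fit
#'
#' @param x A `wc_fstat` object.
#' @param ... Unused.
#' @return Tibble with `fst`, `fis`, `n_pops`, `n_loci`.
#' @method glance wc_fstat
#' @export
glance.wc_fstat <- function(x, ...) {
  tibble::tibble(fst = x$fst, fis = x$fis, n_pops = length(x$pops),
                 n_loci = nrow(x$components))
}

#' Pairwise F_ST between all population samples
#'
#' @param gt A genotype table with at least two populations.
#' @return Tibble with columns `pop_a`, `pop_b`, `fst`.
#' @export
pairwise_fst <- function(gt) {
  w <- gt_wide(gt)
  pops <- unique(w$pop)
  if (length(pops) < 2) abort("pairwise F_ST needs at least two populations")
  pairs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    comp <- wc_components_wide(w, pairs[, i]) |> dplyr::filter(.data$r >= 2)
    tibble::tibble(pop_a = pairs[1, i], pop_b = pairs[2, i],
                   fst = sum(comp$a) / sum(comp$a + comp$b + comp$c))
  })
}

# Multi-locus |F_IS| for one population from wide matrices; returns NA for
# monomorphic data (zero within-individual variance denominator).
fis_single_wide <- function(w, pop) {
  popidx <- match(w$pop, pop)
  fis_from_abc(wc_abc_wide(w$A1, w$A2, popidx, w$n_alleles))
}

#' Permutation test for Hardy-Weinberg equilibrium
#'
#' Within each population sample, alleles are permuted among individuals
#' within each locus, and the multi-locus `|F_IS|` is compared with the
#' observed value (two-sided; both heterozygote excess and deficit count).
#' P-values use the add-one correction `(k + 1) / (n_perm + 1)`.
#' Monomorphic samples return `p = 1`.
#'
#' @param gt A genotype table.
#' @param n_perm Number of randomisations (default 2380).
#' @param seed Optional seed.
#' @return Tibble with columns `pop`, `fis`, `p_value`, `n_perm`.
#' @export
hwe_test <- function(gt, n_perm = 2380, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  w <- gt_wide(gt)
  pops <- unique(w$pop)
  purrr::map_dfr(pops, function(p) {
    rows <- which(w$pop == p)
    A1 <- w$A1[rows, , drop = FALSE]
    A2 <- w$A2[rows, , drop = FALSE]
    ones <- rep(1L, length(rows))
    obs <- fis_from_abc(wc_abc_wide(A1, A2, ones, w$n_alleles))
    if (is.na(obs)) {
      return(tibble::tibble(pop = p, fis = NA_real_, p_value = 1,
                            n_perm = as.integer(n_perm)))
    }
    valid <- lapply(seq_along(w$loci), function(j) which(!is.na(A1[, j])))
    k <- 0L
    P1 <- A1
    P2 <- A2
    for (b in seq_len(n_perm)) {
      for (j in seq_along(w$loci)) {
        v <- valid[[j]]
        pool <- sample(c(A1[v, j], A2[v, j]))
        P1[v, j] <- pool[seq_along(v)]
        P2[v, j] <- pool[length(v) + seq_along(v)]
      }
      fb <- fis_from_abc(wc_abc_wide(P1, P2, ones, w$n_alleles))
      if (!is.na(fb) && abs(fb) >= abs(obs)) k <- k + 1L
    }
    tibble::tibble(pop = p, fis = obs, p_value = (k + 1) / (n_perm + 1),
                   n_perm = as.integer(n_perm))
  })
}

#' Permutation test of genetic differentiation between sample pairs
#'
#' For each pair of population samples, individuals are permuted between
#' the two samples (sample sizes kept) and the pairwise Weir-Cockerham
#' F_ST recomputed; the add-one-corrected p-value is the proportion of
#' permutations with F_ST at least the observed.
#'
#' @param gt A genotype table with at least two populations.
#' @param n_perm Number of randomisations (default 21000).
#' @param seed Optional seed.
#' @return Tibble with columns `pop_a`, `pop_b`, `fst`, `p_value`, `n_perm`.
#' @export
differentiation_test <- function(gt, n_perm = 21000, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  w <- gt_wide(gt)
  pops <- unique(w$pop)
  if (length(pops) < 2) abort("differentiation test needs two populations")
  sizes <- table(w$pop)
  if (any(sizes == 0)) abort("empty population sample")
  pairs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    pr <- pairs[, i]
    rows <- which(w$pop %in% pr)
    A1 <- w$A1[rows, , drop = FALSE]
    A2 <- w$A2[rows, , drop = FALSE]
    popidx <- match(w$pop[rows], pr)
    obs <- fst_from_abc(wc_abc_wide(A1, A2, popidx, w$n_alleles))
    k <- 0L
    for (b in seq_len(n_perm)) {
      fb <- fst_from_abc(wc_abc_wide(A1, A2, sample(popidx), w$n_alleles))
      if (!is.na(fb) && fb >= obs) k <- k + 1L
    }
    tibble::tibble(pop_a = pr[1], pop_b = pr[2], fst = obs,
                   p_value = (k + 1) / (n_perm + 1),
                   n_perm = as.integer(n_perm))
  })
}

#' Per-sample diversity summary table
#'
#' One row per population sample: size, number of families, mean unbiased
#' gene diversity, mean observed allele count across loci, multi-locus
#' F_IS and (optionally) its permutation p-value.
#'
#' @param gt A genotype table.
#' @param n_perm Randomisations for the HWE test; 0 skips the test.
#' @param seed Optional seed for the permutation test.
#' @return A tibble with columns `pop`, `n`, `n_families`, `mean_he`,
#'   `mean_alleles`, `fis`, `fis_p`.
#' @export
popstats_summary <- function(gt, n_perm = 0, seed = NULL) {
  div <- gene_diversity(gt) |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(mean_he = mean(.data$he),
                     mean_alleles = mean(.data$n_alleles_obs),
                     .groups = "drop")
  fam <- family_structure_index(gt) |>
    dplyr::select("pop", "n", "n_families")
  w <- gt_wide(gt)
  fis <- purrr::map_dfr(unique(w$pop), function(p) {
    rows <- which(w$pop == p)
    sub <- list(pop = w$pop[rows], loci = w$loci,
                A1 = w$A1[rows, , drop = FALSE],
                A2 = w$A2[rows, , drop = FALSE],
                n_alleles = w$n_alleles)
    tibble::tibble(pop = p, fis = fis_single_wide(sub, p))
  })
  out <- fam |>
    dplyr::left_join(div, by = "pop") |>
    dplyr::left_join(fis, by = "pop")
  if (n_perm > 0) {
    hw <- hwe_test(gt, n_perm = n_perm, seed = seed) |>
      dplyr::select("pop", fis_p = "p_value")
    out <- dplyr::left_join(out, hw, by = "pop")
  } else {
    out$fis_p <- NA_real_
  }
  out
}
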