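# Shared post-processing: argmax with deterministic first-in-baseline-order
# tie-break and softmax scores under a uniform prior.
assignments_from_loglik <- function(M, excluded) {
  K <- ncol(M)
  rmax <- apply(M, 1, max)
  S <- exp(M - rmax)
  S <- S / rowSums(S)
  best <- apply(M, 1, which.max)  # which.max takes the first maximum
  tie <- apply(M, 1, function(r) sum(r >= max(r) - 1e-12) > 1)
  tibble::tibble(
    individual = rownames(M),
    assigned = colnames(M)[best],
    score = S[cbind(seq_len(nrow(M)), best)],
    tie = tie,
    excluded = excluded
  ) |>
    dplyr::bind_cols(tibble::as_tibble(S, .name_repair = "minimal") |>
                       setNames(paste0("score_", colnames(M))))
}

#' Individual assignment against a baseline
#'
#' Assigns every individual to the baseline population with the highest
#' genotype log-likelihood. Ties are broken deterministically in favour of
#' the first population in baseline order and flagged. In strict mode
#' (the default), individuals missing one or more loci are flagged
#' `excluded` and ignored by accuracy summaries.
#'
#' @param mixture Genotype table of individuals to assign.
#' @param baseline Genotype table of reference samples.
#' @param strict Flag individuals with any missing locus as excluded
#'   (default TRUE).
#' @param prior_weight Prior weight for the genotype likelihood.
#' @return Tibble with one row per individual: `individual`, `origin`
#'   (true origin when known), `assigned`, `score` (softmax posterior of
#'   the winning population), `tie`, `excluded`, plus one `score_<pop>`
#'   column per baseline population.
#' @export
assign_individuals <- function(mixture, baseline, strict = TRUE,
                               prior_weight = 1) {
  M <- loglik_matrix(mixture, baseline, prior_weight = prior_weight)
  mw <- gt_wide(mixture)
  excl <- if (strict) rowSums(is.na(mw$A1)) > 0 else rep(FALSE, nrow(M))
  out <- assignments_from_loglik(M, unname(excl))
  out$origin <- mw$origin[match(out$individual, mw$ind)]
  dplyr::relocate(out, "origin", .after = "individual")
}

#' Leave-one-out self-assignment test
#'
#' Each baseline individual is assigned back to the most likely population
#' after its own two alleles per locus are removed from its source
#' population's allele counts (leave-one-out), so an individual never
#' informs its own likelihood. Estimated accuracy per population is the
#' fraction of its non-excluded individuals assigned back to it. Strict
#' missing-data exclusion is on by default.
#'
#' @param baseline Genotype table of reference samples.
#' @param strict Exclude individuals with missing loci (default TRUE).
#' @param prior_weight Prior weight for the genotype likelihood.
#' @return Object of class `self_assign` with elements `assignments`
#'   (per-individual tibble as in [assign_individuals()]), `accuracy`
#'   (per-population tibble) and `confusion` (source x assigned count
#'   matrix). `tidy()` returns the accuracy table.
#' @export
self_assignment <- function(baseline, strict = TRUE, prior_weight = 1) {
  w <- gt_wide(baseline)
  if (any(table(w$pop) == 0)) abort("empty population sample")
  ca <- counts_arrays(w)
  M <- loglik_matrix_wide(w, ca, prior_weight = prior_weight)
  # leave-one-out correction of each individual's own-population column
  popidx <- match(w$pop, ca$pops)
  for (j in seq_along(ca$loci)) {
    a1 <- w$A1[, j]
    a2 <- w$A2[, j]
    v <- which(!is.na(a1))
    if (length(v) == 0) next
    A <- nrow(ca$X[[j]])
    wgt <- prior_weight / A
    k <- popidx[v]
    d <- as.numeric(a1[v] == a2[v])
    X <- ca$X[[j]]
    nl <- ca$n[j, k]
    x1 <- X[cbind(a1[v], k)]
    x2 <- X[cbind(a2[v], k)]
    old <- log(x1 + wgt) + log(x2 + d + wgt) -
      log(nl + prior_weight) - log(nl + prior_weight + 1)
    new <- log(x1 - 1 - d + wgt) + log(x2 - 1 + wgt) -
      log(nl - 2 + prior_weight) - log(nl - 1 + prior_weight)
    M[cbind(v, k)] <- M[cbind(v, k)] + (new - old)
  }
  excl <- if (strict) rowSums(is.na(w$A1)) > 0 else rep(FALSE, nrow(M))
  asg <- assignments_from_loglik(M, unname(excl))
  asg$origin <- w$pop
  asg <- dplyr::relocate(asg, "origin", .after = "individual")
  acc <- asg |>
    dplyr::group_by(pop = .data$origin) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_excluded = sum(.data$excluded),
      accuracy = mean((.data$assigned == .data$origin)[!.data$excluded]),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$pop, ca$pops))
  kept <- asg[!asg$excluded, ]
  confusion <- table(factor(kept$origin, levels = ca$pops),
                     factor(kept$assigned, levels = ca$pops))
  structure(list(assignments = asg, accuracy = acc, confusion = confusion),
            class = "self_assign")
}

#' @export
print.self_assign <- function(x, ...) {
  cat("Leave-one-out self-assignment\n")
  print(x$accuracy, ...)
  invisible(x)
}

#' Tidy self-assignment accuracies
#'
#' @param x A `self_assign` object.
#' @param ... Unused.
#' @return The per-population accuracy tibble.
#' @method tidy self_assign
#' @export
tidy.self_assign <- function(x, ...) x$accuracy

#' 100% simulation baseline power test
#'
#' The classic single-population power test: for each baseline population
#' in turn, each replicate (i) resamples a parametric baseline — for every
#' population, Hardy-Weinberg draws at the original per-locus gene-copy
#' totals from that sample's estimated allele frequencies — and (ii)
#' simulates a pure mixture of `mix_size` unrelated genotypes from the
#' focal population's estimated frequencies, then runs the EM mixture
#' estimator and records the proportion credited back to the focal
#' population. Because the simulating frequencies are estimated from the
#' (possibly sibling-laden) baseline sample, any family-induced frequency
#' bias propagates into the test, which is precisely why the test can
#' overstate real-world accuracy.
#'
#' @param baseline Genotype table of reference samples.
#' @param mix_size Simulated mixture size per replicate (default 200).
#' @param n_sim Replicates per population (default 100).
#' @param seed Optional seed.
#' @param prior_weight Prior weight for the genotype likelihood.
#' @param level Confidence level for the percentile interval over
#'   replicates (default 0.95).
#' @return Tibble with one row per population: `pop`, `accuracy` (mean
#'   estimated proportion of the true population), `ci_low`, `ci_high`,
#'   `n_sim`, `mix_size`.
#' @export
sim100 <- function(baseline, mix_size = 200, n_sim = 100, seed = NULL,
                   prior_weight = 1, level = 0.95) {
  stopifnot(mix_size >= 1, n_sim >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  w <- gt_wide(baseline)
  ca <- counts_arrays(w)
  K <- length(ca$pops)
  L <- length(ca$loci)
  phat <- lapply(seq_len(L), function(j) {
    P <- sweep(ca$X[[j]], 2, pmax(ca$n[j, ], 1), "/")
    # empty sample at a locus: fall back to uniform
    zero <- ca$n[j, ] == 0
    if (any(zero)) P[, zero] <- 1 / nrow(P)
    P
  })
  alpha <- (1 - level) / 2
  purrr::map_dfr(seq_len(K), function(k) {
    est <- vapply(seq_len(n_sim), function(s) {
      Xb <- lapply(seq_len(L), function(j) {
        m <- vapply(seq_len(K), function(kk) {
          rmultinom(1, ca$n[j, kk], phat[[j]][, kk])[, 1]
        }, numeric(nrow(phat[[j]])))
        m <- matrix(m, nrow = nrow(phat[[j]]))
        colnames(m) <- ca$pops
        m
      })
      names(Xb) <- ca$loci
      cab <- list(X = Xb, n = ca$n, pops = ca$pops, loci = ca$loci,
                  n_alleles = ca$n_alleles)
      A1 <- matrix(NA_integer_, mix_size, L)
      A2 <- matrix(NA_integer_, mix_size, L)
      for (j in seq_len(L)) {
        g <- hwe_draw(phat[[j]][, k], mix_size)
        A1[, j] <- g[, 1L]
        A2[, j] <- g[, 2L]
      }
      mwb <- list(ind = sprintf("s%04d", seq_len(mix_size)), loci = ca$loci,
                  A1 = A1, A2 = A2)
      Mb <- loglik_matrix_wide(mwb, cab, prior_weight = prior_weight)
      em_theta(Mb)$theta[[k]]
    }, numeric(1))
    tibble::tibble(pop = ca$pops[k], accuracy = mean(est),
                   ci_low = quantile(est, alpha)[[1]],
                   ci_high = quantile(est, 1 - alpha)[[1]],
                   n_sim = as.integer(n_sim), mix_size = as.integer(mix_size))
  })
}
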