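# EM on a log-likelihood matrix. Rows are rescaled by their maximum before
# exponentiation; the mixture log-likelihood is recovered by adding the
# row maxima back.
em_theta <- function(M, tol = 1e-6, max_iter = 10000) {
  K <- ncol(M)
  rmax <- apply(M, 1, max)
  P <- exp(M - rmax)
  theta <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mix <- as.vector(P %*% theta)
    ll <- sum(log(mix) + rmax)
    if (ll < ll_old - 1e-8 * (1 + abs(ll_old))) {
      abort("EM log-likelihood decreased; this is a bug")
    }
    r <- P * rep(theta, each = nrow(P)) / mix
    theta_new <- colMeans(r)
    theta_new <- theta_new / sum(theta_new)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    ll_old <- ll
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  stopifnot(abs(sum(theta) - 1) < 1e-9)
  list(theta = setNames(theta, colnames(M)),
       loglik = sum(log(as.vector(P %*% theta)) + rmax),
       iterations = iter, converged = converged)
}

new_msa_fit <- function(em, pops, n_mixture, ci = NULL, n_boot = 0L) {
  structure(list(theta = em$theta, pops = pops, n_mixture = n_mixture,
                 loglik = em$loglik, iterations = em$iterations,
                 converged = em$converged, ci_low = ci$low, ci_high = ci$high,
                 n_boot = n_boot),
            class = "msa_fit")
}

#' Mixed stock analysis by EM maximum likelihood
#'
#' Estimates the proportion vector `theta` over baseline populations that
#' maximises the mixture log-likelihood
#' `sum_i log sum_k theta_k P(g_i | baseline k)` by
#' expectation-maximisation: responsibilities
#' `r_ik = theta_k P_ik / sum_j theta_j P_ij`, then
#' `theta_k <- mean_i r_ik`, starting from the uniform vector. The
#' log-likelihood is checked to be non-decreasing at every iteration.
#' Non-convergence within `max_iter` is flagged, not an error.
#'
#' @param mixture Genotype table of the mixed sample.
#' @param baseline Genotype table of reference population samples.
#' @param tol Convergence tolerance on `max |delta theta|` (default 1e-6).
#' @param max_iter Iteration cap (default 10000).
#' @param prior_weight Prior weight for the genotype likelihood.
#' @return An `msa_fit` object; see [tidy.msa_fit()] and
#'   [glance.msa_fit()].
#' @export
msa_em <- function(mixture, baseline, tol = 1e-6, max_iter = 10000,
                   prior_weight = 1) {
  if (nrow(mixture) == 0) abort("empty mixture sample")
  M <- loglik_matrix(mixture, baseline, prior_weight = prior_weight)
  em <- em_theta(M, tol = tol, max_iter = max_iter)
  new_msa_fit(em, colnames(M), nrow(M))
}

#' Mixed stock analysis with percentile bootstrap confidence intervals
#'
#' The point estimate comes from the unresampled data. Each of the `n_boot`
#' bootstrap replicates resamples mixture individuals with replacement and
#' (by default) baseline individuals with replacement within each
#' population, refits the EM, and the 2.5/97.5 percentiles of the
#' bootstrap distribution give elementwise 95% bounds.
#'
#' @inheritParams msa_em
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @param resample_baseline Also resample the baseline (default TRUE);
#'   FALSE resamples the mixture only.
#' @param level Confidence level (default 0.95).
#' @return An `msa_fit` object with `ci_low`/`ci_high`.
#' @export
msa_bootstrap <- function(mixture, baseline, n_boot = 1000, seed = NULL,
                          resample_baseline = TRUE, level = 0.95,
                          tol = 1e-6, max_iter = 10000, prior_weight = 1) {
  stopifnot(n_boot >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  bw <- gt_wide(baseline)
  mw <- gt_wide(mixture)
  common <- intersect(names(mw$n_alleles), names(bw$n_alleles))
  bw$n_alleles[common] <- pmax(bw$n_alleles[common], mw$n_alleles[common])
  ca <- counts_arrays(bw)
  M <- loglik_matrix_wide(mw, ca, prior_weight = prior_weight)
  em <- em_theta(M, tol = tol, max_iter = max_iter)
  by_pop <- split(seq_along(bw$pop), factor(bw$pop, levels = unique(bw$pop)))
  # precomputed combined (pop, allele) tabulation indices: recounting a
  # baseline resample is then a single tabulate() per locus
  K <- length(ca$pops)
  popidx <- match(bw$pop, ca$pops)
  L <- length(ca$loci)
  jj <- match(ca$loci, bw$loci)
  base1 <- lapply(seq_len(L), function(j) {
    (popidx - 1L) * ca$n_alleles[[j]] + bw$A1[, jj[j]]
  })
  base2 <- lapply(seq_len(L), function(j) {
    (popidx - 1L) * ca$n_alleles[[j]] + bw$A2[, jj[j]]
  })
  has_na <- vapply(base1, anyNA, logical(1))
  boot <- matrix(NA_real_, n_boot, ncol(M), dimnames = list(NULL, colnames(M)))
  for (b in seq_len(n_boot)) {
    if (resample_baseline) {
      rows <- unlist(lapply(by_pop, function(ix) {
        ix[sample.int(length(ix), replace = TRUE)]
      }), use.names = FALSE)
      pr <- popidx[rows]
      nmat <- ca$n
      Xb <- vector("list", L)
      for (j in seq_len(L)) {
        idx <- c(base1[[j]][rows], base2[[j]][rows])
        if (has_na[j]) {
          idx <- idx[!is.na(idx)]
          nmat[j, ] <- tabulate(pr[!is.na(base1[[j]][rows])], nbins = K) * 2L
        } else {
          nmat[j, ] <- tabulate(pr, nbins = K) * 2L
        }
        Xb[[j]] <- matrix(tabulate(idx, nbins = ca$n_alleles[[j]] * K),
                          ca$n_alleles[[j]], K, dimnames = list(NULL, ca$pops))
      }
      names(Xb) <- ca$loci
      cab <- list(X = Xb, n = nmat, pops = ca$pops, loci = ca$loci,
                  n_alleles = ca$n_alleles)
    } else {
      cab <- ca
    }
    mrows <- sample.int(length(mw$ind), replace = TRUE)
    mwb <- list(ind = mw$ind[mrows], loci = mw$loci,
                A1 = mw$A1[mrows, , drop = FALSE],
                A2 = mw$A2[mrows, , drop = FALSE])
    Mb <- loglik_matrix_wide(mwb, cab, prior_weight = prior_weight)
    boot[b, ] <- em_theta(Mb, tol = tol, max_iter = max_iter)$theta
  }
  alpha <- (1 - level) / 2
  ci <- list(low = apply(boot, 2, quantile, alpha),
             high = apply(boot, 2, quantile, 1 - alpha))
  new_msa_fit(em, colnames(M), nrow(M), ci = ci, n_boot = as.integer(n_boot))
}

#' @export
print.msa_fit <- function(x, ...) {
  cat("Mixed stock analysis:", x$n_mixture, "mixture individuals,",
      length(x$pops), "baseline populations\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy mixture proportion estimates
#'
#' @param x An `msa_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `pop`, `estimate` and, when bootstrapped,
#'   `conf.low`, `conf.high`.
#' @method tidy msa_fit
#' @export
tidy.msa_fit <- function(x, ...) {
  out <- tibble::tibble(pop = x$pops, estimate = unname(x$theta))
  if (!is.null(x$ci_low)) {
    out$conf.low <- unname(x$ci_low)
    out$conf.high <- unname(x$ci_high)
  }
  out
}

#' One-row summary of an MSA fit
#'
#' @param x An `msa_fit` object.
#' @param ... Unused.
#' @return Tibble with `logLik`, `iterations`, `converged`, `n_mixture`,
#'   `n_boot`.
#' @method glance msa_fit
#' @export
glance.msa_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged, n_mixture = x$n_mixture,
                 n_boot = x$n_boot %||% 0L)
}

#' Plot estimated mixture proportions
#'
#' Bars of estimated proportions per baseline population with bootstrap
#' 95% intervals when available; optional reference points for known true
#' proportions.
#'
#' @param object An `msa_fit` object.
#' @param true_props Optional named vector of true proportions to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msa_fit
#' @export
autoplot.msa_fit <- function(object, true_props = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pop, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "estimated proportion") +
    ggplot2::theme_minimal()
  if (!is.null(d$conf.low)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high), width = 0.2)
  }
  if (!is.null(true_props)) {
    td <- tibble::tibble(pop = names(true_props), true = unname(true_props))
    p <- p + ggplot2::geom_point(data = td,
                                 ggplot2::aes(x = .data$pop, y = .data$true),
                                 shape = 4, size = 3, colour = "black")
  }
  p
}
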