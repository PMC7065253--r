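# Genotype log-likelihood machinery.
#
# The genotype-probability model is a compound-Dirichlet (posterior
# predictive) draw from the baseline allele counts with total prior weight 1
# spread uniformly over the locus inventory (1/A per allele): the two
# alleles are drawn without replacement,
#   P(g = a,b | x, n) = m * (x_a + 1/A)/(n + 1) * (x_b + d_ab + 1/A)/(n + 2)
# with m = 2 for heterozygotes, 1 otherwise, and d_ab = 1 for homozygotes.
# The prior guarantees strictly positive likelihoods for alleles unseen in
# a baseline sample, so log-likelihoods are always finite. Loci with a
# missing genotype contribute nothing (empty product).

# Per-locus log-probability contributions for all individuals against all
# populations in a counts_arrays object. Optional per-individual count
# adjustment supports leave-one-out (see self_assignment).
loglik_matrix_wide <- function(mw, ca, prior_weight = 1) {
  n <- length(mw$ind)
  K <- length(ca$pops)
  M <- matrix(0, n, K, dimnames = list(mw$ind, ca$pops))
  loci <- ca$loci
  for (j in seq_along(loci)) {
    jj <- match(loci[j], mw$loci)
    if (is.na(jj)) next
    a1 <- mw$A1[, jj]
    a2 <- mw$A2[, jj]
    v <- which(!is.na(a1))
    if (length(v) == 0) next
    A <- nrow(ca$X[[j]])
    wgt <- prior_weight / A
    d <- as.numeric(a1[v] == a2[v])
    nl <- ca$n[j, ]
    X <- ca$X[[j]]
    # (2 - d) folds the heterozygote multiplicity into one log
    contrib <- log((X[a1[v], , drop = FALSE] + wgt) *
                     ((X[a2[v], , drop = FALSE] + wgt) + d) * (2 - d)) -
      rep(log((nl + prior_weight) * (nl + prior_weight + 1)),
          each = length(v))
    if (length(v) == n) {
      M <- M + contrib
    } else {
      M[v, ] <- M[v, ] + contrib
    }
  }
  M
}

#' Genotype log-likelihood matrix against a baseline
#'
#' Computes, for every individual in `mixture` and every population sample
#' in `baseline`, the log probability of the individual's multilocus
#' genotype under a compound-Dirichlet model: each locus's two alleles are
#' drawn without replacement from the baseline allele counts augmented by a
#' uniform prior of total weight `prior_weight` (default 1, i.e. `1/A` per
#' allele), which keeps likelihoods finite for alleles unseen in a baseline.
#' Missing loci contribute nothing; an all-missing individual has
#' log-likelihood 0 for every population.
#'
#' @param mixture Genotype table of individuals to score.
#' @param baseline Genotype table of reference population samples.
#' @param prior_weight Total prior weight added per locus (default 1).
#' @return Numeric matrix (individuals x baseline populations) of
#'   log-likelihoods.
#' @export
loglik_matrix <- function(mixture, baseline, prior_weight = 1) {
  bw <- gt_wide(baseline)
  mw <- gt_wide(mixture)
  # shared inventory: a mixture allele code beyond the baseline's inventory
  # enlarges it (zero counts, prior mass only)
  common <- intersect(names(mw$n_alleles), names(bw$n_alleles))
  bw$n_alleles[common] <- pmax(bw$n_alleles[common], mw$n_alleles[common])
  loglik_matrix_wide(mw, counts_arrays(bw), prior_weight = prior_weight)
}
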