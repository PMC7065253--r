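#' Simulate locus models (allele inventories and ancestral frequencies)
#'
#' Each locus gets `n_alleles` alleles whose ancestral frequencies are a
#' sorted flat Dirichlet draw (broken-stick), which for ~10 alleles yields
#' expected heterozygosity around 0.7, typical of multi-allelic
#' microsatellites.
#'
#' @param n_loci Number of loci.
#' @param n_alleles Alleles per locus; scalar or vector of length `n_loci`.
#' @param seed Optional integer seed; the result is a pure function of the
#'   arguments and the seed.
#' @return Tibble with columns `locus`, `allele`, `ancestral` (frequency).
#' @export
sim_loci <- function(n_loci = 17, n_alleles = 10, seed = NULL) {
  stopifnot(n_loci >= 1, all(n_alleles >= 2))
  if (!is.null(seed)) withr::local_seed(seed)
  A <- rep_len(as.integer(n_alleles), n_loci)
  loci <- sprintf("L%02d", seq_len(n_loci))
  purrr::map2_dfr(loci, A, function(l, a) {
    g <- rgamma(a, shape = 1)
    tibble::tibble(locus = l, allele = seq_len(a),
                   ancestral = sort(g / sum(g), decreasing = TRUE))
  })
}

#' Simulate diverged population allele frequencies
#'
#' Population frequencies are drawn per locus from a Dirichlet distribution
#' centred on the ancestral frequencies with concentration
#' `(1 - F) / F` (Balding-Nichols parameterisation), so that the expected
#' Weir-Cockerham F_ST among populations is approximately `F`.
#'
#' @param loci Tibble from [sim_loci()].
#' @param n_pops Number of populations.
#' @param fst Divergence parameter F, strictly inside (0, 1).
#' @param seed Optional integer seed.
#' @return Tibble with columns `pop`, `locus`, `allele`, `freq`.
#' @export
sim_pop_freqs <- function(loci, n_pops = 7, fst = 0.05, seed = NULL) {
  if (!(fst > 0 && fst < 1)) {
    abort("`fst` must lie strictly between 0 and 1")
  }
  stopifnot(n_pops >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  scale <- (1 - fst) / fst
  pops <- sprintf("pop_%d", seq_len(n_pops))
  by_locus <- split(loci, factor(loci$locus, levels = unique(loci$locus)))
  purrr::map_dfr(pops, function(p) {
    purrr::map_dfr(by_locus, function(lc) {
      g <- rgamma(nrow(lc), shape = lc$ancestral * scale)
      # guard against all-zero gamma draws at extreme concentrations
      if (sum(g) == 0) g[which.max(lc$ancestral)] <- 1
      tibble::tibble(pop = p, locus = lc$locus, allele = lc$allele,
                     freq = g / sum(g))
    })
  })
}

# list(mats = per-locus A x K frequency matrix, pops, loci, n_alleles)
freqs_arrays <- function(pop_freqs) {
  pops <- unique(pop_freqs$pop)
  loci <- unique(pop_freqs$locus)
  mats <- lapply(loci, function(l) {
    d <- pop_freqs[pop_freqs$locus == l, ]
    A <- max(d$allele)
    m <- matrix(0, A, length(pops), dimnames = list(NULL, pops))
    m[cbind(d$allele, match(d$pop, pops))] <- d$freq
    m
  })
  names(mats) <- loci
  list(mats = mats, pops = pops, loci = loci,
       n_alleles = vapply(mats, nrow, integer(1)))
}

#' Full-sib family size specifications
#'
#' Builds the list of family sizes defining a sample's family-structure
#' level:
#' * `weak` — all singletons (unrelated individuals);
#' * `medium` — sizes drawn i.i.d. from a shifted geometric distribution
#'   with mean `medium_mean` (default 2.5), the last family truncated so the
#'   sizes sum to `n`;
#' * `strong` — families of `strong_size` (default 15); when `n` is not a
#'   multiple, the final family holds the remainder.
#'
#' @param n Sample size (sum of family sizes).
#' @param level `"weak"`, `"medium"` or `"strong"`.
#' @param seed Optional seed (used by `medium` only).
#' @param medium_mean Mean family size for `medium`.
#' @param strong_size Family size for `strong`.
#' @return Integer vector of family sizes summing to `n`.
#' @export
family_sizes <- function(n, level = c("weak", "medium", "strong"),
                         seed = NULL, medium_mean = 2.5, strong_size = 15) {
  level <- match.arg(level)
  stopifnot(n >= 1)
  if (level == "weak") return(rep(1L, n))
  if (level == "strong") {
    k <- n %/% strong_size
    rem <- n %% strong_size
    return(as.integer(c(rep(strong_size, k), if (rem > 0) rem)))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(medium_mean > 1)
  p <- 1 / medium_mean
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, rgeom(max(16L, ceiling(n / medium_mean)), p) + 1L)
  }
  cut <- which(cumsum(sizes) >= n)[1]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (sum(sizes) - n)
  as.integer(sizes[sizes > 0])
}

#' Mendelian offspring of two diploid parents at one locus
#'
#' Each offspring receives one uniformly chosen allele from each parent.
#' Exposed as the primitive underlying the family simulator so Mendelian
#' segregation can be checked directly.
#'
#' @param parent1,parent2 Length-2 integer vectors of parental alleles.
#' @param n Number of offspring.
#' @param seed Optional seed.
#' @return `n x 2` integer matrix of offspring genotypes.
#' @export
mendelian_offspring <- function(parent1, parent2, n, seed = NULL) {
  stopifnot(length(parent1) == 2, length(parent2) == 2, n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  cbind(parent1[rbinom(n, 1, 0.5) + 1L], parent2[rbinom(n, 1, 0.5) + 1L])
}

# Draw n HWE genotypes (n x 2 allele codes) from frequency vector p.
hwe_draw <- function(p, n) {
  A <- length(p)
  matrix(sample.int(A, 2L * n, replace = TRUE, prob = p), n, 2L)
}

# Simulate one population sample with the given family sizes, as wide
# matrices. Parents are drawn from HWE at the population frequencies and
# never emitted.
sim_pop_sample_wide <- function(fa, pop, sizes, id_prefix = pop) {
  k <- match(pop, fa$pops)
  if (is.na(k)) abort(paste0("unknown population: ", pop))
  n <- sum(sizes)
  nf <- length(sizes)
  fam_of <- rep(seq_len(nf), sizes)
  L <- length(fa$loci)
  A1 <- matrix(NA_integer_, n, L)
  A2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    p <- fa$mats[[j]][, k]
    par <- matrix(sample.int(length(p), 4L * nf, replace = TRUE, prob = p),
                  nf, 4L)  # columns: p1a, p1b, p2a, p2b
    pick1 <- rbinom(n, 1, 0.5)
    pick2 <- rbinom(n, 1, 0.5)
    A1[, j] <- ifelse(pick1 == 1L, par[fam_of, 1L], par[fam_of, 2L])
    A2[, j] <- ifelse(pick2 == 1L, par[fam_of, 3L], par[fam_of, 4L])
  }
  list(
    ind = sprintf("%s_i%03d", id_prefix, seq_len(n)),
    pop = rep(pop, n),
    family = sprintf("%s_f%03d", id_prefix, fam_of),
    origin = rep(NA_character_, n),
    loci = fa$loci, A1 = A1, A2 = A2, n_alleles = fa$n_alleles
  )
}

bind_wides <- function(ws) {
  list(
    ind = unlist(lapply(ws, `[[`, "ind"), use.names = FALSE),
    pop = unlist(lapply(ws, `[[`, "pop"), use.names = FALSE),
    family = unlist(lapply(ws, `[[`, "family"), use.names = FALSE),
    origin = unlist(lapply(ws, `[[`, "origin"), use.names = FALSE),
    loci = ws[[1]]$loci,
    A1 = do.call(rbind, lapply(ws, `[[`, "A1")),
    A2 = do.call(rbind, lapply(ws, `[[`, "A2")),
    n_alleles = ws[[1]]$n_alleles
  )
}

#' Simulate a full-sib structured sample from one population
#'
#' Parents of each family are unrelated Hardy-Weinberg draws from the
#' population's allele frequencies (and are not included in the output);
#' each offspring receives one uniformly chosen allele per parent per locus,
#' loci independent.
#'
#' @param pop_freqs Tibble from [sim_pop_freqs()].
#' @param pop Population label to sample from.
#' @param sizes Integer vector of family sizes (see [family_sizes()]).
#' @param seed Optional seed.
#' @return A genotype table of `sum(sizes)` individuals with family labels.
#' @export
sim_family_sample <- function(pop_freqs, pop, sizes, seed = NULL) {
  if (length(sizes) == 0) abort("`sizes` must contain at least one family")
  stopifnot(all(sizes >= 1))
  if (!is.null(seed)) withr::local_seed(seed)
  fa <- freqs_arrays(pop_freqs)
  gt_from_wide(sim_pop_sample_wide(fa, pop, as.integer(sizes)))
}

#' Simulate a multi-population baseline on the size x structure grid
#'
#' Convenience wrapper drawing one family-structured sample of `n`
#' individuals per population.
#'
#' @param pop_freqs Tibble from [sim_pop_freqs()].
#' @param n Individuals per population sample.
#' @param level Family-structure level (see [family_sizes()]).
#' @param seed Optional seed.
#' @param ... Passed to [family_sizes()].
#' @return A genotype table covering all populations in `pop_freqs`.
#' @export
sim_baseline <- function(pop_freqs, n = 150,
                         level = c("weak", "medium", "strong"),
                         seed = NULL, ...) {
  level <- match.arg(level)
  if (!is.null(seed)) withr::local_seed(seed)
  fa <- freqs_arrays(pop_freqs)
  ws <- lapply(fa$pops, function(p) {
    sizes <- family_sizes(n, level, ...)
    sim_pop_sample_wide(fa, p, sizes)
  })
  gt_from_wide(bind_wides(ws))
}

#' Simulate a known-origin mixture sample
#'
#' Individuals are unrelated Hardy-Weinberg draws from each contributing
#' population, generated independently of any baseline sample. True origins
#' are recorded in the `origin` column; the `pop` label is `"mixture"`.
#'
#' @param pop_freqs Tibble from [sim_pop_freqs()].
#' @param composition Named integer vector or two-column data frame
#'   (`pop`, `n`) of per-population counts; zero counts are allowed.
#' @param seed Optional seed.
#' @return A genotype table of `sum(composition)` individuals ordered by
#'   population then index.
#' @export
sim_mixture <- function(pop_freqs, composition, seed = NULL) {
  if (is.data.frame(composition)) {
    composition <- setNames(composition$n, composition$pop)
  }
  if (any(composition < 0) || sum(composition) == 0) {
    abort("composition counts must be >= 0 with at least one positive")
  }
  fa <- freqs_arrays(pop_freqs)
  bad <- setdiff(names(composition), fa$pops)
  if (length(bad) > 0) {
    abort(paste0("composition names unknown population(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  composition <- composition[composition > 0]
  L <- length(fa$loci)
  ws <- lapply(names(composition), function(p) {
    n <- composition[[p]]
    k <- match(p, fa$pops)
    A1 <- matrix(NA_integer_, n, L)
    A2 <- matrix(NA_integer_, n, L)
    for (j in seq_len(L)) {
      g <- hwe_draw(fa$mats[[j]][, k], n)
      A1[, j] <- g[, 1L]
      A2[, j] <- g[, 2L]
    }
    list(ind = sprintf("mix_%s_%03d", p, seq_len(n)),
         pop = rep("mixture", n),
         family = sprintf("mix_%s_%03d", p, seq_len(n)),
         origin = rep(p, n),
         loci = fa$loci, A1 = A1, A2 = A2, n_alleles = fa$n_alleles)
  })
  gt_from_wide(bind_wides(ws))
}

#' Introduce missing genotypes at random (QC testing aid)
#'
#' @param gt A genotype table.
#' @param rate Per-genotype missingness probability.
#' @param seed Optional seed.
#' @return The table with approximately `rate` of genotypes set missing.
#' @export
add_missingness <- function(gt, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  drop <- runif(nrow(gt)) < rate
  gt$a1[drop] <- NA_integer_
  gt$a2[drop] <- NA_integer_
  gt
}
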