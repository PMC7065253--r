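#' Genotype tables
#'
#' A genotype table is the package's central data structure: a tidy tibble
#' with one row per individual x locus, holding a diploid genotype as an
#' unordered pair of integer allele codes (`a1`, `a2`; both `NA` when the
#' genotype is missing) together with per-individual metadata:
#'
#' * `individual` — unique identifier (character),
#' * `pop` — population sample label,
#' * `family` — full-sib family label (partitioning individuals within a
#'   population sample); singletons are their own family,
#' * `origin` — true population of origin for known-origin mixture
#'   individuals (`NA` for baseline samples).
#'
#' The table carries an optional `n_alleles` attribute (named integer vector,
#' one entry per locus) recording each locus's allele inventory size. When
#' absent, the inventory is taken to be `1:max(observed code)` per locus.
#'
#' @param x A data frame with columns `individual`, `pop`, `family`,
#'   `origin`, `locus`, `a1`, `a2`.
#' @param n_alleles Optional named integer vector of allele-inventory sizes
#'   per locus.
#' @return A validated genotype tibble.
#' @export
genotype_table <- function(x, n_alleles = NULL) {
  x <- tibble::as_tibble(x)
  needed <- c("individual", "pop", "family", "origin", "locus", "a1", "a2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$individual <- as.character(x$individual)
  x$pop <- as.character(x$pop)
  x$family <- as.character(x$family)
  x$origin <- as.character(x$origin)
  x$locus <- as.character(x$locus)
  x$a1 <- as.integer(x$a1)
  x$a2 <- as.integer(x$a2)
  if (any(xor(is.na(x$a1), is.na(x$a2)))) {
    abort("half-missing genotypes: a1 and a2 must be both present or both NA")
  }
  if (any(c(x$a1, x$a2) < 1L, na.rm = TRUE)) {
    abort("allele codes must be positive integers")
  }
  na <- n_alleles %||% attr(x, "n_alleles")
  if (!is.null(na)) {
    loci <- unique(x$locus)
    if (!all(loci %in% names(na))) {
      abort("n_alleles must name every locus in the table")
    }
    obs_max <- vapply(split(c(x$a1, x$a2), rep(x$locus, 2L)),
                      function(v) if (all(is.na(v))) 0L else max(v, na.rm = TRUE),
                      integer(1))
    if (any(obs_max[names(obs_max)] > na[names(obs_max)])) {
      abort("observed allele code exceeds the locus allele inventory")
    }
    na_int <- setNames(as.integer(na), names(na))
    attr(x, "n_alleles") <- na_int[loci]
  }
  x
}

#' Locus allele-inventory sizes of a genotype table
#'
#' @param gt A genotype table.
#' @return Named integer vector, one entry per locus (in order of first
#'   appearance). Falls back to the maximum observed code when the table
#'   carries no `n_alleles` attribute.
#' @export
loci_inventory <- function(gt) {
  loci <- unique(gt$locus)
  na <- attr(gt, "n_alleles")
  if (!is.null(na) && all(loci %in% names(na))) {
    return(as.integer(na[loci]) |> setNames(loci))
  }
  vapply(loci, function(l) {
    v <- c(gt$a1[gt$locus == l], gt$a2[gt$locus == l])
    if (all(is.na(v))) 1L else max(v, na.rm = TRUE)
  }, integer(1))
}

# Internal wide representation: metadata vectors plus n x L allele matrices.
# All engine-level computation (counts, likelihoods, F-statistics) runs on
# this; the tibble is the user-facing form.
gt_wide <- function(gt) {
  ids <- unique(gt$individual)
  loci <- unique(gt$locus)
  n <- length(ids)
  L <- length(loci)
  i <- match(gt$individual, ids)
  j <- match(gt$locus, loci)
  A1 <- matrix(NA_integer_, n, L, dimnames = list(ids, loci))
  A2 <- A1
  A1[cbind(i, j)] <- gt$a1
  A2[cbind(i, j)] <- gt$a2
  first <- !duplicated(gt$individual)
  list(
    ind = ids,
    pop = gt$pop[first][match(ids, gt$individual[first])],
    family = gt$family[first][match(ids, gt$individual[first])],
    origin = gt$origin[first][match(ids, gt$individual[first])],
    loci = loci,
    A1 = A1, A2 = A2,
    n_alleles = loci_inventory(gt)
  )
}

gt_from_wide <- function(w) {
  n <- length(w$ind)
  L <- length(w$loci)
  out <- tibble::tibble(
    individual = rep(w$ind, each = L),
    pop = rep(w$pop, each = L),
    family = rep(w$family, each = L),
    origin = rep(w$origin, each = L),
    locus = rep(w$loci, times = n),
    a1 = as.integer(t(w$A1)),
    a2 = as.integer(t(w$A2))
  )
  attr(out, "n_alleles") <- w$n_alleles
  out
}

# One-row-per-individual metadata.
gt_individuals <- function(gt) {
  gt |>
    dplyr::distinct(.data$individual, .data$pop, .data$family, .data$origin)
}

#' Family structure index (FSI)
#'
#' Quantifies full-sib family structure in a sample as `1 - n_eff / n`,
#' where `n_eff = (sum s_i)^2 / sum s_i^2` is the effective number of
#' families given family sizes `s_i`. FSI is 0 for a sample of unrelated
#' singletons and approaches 1 as the sample collapses into few large
#' families (five families of 15 give FSI = 1 - 5/75 = 0.933).
#'
#' @param gt A genotype table with family labels.
#' @return A tibble with one row per population: `pop`, `n` (individuals),
#'   `n_families`, `n_eff`, `fsi`.
#' @export
family_structure_index <- function(gt) {
  ind <- gt_individuals(gt)
  if (any(is.na(ind$family))) {
    abort("family labels are required to compute the family structure index")
  }
  ind |>
    dplyr::count(.data$pop, .data$family, name = "size") |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(
      n = sum(.data$size),
      n_families = dplyr::n(),
      n_eff = sum(.data$size)^2 / sum(.data$size^2),
      fsi = fsi_from_sizes(.data$size),
      .groups = "drop"
    )
}

#' FSI from a vector of family sizes
#'
#' @param sizes Positive integer family sizes.
#' @return `1 - n_eff/n` with `n_eff = (sum s)^2 / sum s^2`.
#' @export
fsi_from_sizes <- function(sizes) {
  if (length(sizes) == 0 || any(sizes <= 0)) {
    abort("family sizes must be positive")
  }
  n <- sum(sizes)
  1 - (n^2 / sum(sizes^2)) / n
}
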