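# Build a genotype table from allele matrices (individuals x loci).
make_gt <- function(a1, a2, pop, family = NULL, origin = NA_character_,
                    loci = NULL, n_alleles = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  n <- nrow(a1)
  L <- ncol(a1)
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  ids <- sprintf("i%03d", seq_len(n))
  pop <- rep_len(pop, n)
  if (is.null(family)) family <- ids
  origin <- rep_len(origin, n)
  gt <- tibble::tibble(
    individual = rep(ids, each = L),
    pop = rep(pop, each = L),
    family = rep(family, each = L),
    origin = rep(origin, each = L),
    locus = rep(loci, times = n),
    a1 = as.integer(t(a1)),
    a2 = as.integer(t(a2))
  )
  genotype_table(gt, n_alleles = n_alleles)
}

# Small standard population system shared across tests.
test_system <- function(n_loci = 8, n_alleles = 6, n_pops = 3, fst = 0.08,
                        seed = 101) {
  loci <- sim_loci(n_loci, n_alleles, seed = seed)
  sim_pop_freqs(loci, n_pops, fst, seed = seed + 1)
}
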