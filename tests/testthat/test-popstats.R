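test_that("allele counting handles zeros, missing data and round-trips", {
  gt <- make_gt(a1 = matrix(c(1L, 1L)), a2 = matrix(c(1L, 2L)), pop = "A",
                n_alleles = c(L01 = 3L))
  ac <- allele_counts(gt)
  expect_identical(ac$count, c(3L, 1L, 0L))
  expect_identical(ac$n, c(4L, 4L, 4L))
  expect_equal(ac$freq, c(0.75, 0.25, 0))

  gt2 <- make_gt(a1 = matrix(c(1L, NA), 2, 1), a2 = matrix(c(1L, NA), 2, 1),
                 pop = "A")
  expect_identical(allele_counts(gt2)$n, 2L)

  expect_error(make_gt(matrix(5L), matrix(5L), "A", n_alleles = c(L01 = 3L)),
               "inventory")
})

test_that("unbiased gene diversity matches closed forms and the oracle", {
  mono <- make_gt(matrix(1L, 4, 1), matrix(1L, 4, 1), pop = "A")
  expect_equal(gene_diversity(mono)$he, 0)
  het1 <- make_gt(matrix(1L), matrix(2L), pop = "A")
  expect_equal(gene_diversity(het1)$he, 1)

  fr <- test_system()
  bl <- sim_baseline(fr, n = 50, level = "weak", seed = 61)
  gd <- gene_diversity(bl)
  for (i in sample(nrow(gd), 10)) {
    expect_equal(gd$he[i], oracle_he(bl, gd$pop[i], gd$locus[i]),
                 tolerance = 1e-12)
  }
  # invariant under relabeling of alleles (swap codes 1 and 2)
  swap <- bl
  one <- swap$a1 == 1L
  two <- swap$a1 == 2L
  swap$a1[one] <- 2L
  swap$a1[two] <- 1L
  one <- swap$a2 == 1L
  two <- swap$a2 == 2L
  swap$a2[one] <- 2L
  swap$a2[two] <- 1L
  expect_equal(sort(gene_diversity(swap)$he), sort(gd$he), tolerance = 1e-12)
})

test_that("diversity is in the microsatellite-typical range at defaults", {
  loci <- sim_loci(17, 10, seed = 71)
  fr <- sim_pop_freqs(loci, 7, 0.05, seed = 72)
  bl <- sim_baseline(fr, n = 300, level = "weak", seed = 73)
  s <- popstats_summary(bl)
  expect_true(all(s$mean_he > 0.5 & s$mean_he < 0.9))
  expect_true(all(s$mean_alleles > 5))
})

test_that("Weir-Cockerham estimates match the naive-loop oracle", {
  # tiny hand-checkable instance: 3 individuals x 2 samples x 1 locus
  gt <- make_gt(a1 = matrix(c(1L, 1L, 2L, 1L, 2L, 2L)),
                a2 = matrix(c(1L, 2L, 2L, 1L, 2L, 2L)),
                pop = rep(c("A", "B"), each = 3))
  wc <- weir_cockerham(gt)
  orc <- oracle_wc(gt)
  expect_equal(wc$fst, orc$fst, tolerance = 1e-12)
  expect_equal(wc$fis, orc$fis, tolerance = 1e-12)

  fr <- test_system(n_pops = 3)
  bl <- sim_baseline(fr, n = 10, level = "weak", seed = 81)
  wc2 <- weir_cockerham(bl)
  orc2 <- oracle_wc(bl)
  expect_equal(wc2$fst, orc2$fst, tolerance = 1e-12)
  expect_equal(wc2$fis, orc2$fis, tolerance = 1e-12)
  expect_identical(nrow(tidy(wc2)), 8L)
  expect_identical(glance(wc2)$n_pops, 3L)
})

test_that("duplicated samples give non-positive F_ST", {
  fr <- test_system(n_pops = 1)
  bl <- sim_baseline(fr, n = 30, level = "weak", seed = 91)
  twin <- bl
  twin$pop <- "copy"
  twin$individual <- paste0("c_", twin$individual)
  both <- genotype_table(dplyr::bind_rows(bl, twin),
                         n_alleles = loci_inventory(bl))
  expect_lte(weir_cockerham(both)$fst, 1e-12)
})

test_that("F_IS is near zero under Hardy-Weinberg sampling", {
  fr <- test_system(n_pops = 1, n_loci = 10)
  fis <- vapply(1:20, function(r) {
    weir_cockerham(sim_baseline(fr, n = 300, level = "weak",
                                seed = 400 + r))$fis
  }, numeric(1))
  expect_lt(mean(abs(fis)), 0.05)
})

test_that("realized F_ST is monotone in the divergence parameter", {
  ordered <- vapply(1:10, function(r) {
    loci <- sim_loci(10, 8, seed = 3000 + r)
    ms <- vapply(c(0.01, 0.05, 0.10), function(f) {
      fr <- sim_pop_freqs(loci, 3, f, seed = 4000 + r)
      mean(pairwise_fst(sim_baseline(fr, n = 100, level = "weak",
                                     seed = 5000 + r))$fst)
    }, numeric(1))
    all(diff(ms) > 0)
  }, logical(1))
  expect_gte(mean(ordered), 0.9)
})

test_that("HWE randomisation test is calibrated and flags sib structure", {
  mono <- make_gt(matrix(1L, 5, 2), matrix(1L, 5, 2), pop = "A")
  expect_equal(hwe_test(mono, n_perm = 19, seed = 1)$p_value, 1)

  fr <- test_system(n_loci = 5, n_alleles = 5, n_pops = 1, seed = 111)
  # type-I error under the null within binomial bounds of 0.05
  rej <- vapply(1:200, function(r) {
    bl <- sim_baseline(fr, n = 40, level = "weak", seed = 6000 + r)
    hwe_test(bl, n_perm = 199, seed = 7000 + r)$p_value <= 0.05
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(sum(rej), bounds[1])
  expect_lte(sum(rej), bounds[2])

  # full-sib families distort genotype proportions: higher rejection rate
  rej2 <- vapply(1:60, function(r) {
    strong <- sim_baseline(fr, n = 60, level = "strong", seed = 8000 + r)
    weak <- sim_baseline(fr, n = 60, level = "weak", seed = 9000 + r)
    c(hwe_test(strong, n_perm = 99, seed = r)$p_value <= 0.05,
      hwe_test(weak, n_perm = 99, seed = r)$p_value <= 0.05)
  }, logical(2))
  expect_gt(mean(rej2[1, ]), mean(rej2[2, ]))
})

test_that("differentiation test is valid under the null and powerful at F=0.1", {
  fr0 <- test_system(n_loci = 5, n_alleles = 5, n_pops = 1, seed = 121)
  ps <- vapply(1:40, function(r) {
    bl <- sim_baseline(fr0, n = 40, level = "weak", seed = 10000 + r)
    half <- sample(unique(bl$individual), 20)
    bl$pop[bl$individual %in% half] <- "B"
    differentiation_test(bl, n_perm = 99, seed = r)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 40))

  hits <- vapply(1:20, function(r) {
    loci <- sim_loci(8, 6, seed = 11000 + r)
    fr <- sim_pop_freqs(loci, 2, 0.10, seed = 12000 + r)
    bl <- sim_baseline(fr, n = 75, level = "weak", seed = 13000 + r)
    differentiation_test(bl, n_perm = 99, seed = r)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("add-one correction bounds permutation p-values", {
  fr <- test_system(n_loci = 3, n_pops = 2, seed = 131)
  bl <- sim_baseline(fr, n = 10, level = "weak", seed = 132)
  p1 <- differentiation_test(bl, n_perm = 1, seed = 5)$p_value
  expect_true(p1 %in% c(0.5, 1))
  ph <- hwe_test(bl, n_perm = 1, seed = 5)$p_value
  expect_true(all(ph %in% c(0.5, 1)))
})

test_that("summary table carries the per-sample statistics", {
  fr <- test_system(n_pops = 2)
  bl <- sim_baseline(fr, n = 40, level = "strong", seed = 141)
  s <- popstats_summary(bl, n_perm = 49, seed = 142)
  expect_identical(names(s), c("pop", "n", "n_families", "mean_he",
                               "mean_alleles", "fis", "fis_p"))
  expect_identical(s$n, c(40L, 40L))
  expect_identical(s$n_families, c(3L, 3L))
  expect_true(all(s$fis_p > 0 & s$fis_p <= 1))
})
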