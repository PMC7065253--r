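test_that("genotype likelihood matches the compound-Dirichlet closed form", {
  # baseline: 5 individuals all homozygous 1/1 at one locus with A = 2
  base <- make_gt(matrix(1L, 5, 1), matrix(1L, 5, 1), pop = "A",
                  n_alleles = c(L01 = 2L))
  het <- make_gt(matrix(1L), matrix(2L), pop = "mix", n_alleles = c(L01 = 2L))
  M <- loglik_matrix(het, base)
  expect_equal(exp(M[1, 1]), 2 * (10.5 / 11) * (0.5 / 12), tolerance = 1e-12)

  hom <- make_gt(matrix(2L), matrix(2L), pop = "mix", n_alleles = c(L01 = 2L))
  expect_equal(exp(loglik_matrix(hom, base)[1, 1]),
               (0.5 / 11) * (1.5 / 12), tolerance = 1e-12)

  # all loci missing: empty product, log-likelihood exactly 0
  miss <- make_gt(matrix(NA_integer_), matrix(NA_integer_), pop = "mix")
  expect_identical(unname(loglik_matrix(miss, base)[1, ]), 0)

  # identical baseline samples give identical likelihoods
  twin <- base
  twin$pop <- "B"
  twin$individual <- paste0("b_", twin$individual)
  both <- genotype_table(dplyr::bind_rows(base, twin), c(L01 = 2L))
  M2 <- loglik_matrix(het, both)
  expect_equal(M2[, 1], M2[, 2])
})

test_that("EM mixture estimation has its fixed points and simplex invariants", {
  fr <- test_system(n_pops = 1)
  bl <- sim_baseline(fr, n = 30, level = "weak", seed = 201)
  mx <- sim_mixture(fr, c(pop_1 = 20), seed = 202)
  fit <- msa_em(mx, bl)
  expect_equal(unname(fit$theta), 1)

  # two identical baseline populations: uniform start is a fixed point
  twin <- bl
  twin$pop <- "pop_dup"
  twin$individual <- paste0("d_", twin$individual)
  both <- genotype_table(dplyr::bind_rows(bl, twin), loci_inventory(bl))
  fit2 <- msa_em(mx, both)
  expect_equal(unname(fit2$theta), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(fit2$theta), 1, tolerance = 1e-9)
  expect_true(fit2$converged)
  expect_true(glance(fit2)$iterations >= 1)
})

test_that("EM equals brute-force likelihood grid search on 2-population mixes", {
  for (r in 1:3) {
    loci <- sim_loci(10, 8, seed = 210 + r)
    fr <- sim_pop_freqs(loci, 2, 0.15, seed = 220 + r)
    bl <- sim_baseline(fr, n = 300, level = "weak", seed = 230 + r)
    mx <- sim_mixture(fr, c(pop_1 = 150, pop_2 = 50), seed = 240 + r)
    fit <- msa_em(mx, bl)
    M <- loglik_matrix(mx, bl)
    expect_equal(unname(fit$theta[1]), oracle_grid_theta(M), tolerance = 5e-3)
    expect_equal(unname(fit$theta[1]), 0.75, tolerance = 0.05)
  }
})

test_that("bootstrap CIs behave: degenerate at B=1, narrower with larger baselines", {
  fr <- test_system(n_pops = 2, fst = 0.1, seed = 251)
  bl <- sim_baseline(fr, n = 50, level = "weak", seed = 252)
  mx <- sim_mixture(fr, c(pop_1 = 20, pop_2 = 20), seed = 253)
  one <- msa_bootstrap(mx, bl, n_boot = 1, seed = 254)
  expect_equal(one$ci_low, one$ci_high)

  widths <- vapply(1:8, function(r) {
    vapply(c(75, 300), function(n) {
      b <- sim_baseline(fr, n = n, level = "weak", seed = 260 + r)
      m <- sim_mixture(fr, c(pop_1 = 30, pop_2 = 30), seed = 270 + r)
      f <- msa_bootstrap(m, b, n_boot = 80, seed = 280 + r)
      mean(f$ci_high - f$ci_low)
    }, numeric(1))
  }, numeric(2))
  expect_lt(median(widths[2, ]), median(widths[1, ]))
})

test_that("individual assignment resolves private alleles, ties and missing data", {
  # locus where allele 3 is private to pop A and common there
  base <- make_gt(a1 = matrix(c(3L, 3L, 3L, 1L, 1L, 1L)),
                  a2 = matrix(c(3L, 3L, 1L, 1L, 2L, 1L)),
                  pop = rep(c("A", "B"), each = 3), n_alleles = c(L01 = 3L))
  g <- make_gt(matrix(3L), matrix(3L), pop = "mix", n_alleles = c(L01 = 3L))
  asg <- assign_individuals(g, base)
  expect_identical(asg$assigned, "A")
  expect_false(asg$tie)
  expect_gt(asg$score, 0.5)

  # identical baselines: tie flagged, first population wins
  dup <- make_gt(a1 = matrix(rep(c(1L, 2L), 2)), a2 = matrix(rep(c(1L, 2L), 2)),
                 pop = rep(c("A", "B"), each = 2), n_alleles = c(L01 = 2L))
  asg2 <- assign_individuals(g <- make_gt(matrix(1L), matrix(2L), pop = "mix",
                                          n_alleles = c(L01 = 2L)), dup)
  expect_true(asg2$tie)
  expect_identical(asg2$assigned, "A")

  # strict mode excludes records with a missing locus
  base2 <- make_gt(matrix(c(1L, 2L), 2, 2), matrix(c(1L, 2L), 2, 2), pop = "A")
  g2 <- make_gt(matrix(c(1L, NA), 1, 2), matrix(c(1L, NA), 1, 2), pop = "mix")
  expect_true(assign_individuals(g2, base2, strict = TRUE)$excluded)
  expect_false(assign_individuals(g2, base2, strict = FALSE)$excluded)
})

test_that("leave-one-out self-assignment never uses an individual's own alleles", {
  fr <- test_system(n_loci = 4, n_alleles = 4, n_pops = 2, seed = 301)
  bl <- sim_baseline(fr, n = 8, level = "weak", seed = 302)
  sa <- self_assignment(bl)
  inv <- loci_inventory(bl)
  for (id in unique(bl$individual)) {
    rest <- genotype_table(bl[bl$individual != id, ], inv)
    me <- genotype_table(bl[bl$individual == id, ], inv)
    Mi <- loglik_matrix(me, rest)
    expected <- exp(Mi[1, ] - max(Mi[1, ]))
    expected <- expected / sum(expected)
    row <- sa$assignments[sa$assignments$individual == id, ]
    got <- unname(unlist(row[paste0("score_", colnames(Mi))]))
    expect_equal(got, unname(expected), tolerance = 1e-10)
  }
})

test_that("self-assignment is perfect for fixed disjoint alleles and symmetric for twins", {
  base <- make_gt(a1 = matrix(rep(c(1L, 2L), each = 10)),
                  a2 = matrix(rep(c(1L, 2L), each = 10)),
                  pop = rep(c("A", "B"), each = 10), n_alleles = c(L01 = 2L))
  sa <- self_assignment(base)
  expect_equal(tidy(sa)$accuracy, c(1, 1))

  # two independent samples from the same population model: accuracy ~ 0.5
  fr <- test_system(n_pops = 1, seed = 311)
  accs <- vapply(1:10, function(r) {
    s1 <- sim_baseline(fr, n = 40, level = "weak", seed = 320 + r)
    s2 <- sim_baseline(fr, n = 40, level = "weak", seed = 360 + r)
    s2$pop <- "pop_1b"
    s2$individual <- paste0("b_", s2$individual)
    both <- genotype_table(dplyr::bind_rows(s1, s2), loci_inventory(s1))
    mean(tidy(self_assignment(both))$accuracy)
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.1)
})

test_that("the 100% simulation test has its degenerate and symmetric limits", {
  fr <- test_system(n_pops = 1)
  bl <- sim_baseline(fr, n = 30, level = "weak", seed = 401)
  s <- sim100(bl, mix_size = 20, n_sim = 3, seed = 402)
  expect_equal(s$accuracy, 1)

  # statistically identical baseline populations (one sample duplicated
  # under two labels) split accuracy evenly by symmetry
  fr2 <- test_system(n_loci = 8, n_pops = 1, seed = 411)
  s1 <- sim_baseline(fr2, n = 50, level = "weak", seed = 412)
  s2 <- s1
  s2$pop <- "pop_1b"
  s2$individual <- paste0("b_", s2$individual)
  both <- genotype_table(dplyr::bind_rows(s1, s2), loci_inventory(s1))
  s100 <- sim100(both, mix_size = 50, n_sim = 40, seed = 414)
  expect_lt(max(abs(s100$accuracy - 0.5)), 0.1)
})

test_that("an all-missing locus changes no likelihood, assignment or theta", {
  fr <- test_system(n_pops = 2, seed = 421)
  bl <- sim_baseline(fr, n = 30, level = "weak", seed = 422)
  mx <- sim_mixture(fr, c(pop_1 = 10, pop_2 = 10), seed = 423)
  pad <- function(gt) {
    extra <- dplyr::distinct(gt, individual, pop, family, origin) |>
      dplyr::mutate(locus = "L_GHOST", a1 = NA_integer_, a2 = NA_integer_)
    genotype_table(dplyr::bind_rows(gt, extra),
                   c(loci_inventory(gt), L_GHOST = 2L))
  }
  expect_equal(unname(msa_em(mx, bl)$theta),
               unname(msa_em(pad(mx), pad(bl))$theta), tolerance = 1e-12)
  a0 <- assign_individuals(mx, bl, strict = FALSE)
  a1 <- assign_individuals(pad(mx), pad(bl), strict = FALSE)
  expect_identical(a0$assigned, a1$assigned)
  expect_equal(a0$score, a1$score, tolerance = 1e-12)
})

test_that("family structure inflates estimated accuracy and deflates true accuracy", {
  loci <- sim_loci(17, 10, seed = 431)
  fr <- sim_pop_freqs(loci, 7, 0.05, seed = 432)
  res <- vapply(1:6, function(r) {
    mx <- sim_mixture(fr, setNames(c(4, 8, 30, 20, 14, 0, 12),
                                   sprintf("pop_%d", 1:7)), seed = 440 + r)
    out <- vapply(c("weak", "strong"), function(lv) {
      bl <- sim_baseline(fr, n = 75, level = lv, seed = 450 + r)
      asg <- assign_individuals(mx, bl)
      c(est = mean(tidy(self_assignment(bl))$accuracy),
        true = mean(asg$assigned == asg$origin))
    }, numeric(2))
    c(est_up = out["est", "strong"] > out["est", "weak"],
      true_down = out["true", "strong"] < out["true", "weak"])
  }, logical(2))
  expect_gte(mean(res["est_up", ]), 5 / 6)
  expect_gte(mean(res["true_down", ]), 5 / 6)
})
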