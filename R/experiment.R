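#' Keep one individual per full-sib family
#'
#' Reduces each population sample to its first individual (by id order of
#' appearance) per family, producing a weak-structure sample (FSI = 0).
#'
#' @param gt A genotype table with family labels.
#' @return The pruned genotype table.
#' @export
prune_to_one_per_family <- function(gt) {
  ind <- gt_individuals(gt)
  if (any(is.na(ind$family))) abort("family labels are required")
  keep <- ind |>
    dplyr::group_by(.data$pop, .data$family) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::pull("individual")
  out <- gt[gt$individual %in% keep, ]
  attr(out, "n_alleles") <- attr(gt, "n_alleles")
  out
}

#' Keep the largest full-sib families up to a size cap
#'
#' Whole families are added in decreasing size order (ties broken by family
#' id) for each population until adding the next family would exceed
#' `n_max`; the result never exceeds `n_max` individuals per population.
#'
#' @param gt A genotype table with family labels.
#' @param n_max Maximum individuals retained per population.
#' @return The truncated genotype table with strong family structure.
#' @export
keep_largest_families <- function(gt, n_max) {
  stopifnot(n_max >= 1)
  ind <- gt_individuals(gt)
  if (any(is.na(ind$family))) abort("family labels are required")
  keep_fams <- ind |>
    dplyr::count(.data$pop, .data$family, name = "size") |>
    dplyr::arrange(.data$pop, dplyr::desc(.data$size), .data$family) |>
    dplyr::group_by(.data$pop) |>
    dplyr::mutate(running = cumsum_fit(.data$size, n_max)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$running)
  keep <- ind |>
    dplyr::semi_join(keep_fams, by = c("pop", "family")) |>
    dplyr::pull("individual")
  out <- gt[gt$individual %in% keep, ]
  attr(out, "n_alleles") <- attr(gt, "n_alleles")
  out
}

# Greedy knapsack indicator: TRUE for families kept under the cap, in the
# order given (sizes already sorted decreasing).
cumsum_fit <- function(sizes, n_max) {
  total <- 0
  keep <- logical(length(sizes))
  for (i in seq_along(sizes)) {
    if (total + sizes[i] <= n_max) {
      keep[i] <- TRUE
      total <- total + sizes[i]
    }
  }
  keep
}

#' Random one-per-family subsample
#'
#' Draws `n` families at random per population and keeps one random
#' individual from each, yielding a weak-structure sample. When a
#' population has fewer than `n` families, all of them are used (with a
#' warning) and the sample is smaller.
#'
#' @param gt A genotype table with family labels.
#' @param n Target number of individuals (= families) per population.
#' @param seed Optional seed.
#' @return The subsampled genotype table.
#' @export
random_unrelated_subset <- function(gt, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  ind <- gt_individuals(gt)
  if (any(is.na(ind$family))) abort("family labels are required")
  keep <- unlist(lapply(split(ind, ind$pop), function(d) {
    fams <- unique(d$family)
    if (length(fams) < n) {
      warn(paste0("population ", d$pop[1], ": only ", length(fams),
                  " families available (", n, " requested)"))
      chosen <- fams
    } else {
      chosen <- sample(fams, n)
    }
    vapply(chosen, function(f) {
      ids <- d$individual[d$family == f]
      if (length(ids) == 1) ids else sample(ids, 1)
    }, character(1))
  }), use.names = FALSE)
  out <- gt[gt$individual %in% keep, ]
  attr(out, "n_alleles") <- attr(gt, "n_alleles")
  out
}

#' Mixture composition table with rounded proportions
#'
#' @param counts Data frame with columns `pop` and `n`, or a named vector.
#' @return Tibble with `pop`, `n` and `prop` (proportion of the total,
#'   rounded to two decimals).
#' @export
mixture_composition <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(pop = names(counts), n = unname(counts))
  }
  counts <- tibble::as_tibble(counts)
  stopifnot(all(counts$n >= 0), sum(counts$n) > 0)
  counts |>
    dplyr::mutate(prop = round(.data$n / sum(.data$n), 2))
}

#' Standard test-mixture compositions
#'
#' The two mixture designs used throughout: an equal design (22 individuals
#' from each of four populations, three populations absent) and an unequal
#' design (4/8/30/20/14/0/12 across seven populations). Both sum to 88
#' individuals; populations with zero counts stay in the baseline.
#'
#' @param pops Character vector of the seven population labels.
#' @return Named list of two composition tibbles (`equal`, `unequal`) with
#'   columns `pop`, `n`, `prop`.
#' @export
ts_compositions <- function(pops = sprintf("pop_%d", 1:7)) {
  stopifnot(length(pops) == 7)
  list(
    equal = mixture_composition(
      tibble::tibble(pop = pops, n = c(0, 22, 22, 22, 22, 0, 0))),
    unequal = mixture_composition(
      tibble::tibble(pop = pops, n = c(4, 8, 30, 20, 14, 0, 12)))
  )
}

#' Experiment configuration
#'
#' Bundles every knob of the factorial evaluation: the synthetic population
#' system (populations, loci, alleles, divergence), the baseline grid
#' (sample sizes x family-structure levels), the test-mixture
#' compositions, replicate count and engine settings. Defaults follow the
#' study conditions: 7 populations x 17 loci x 10 alleles at divergence
#' F = 0.05, grid {75, 150, 300} x {weak, medium, strong}, the two
#' standard 88-individual mixtures, with desk-scale engine settings
#' (n_sim = 20, mix_size = 100, n_boot = 200).
#'
#' @param n_pops,n_loci,n_alleles,fst Population-system parameters.
#' @param sizes Baseline sample sizes per population.
#' @param levels Family-structure levels.
#' @param compositions Named list of composition tibbles (`pop`, `n`).
#' @param replicates Replicate grids.
#' @param n_sim,mix_size 100%-simulation settings.
#' @param n_boot Bootstrap replicates for MSA confidence intervals
#'   (0 skips bootstrapping).
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_pops = 7, n_loci = 17, n_alleles = 10,
                              fst = 0.05, sizes = c(75, 150, 300),
                              levels = c("weak", "medium", "strong"),
                              compositions = NULL, replicates = 5,
                              n_sim = 20, mix_size = 100, n_boot = 200,
                              seed = 1) {
  pops <- sprintf("pop_%d", seq_len(n_pops))
  if (is.null(compositions)) {
    compositions <- if (n_pops == 7) ts_compositions(pops) else
      list(equal = mixture_composition(
        tibble::tibble(pop = pops, n = rep(22L, n_pops))))
  }
  for (cmp in compositions) {
    if (!all(cmp$pop %in% pops)) {
      abort("composition references unknown populations")
    }
  }
  stopifnot(all(sizes > 0), replicates >= 1)
  structure(list(n_pops = n_pops, n_loci = n_loci, n_alleles = n_alleles,
                 fst = fst, sizes = sizes,
                 levels = match.arg(levels, c("weak", "medium", "strong"),
                                    several.ok = TRUE),
                 compositions = compositions, replicates = replicates,
                 n_sim = n_sim, mix_size = mix_size, n_boot = n_boot,
                 seed = seed),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()];
#' `compositions` is a mapping from mixture name to a mapping of population
#' label to count.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config` object.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$compositions)) {
    y$compositions <- lapply(y$compositions, function(m) {
      mixture_composition(tibble::tibble(pop = names(m),
                                         n = as.numeric(unlist(m))))
    })
  }
  do.call(experiment_config, y)
}

#' Evaluate one baseline against the full GSI battery
#'
#' Runs the 100% simulation test, leave-one-out self-assignment, and — for
#' each supplied known-origin mixture — individual assignment (true
#' accuracy per population) and EM mixture estimation (bias against the
#' true proportions, with bootstrap confidence intervals and a coverage
#' indicator when `n_boot > 0`).
#'
#' @param baseline Genotype table of reference samples.
#' @param mixtures Named list of known-origin mixture genotype tables.
#' @param n_sim,mix_size 100%-simulation settings.
#' @param n_boot Bootstrap replicates for MSA (0 = point estimates only).
#' @param seed Optional seed.
#' @param strict Strict missing-data exclusion for IA/self-assignment.
#' @return Tidy tibble with columns `pop`, `metric`, `mixture` (`NA` for
#'   baseline-only metrics) and `value`. Metrics: `fsi`,
#'   `sim100_accuracy`, `self_assign_accuracy`, `ia_true_accuracy`,
#'   `msa_estimate`, `msa_true`, `msa_bias`, and with bootstrapping
#'   `msa_ci_low`, `msa_ci_high`, `msa_covered`.
#' @export
evaluate_baseline <- function(baseline, mixtures, n_sim = 20, mix_size = 100,
                              n_boot = 0, seed = NULL, strict = TRUE) {
  if (!is.null(seed)) withr::local_seed(seed)
  pops <- unique(baseline$pop)
  fsi <- family_structure_index(baseline) |>
    dplyr::transmute(pop = .data$pop, metric = "fsi", mixture = NA_character_,
                     value = .data$fsi)
  s100 <- sim100(baseline, mix_size = mix_size, n_sim = n_sim) |>
    dplyr::transmute(pop = .data$pop, metric = "sim100_accuracy",
                     mixture = NA_character_, value = .data$accuracy)
  sa <- tidy(self_assignment(baseline, strict = strict)) |>
    dplyr::transmute(pop = .data$pop, metric = "self_assign_accuracy",
                     mixture = NA_character_, value = .data$accuracy)
  mix_rows <- purrr::imap_dfr(mixtures, function(mx, nm) {
    asg <- assign_individuals(mx, baseline, strict = strict)
    ia <- asg |>
      dplyr::filter(!.data$excluded, !is.na(.data$origin)) |>
      dplyr::group_by(pop = .data$origin) |>
      dplyr::summarise(value = mean(.data$assigned == .data$origin),
                       .groups = "drop")
    ia <- tibble::tibble(pop = pops) |>
      dplyr::left_join(ia, by = "pop") |>
      dplyr::transmute(.data$pop, metric = "ia_true_accuracy", mixture = nm,
                       value = .data$value)
    truth <- prop.table(table(factor(mx$origin[!duplicated(mx$individual)],
                                     levels = pops)))
    fit <- if (n_boot > 0) {
      msa_bootstrap(mx, baseline, n_boot = n_boot)
    } else {
      msa_em(mx, baseline)
    }
    td <- tidy(fit) |>
      dplyr::mutate(true = as.numeric(truth[.data$pop]))
    est <- td |>
      dplyr::transmute(.data$pop, metric = "msa_estimate", mixture = nm,
                       value = .data$estimate)
    tru <- td |>
      dplyr::transmute(.data$pop, metric = "msa_true", mixture = nm,
                       value = .data$true)
    bias <- td |>
      dplyr::transmute(.data$pop, metric = "msa_bias", mixture = nm,
                       value = .data$estimate - .data$true)
    out <- dplyr::bind_rows(ia, est, tru, bias)
    if (n_boot > 0) {
      out <- dplyr::bind_rows(
        out,
        td |> dplyr::transmute(.data$pop, metric = "msa_ci_low", mixture = nm,
                               value = .data$conf.low),
        td |> dplyr::transmute(.data$pop, metric = "msa_ci_high", mixture = nm,
                               value = .data$conf.high),
        # coverage within a 1e-6 tolerance: for a population absent from
        # the mixture (true proportion exactly 0) the percentile bounds are
        # strictly positive but infinitesimal, and count as covering 0
        td |> dplyr::transmute(.data$pop, metric = "msa_covered", mixture = nm,
                               value = as.numeric(
                                 .data$conf.low <= .data$true + 1e-6 &
                                   .data$true <= .data$conf.high + 1e-6)))
    }
    out
  })
  dplyr::bind_rows(fsi, s100, sa, mix_rows)
}

#' Run the full size x family-structure evaluation experiment
#'
#' For each replicate: draws a fresh population system (ancestral
#' frequencies and diverged population frequencies), simulates the
#' known-origin test mixtures, then for every grid cell (sample size x
#' structure level) simulates a baseline and evaluates it with
#' [evaluate_baseline()]. Fully seeded: the same configuration always
#' produces the same report. Failures in a cell are recorded and the run
#' continues.
#'
#' @param config An [experiment_config()] object.
#' @return A `gsi_report` tibble: one row per replicate x cell x
#'   population x metric, with columns `replicate`, `size`, `level`,
#'   `cell_fsi`, `mixture`, `pop`, `metric`, `value`, plus the config as
#'   attribute `config` and any per-cell failures as attribute `failures`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  n_seeds <- config$replicates * (2 + length(config$sizes) * length(config$levels))
  seeds <- withr::with_seed(config$seed,
                            sample.int(2^31 - 2, n_seeds))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  failures <- list()
  rows <- purrr::map_dfr(seq_len(config$replicates), function(rep_i) {
    loci <- sim_loci(config$n_loci, config$n_alleles, seed = next_seed())
    freqs <- sim_pop_freqs(loci, config$n_pops, config$fst, seed = next_seed())
    mix_seed <- seeds[si]  # mixtures derive from the freqs seed stream
    mixtures <- purrr::imap(config$compositions, function(cmp, nm) {
      sim_mixture(freqs, cmp, seed = (mix_seed + match(nm, names(config$compositions))) %% (2^31 - 2) + 1)
    })
    grid <- expand.grid(size = config$sizes, level = config$levels,
                        stringsAsFactors = FALSE)
    purrr::map_dfr(seq_len(nrow(grid)), function(g) {
      size <- grid$size[g]
      level <- grid$level[g]
      cell_seed <- next_seed()
      res <- tryCatch({
        baseline <- sim_baseline(freqs, n = size, level = level,
                                 seed = cell_seed)
        ev <- evaluate_baseline(baseline, mixtures, n_sim = config$n_sim,
                                mix_size = config$mix_size,
                                n_boot = config$n_boot,
                                seed = (cell_seed + 1) %% (2^31 - 2) + 1)
        cell_fsi <- mean(ev$value[ev$metric == "fsi"])
        dplyr::mutate(ev, replicate = rep_i, size = size, level = level,
                      cell_fsi = cell_fsi, .before = 1)
      }, error = function(e) {
        failures[[length(failures) + 1]] <<- list(
          replicate = rep_i, size = size, level = level,
          message = conditionMessage(e))
        NULL
      })
      res
    })
  })
  rows$level <- factor(rows$level, levels = c("weak", "medium", "strong"))
  structure(rows, config = config, failures = failures,
            class = c("gsi_report", class(rows)))
}

#' Summarise a report into per-cell mean accuracies
#'
#' Averages each metric across populations (and mixtures) within every
#' replicate x cell, the unit used by the rank tests and the accuracy
#' plane.
#'
#' @param report A `gsi_report` from [run_experiment()].
#' @return Tibble with `replicate`, `size`, `level`, `cell_fsi`, `metric`,
#'   `value`.
#' @export
summarise_report <- function(report) {
  report |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$replicate, .data$size, .data$level,
                    .data$cell_fsi, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' Least-squares plane of accuracy on family structure and sample size
#'
#' Fits `accuracy ~ FSI + n` by ordinary least squares over the
#' replicate x cell means of the chosen metric, summarising how family
#' structure degrades — and baseline sample size rescues — true accuracy.
#'
#' @param report A `gsi_report`.
#' @param metric Metric to model (default `"ia_true_accuracy"`).
#' @return An `lm` fit with coefficients `(Intercept)`, `cell_fsi`, `size`.
#' @export
fit_accuracy_plane <- function(report, metric = "ia_true_accuracy") {
  d <- summarise_report(report) |>
    dplyr::filter(.data$metric == !!metric)
  lm(value ~ cell_fsi + size, data = d)
}

#' Rank-based comparison of accuracy distributions
#'
#' Kruskal-Wallis rank-sum test across groups, a rank-based multiple
#' comparison (critical differences of mean ranks with a
#' Bonferroni-corrected normal quantile, Siegel-Castellan style), and
#' pairwise two-sided Wilcoxon rank-sum tests (exact when sample sizes
#' permit and no ties are present).
#'
#' @param data A data frame of accuracy values.
#' @param value Column name (string) holding the values.
#' @param group Column name (string) holding the group labels.
#' @param alpha Familywise significance level for the multiple comparison.
#' @return Object of class `accuracy_tests`: a list with `kruskal`
#'   (htest), `posthoc` (tibble of pairwise mean-rank differences,
#'   critical differences and significance) and `wilcoxon` (tibble of
#'   pairwise W and p-values). `tidy()` returns the post-hoc table.
#' @export
compare_accuracies <- function(data, value, group, alpha = 0.05) {
  x <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(x)
  x <- x[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2 || any(table(g) < 1)) {
    abort("need at least two non-empty groups")
  }
  kw <- kruskal.test(x, g)
  N <- length(x)
  rk <- rank(x)
  mean_ranks <- tapply(rk, g, mean)
  n_g <- table(g)
  k <- nlevels(g)
  pairs <- utils::combn(levels(g), 2)
  posthoc <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- abs(mean_ranks[[a]] - mean_ranks[[b]])
    crit <- qnorm(1 - alpha / (k * (k - 1))) *
      sqrt(N * (N + 1) / 12 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    tibble::tibble(group_a = a, group_b = b, mean_rank_diff = diff,
                   critical_diff = crit, significant = diff > crit)
  })
  wil <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    wt <- suppressWarnings(wilcox.test(x[g == a], x[g == b]))
    tibble::tibble(group_a = a, group_b = b,
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  structure(list(kruskal = kw, posthoc = posthoc, wilcoxon = wil),
            class = "accuracy_tests")
}

#' @export
print.accuracy_tests <- function(x, ...) {
  print(x$kruskal)
  cat("Multiple comparison after Kruskal-Wallis:\n")
  print(x$posthoc, ...)
  invisible(x)
}

#' Tidy the post-hoc comparison table
#'
#' @param x An `accuracy_tests` object.
#' @param ... Unused.
#' @return The pairwise critical-difference tibble.
#' @method tidy accuracy_tests
#' @export
tidy.accuracy_tests <- function(x, ...) x$posthoc

#' One-row Kruskal-Wallis summary
#'
#' @param x An `accuracy_tests` object.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @method glance accuracy_tests
#' @export
glance.accuracy_tests <- function(x, ...) {
  tibble::tibble(statistic = unname(x$kruskal$statistic),
                 df = unname(x$kruskal$parameter),
                 p_value = x$kruskal$p.value)
}

#' Plot accuracy against family structure by baseline size
#'
#' Estimated (self-assignment, 100% simulation) and true (individual
#' assignment) accuracy per cell against the family structure index,
#' faceted by baseline sample size — the package's view of the core
#' contrast between what accuracy tests promise and what independent
#' mixtures deliver.
#'
#' @param object A `gsi_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsi_report
#' @export
autoplot.gsi_report <- function(object, ...) {
  d <- summarise_report(object) |>
    dplyr::filter(.data$metric %in% c("self_assign_accuracy",
                                      "sim100_accuracy", "ia_true_accuracy"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_fsi, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~size, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "family structure index (FSI)", y = "accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
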