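---
title: "Family structure and the reliability of genetic stock identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family structure and the reliability of genetic stock identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gsifam` studies a specific failure mode of genetic stock identification
(GSI): reference baselines contaminated with full siblings. This vignette
is the package's methodological account — the models, the knobs, what the
simulator does and does not emulate, and the numerical decisions a
maintainer would want written down.

## 1. The estimation problem

A baseline is a set of population samples of diploid, codominant
multilocus genotypes (microsatellite-style). Two tasks share one
likelihood:

* **Individual assignment (IA)** — assign individual *i* to
  `argmax_k P(g_i | baseline k)`;
* **Mixed stock analysis (MSA)** — estimate proportions θ maximising the
  mixture likelihood `Σ_i log Σ_k θ_k P(g_i | baseline k)`.

### Genotype likelihood

`P(g | baseline k)` is a compound-Dirichlet posterior predictive: at a
locus with inventory size `A`, allele counts `x` and gene-copy total `n`,
the genotype's two alleles are drawn without replacement from the counts
augmented by a uniform prior of total weight 1 (`1/A` per allele):

    P(a,b | x, n) = m * (x_a + 1/A) / (n + 1) * (x_b + d_ab + 1/A) / (n + 2)

with `m = 2` for heterozygotes and `d_ab = 1` for homozygotes. Loci are
multiplied (no linkage), missing loci are skipped (empty product, so an
all-missing genotype has log-likelihood 0 against every population). The
prior serves one purpose: alleles absent from a baseline sample keep a
strictly positive probability, so log-likelihoods are always finite and an
individual carrying a locally unseen allele is penalised, not discarded.
The prior weight is configurable (`prior_weight`); 1 is the default
because it vanishes at rate 1/n and keeps the convenient "add one gene
copy" reading. Exact numerical parity with any particular GSI program is
not claimed; this is a documented model choice.

### EM and its guarantees

`msa_em()` starts from the uniform vector, iterates responsibilities
`r_ik = θ_k P_ik / Σ_j θ_j P_ij` and `θ_k ← mean_i r_ik`, and stops when
`max|Δθ| < tol` (default `1e-6`; iteration cap 10,000, non-convergence is
flagged, never thrown). Two invariants are asserted on every run: the
log-likelihood never decreases (with relative tolerance `1e-8` against
floating-point noise) and θ stays on the simplex to `1e-9`. Rows of the
log-likelihood matrix are rescaled by their maximum before
exponentiation. On two-population problems the EM optimum is checked in
the test suite against a brute-force grid search of the likelihood
(step 0.001, agreement within 5e-3).

### Uncertainty

`msa_bootstrap()` resamples **both** mixture individuals and baseline
individuals (with replacement, within population), refits the EM, and
reports percentile 2.5/97.5 bounds around the point estimate from the
unresampled data. Resampling the baseline matters here: baseline sampling
noise is precisely what family structure inflates. A mixture-only mode
(`resample_baseline = FALSE`) exists for comparison. Default 1,000
replicates; the factorial experiment uses 200 (see §5).

### Ties, missing data

IA breaks likelihood ties deterministically in favour of the first
population in baseline order and flags them (`tie`), so runs are
reproducible. In strict mode (default, matching common GSI-software
behaviour) individuals missing any locus are flagged `excluded` and
ignored by accuracy summaries; MSA always keeps them and skips the
missing loci.

## 2. The two standard accuracy tests, and why they can lie

* **LOO self-assignment** (`self_assignment()`): each individual's two
  alleles per locus are subtracted from its own population's counts
  before its likelihoods are computed — an audit in the test suite
  verifies the subtraction individual by individual. Accuracy is the
  fraction of (non-excluded) individuals assigned back to their sample.
* **100% simulation** (`sim100()`): per focal population, each replicate
  draws a parametric baseline (Hardy–Weinberg multinomial draws at the
  original per-locus gene-copy totals from each sample's *estimated*
  frequencies) plus a pure mixture from the focal sample's estimate, and
  records the proportion the EM credits back.

Both tests consult only the baseline. If siblings have dragged a sample's
frequency estimate away from its population's truth, the test mixture
inherits the same distortion — the baseline sample becomes *more*
distinguishable from its neighbours, and estimated accuracy rises exactly
when real accuracy falls. That contrast (estimated accuracy
non-decreasing, true accuracy non-increasing in family structure) is the
package's acceptance-level property, checked over 20 replicate grids.

## 3. The synthetic population system

* **Ancestral frequencies**: per locus, a sorted flat Dirichlet
  (broken-stick) over `A = 10` alleles (configurable per locus). This
  yields expected heterozygosity near 0.7 — typical of the multi-allelic
  microsatellite panels the method targets — without copying any
  empirical frequency table.
* **Divergence**: population frequencies are Dirichlet draws centred on
  the ancestral vector with concentration `(1 − F)/F` (Balding–Nichols),
  so expected Weir–Cockerham F_ST ≈ F. The default `F = 0.05` sits in the
  middle of the 0.02–0.10 pairwise range reported for the kind of
  hatchery-stock systems this models; the test suite checks realized
  pairwise F_ST of 7 × 17 × 10 systems lands inside that window, and that
  realized F_ST is monotone in F.
* **Families**: parents are Hardy–Weinberg draws from the population
  frequencies, never emitted; offspring get one uniformly chosen allele
  per parent per locus. Structure levels: *weak* = all singletons;
  *medium* = family sizes i.i.d. shifted-geometric with mean 2.5 (the
  ratio of individuals to inferred families seen in realistic hatchery
  samples), last family truncated to fit `n`; *strong* = families of 15,
  remainder family when `15 ∤ n`.
* **Mixtures**: unrelated Hardy–Weinberg draws per contributing
  population, generated independently of all baseline individuals, with
  true origins recorded. The two standard 88-individual designs are an
  equal mixture (22 × 4 populations, three absent) and an unequal one
  (4/8/30/20/14/0/12).

What the generator does **not** emulate: genotyping error (a missingness
injector exists for QC testing only), linked loci, mutation, half-sib or
multi-generation pedigrees, age structure, temporal frequency drift, and
unsampled ("ghost") populations. Passing tests therefore demonstrate the
family-structure mechanism under clean Mendelian sampling — they do not
certify performance on real baselines where those complications add
error of their own.

### Family structure index

No standard scalar summarises "how sib-contaminated is this sample", so
the package defines one: `FSI = 1 − n_eff/n`, `n_eff = (Σ s_i)²/Σ s_i²`
over family sizes. It is 0 iff all singletons, approaches 1 − 1/n for a
single family, is continuous in the sizes, and equals 0.933 for five
families of 15. It is this package's choice of x-axis for accuracy-vs-
structure summaries, not a field standard.

## 4. Population statistics

Weir–Cockerham (1984) variance components are summed over alleles and
loci before forming ratios; negative estimates are reported as computed
(not truncated), matching how F_IS deficits and excesses are read in
practice. Loci with data in fewer than two samples are excluded from F_ST
with a warning but still inform F_IS. Unbiased gene diversity is
`n/(n−1) (1 − Σ p²)` on gene copies; loci with fewer than two copies are
skipped with a warning; monomorphic loci legitimately give 0. Both
estimators are pinned to independent naive-loop recomputations at 1e-12
in the tests.

Permutation tests follow the classical randomisation schemes — alleles
among individuals within sample and locus for HWE (statistic `|F_IS|`,
two-sided, since both heterozygote excess and deficit occur under family
sampling), individuals between samples for differentiation (statistic
pairwise F_ST). Defaults are 2,380 and 21,000 randomisations
(configurable); p-values use the add-one correction `(k+1)/(n_perm+1)` so
p = 0 is impossible, and monomorphic samples return p = 1. Calibration
(type-I error within binomial bounds of 0.05) is verified by simulation.

## 5. The factorial experiment

`run_experiment()` sweeps sample sizes {75, 150, 300} × structure levels
{weak, medium, strong}, with fresh ancestral/population frequencies and
fresh test mixtures per replicate, and evaluates each cell with the full
battery. All randomness derives from one master seed via a pre-drawn seed
stream, so a configuration reproduces bit-identically; per-cell failures
are recorded and skipped, never fatal.

Desk-scale defaults — `replicates = 5` per config (the acceptance run
uses 20), `n_sim = 20`, `mix_size = 100`, `n_boot = 200` — were chosen as
the package's standard problem size: large enough that the monotone
structure effects and the size mitigation are stable across replicate
grids, small enough to sweep the grid routinely (one replicate grid is
roughly 20 s on one CPU; the 20-replicate acceptance run about 6 min).
Full-scale settings (100 simulations of 200, 1,000 bootstraps) remain
available through `experiment_config()`.

Comparisons across cells use `compare_accuracies()`: Kruskal–Wallis
(`stats::kruskal.test`), a rank-based multiple comparison implemented as
Siegel–Castellan-style critical differences of mean ranks with a
Bonferroni-corrected normal quantile (equivalent in spirit to the
familiar `kruskalmc` procedure, not bit-identical to any package), and
pairwise two-sided Wilcoxon tests (`stats::wilcox.test`, exact where
sample sizes permit). `fit_accuracy_plane()` fits
`accuracy ~ FSI + n` by OLS over replicate × cell means — the expected
signature is a negative FSI slope and positive n slope.

### Numerical decisions worth recording

* **CI coverage at the boundary.** Populations absent from a mixture have
  true proportion exactly 0; percentile bootstrap bounds for them are
  strictly positive but infinitesimal (e.g. 1e-68). The coverage
  indicator therefore uses a 1e-6 absolute tolerance — without it,
  structurally-zero populations would be scored as "missed" on numerical
  grounds alone.
* **Greedy family truncation.** `keep_largest_families()` adds whole
  families in decreasing size order (ties by family id), skipping any
  family that would push the sample past `n_max`, and continues down the
  list — so remaining capacity is filled by smaller families when they
  fit, and a cap larger than the sample is the identity.
* **Both CI readings.** Averages of accuracy can be summarised across
  populations within a cell or across replicates; the report keeps
  per-population rows so either aggregation can be formed downstream —
  `summarise_report()` implements the across-populations reading.
* **Medium structure.** The shifted geometric (success probability 0.4)
  was fixed once to give mean family size 2.5; nothing downstream is
  tuned to it.

## 6. Data interchange

GENEPOP is the interchange format (2- or 3-digit dialects read,
3-digit written; `000` missing; ids before the comma preserved verbatim;
parse errors cite line numbers). GENEPOP cannot carry family or
true-origin labels, so the writer emits a tab-separated sidecar
(`individual_id`, `population`, `family_id`, `true_origin`) that the
reader picks up automatically — keeping the `.gen` file strictly
standard. One consequence, deliberate: a written-then-reread table loses
inventory alleles never observed in the data; counts and frequencies are
unaffected.

## 7. Known limitations

* Sibship is known by construction in simulations; on real data the user
  must supply family labels from an external sibship-inference step —
  inferring them is out of scope.
* The genotype-likelihood prior and bootstrap scheme are reasonable,
  documented choices; other GSI programs make different undocumented
  ones, so cross-program numerical agreement should not be expected.
* Full Bayesian MSA (Dirichlet-process / MCMC mixing proportions),
  reporting-group aggregation and conditional-likelihood variants are not
  implemented.
* The medium-structure level is one plausible family-size law; real
  hatchery samples can have heavier-tailed family size distributions
  than a geometric.
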