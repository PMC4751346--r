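---
title: "Evaluating genomic selection in a polycross breeding program: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genomic selection in a polycross breeding program: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycrossGS)
```

# The problem

Perennial ryegrass varieties are bred by recurrent polycross selection:
several hundred plants from a handful of selected half-sib families are
open-intermated, roughly a hundred of the best mother-plants provide seed,
and the resulting half-sib families are evaluated over several seasons in
replicated sward plots.  One cycle takes years, and sward performance
correlates poorly with spaced-plant performance, so genomic selection —
predicting a genomically estimated breeding value (GEBV) for each candidate
mother-plant from genome-wide SNP markers — is attractive.  The awkward
feature of this material is that genotypes come from the mother-plants
while phenotypes come from swards of their open-pollinated half-sib
progeny, with unknown and ungenotyped pollen parents.

`polycrossGS` packages the full evaluation workflow for such a program:
genotype/map/phenotype handling, a breeding-program simulator that stands
in for confidential breeding data, heritability and linkage-disequilibrium
(LD) estimators, the training-population design formulas, four GEBV
prediction engines, and an evaluation pipeline scoring Spearman rank
accuracy across differently composed training populations.

# The prediction model

The core estimator is ridge-regression BLUP (`rrblup()`), the marker-effect
parameterization of GBLUP:

$$y = 1\mu + Zu + e, \qquad u \sim N(0, I\sigma_u^2), \quad
  e \sim N(0, I\sigma_e^2),$$

with $Z$ the $n \times M$ matrix of $-1/0/1$ additive codes.  The ridge
penalty is $\lambda = \sigma_e^2/\sigma_u^2$, and effects are obtained from
the dual form $\hat u = Z'(ZZ' + \lambda I)^{-1}(y - 1\hat\mu)$, with
$\hat\mu$ the generalized-least-squares intercept.  Variance components are
estimated by restricted maximum likelihood: after projecting the intercept
out of $ZZ'$ and decomposing it once, the restricted log-likelihood becomes
a cheap one-dimensional function of $\log\lambda$, maximized on
$\log\lambda \in [-10, 10]$ with tolerance $10^{-6}$.  That interval spans
penalties from $e^{-10}$ (essentially interpolation) to $e^{10}$
(essentially the training mean); a boundary solution means the data carry
no usable signal for that trait, which genuinely happens for near-zero
heritabilities.  The dual and primal ridge solutions are verified to agree
on random instances with $n < M$, $n = M$ and $n > M$, and the spectral
REML profile is checked against a direct determinant-based evaluation of
the restricted likelihood.

Three machine-learning comparators use the same training data: k-nearest
neighbours (mean trait value of the $k$ training individuals closest in
Euclidean distance on the marker codes, $k$ chosen by seeded 5-fold
cross-validation minimizing squared error, ties resolved toward smaller
$k$; distance ties at the k-th rank resolved by ascending training index),
a random forest (500 unpruned trees, $M/3$ candidate features per split,
terminal nodes of at least 5), and gradient-boosted trees (shrinkage 0.01,
subsample 0.5, depth 5, 1500 trees), the latter two as thin adapters over
`randomForest` and `xgboost`.  Genotypes enter all methods as raw
(mean-imputed) $-1/0/1$ codes; no per-marker standardization is applied,
since the codes already share a scale.

# Design formulas

Three classical results link the observable LD to training-population
design, exposed as vectorized functions:

* Sved's drift expectation $r^2 = 1/(4N_ec + 1)$, inverted by `sved_ne()`
  to estimate effective population size from mean adjacent-marker LD
  ($c$ in Morgans; all user-facing map distances are centimorgans and are
  divided by 100 at this interface only);
* the effective number of chromosome segments
  $M_e = 2N_eL/\ln(4N_eL)$ (`effective_segments()`), with $L = 8$ Morgans
  for perennial ryegrass;
* the expected accuracy $r = \sqrt{Nh^2/(Nh^2 + M_e)}$
  (`expected_accuracy()`) and its exact inverse `required_training_n()`.

Chaining them at $r^2 = 0.1$, $c = 0.003$ M, $L = 8$, $h^2 = 0.4$ and a
target squared accuracy of $0.5$ gives $N_e = 750$, $M_e \approx 1190$ and
$N \approx 2975$ — the scale of unrelated training population these
populations would need, and the number `scripts/acceptance.R` recomputes.
Note that the combination of published inputs is self-consistent only under
this reading: inverting Sved's relation at $r^2 = 0.1$, $c = 0.003$ cannot
yield an $N_e$ near 281, and a *squared* accuracy target of 0.5 (not an
accuracy of 0.5) is required to land near $N \approx 2980$.  The functions
implement the formulas; both readings can be evaluated with them.

# Heritability and LD estimators

Broad-sense heritability of half-sib family means uses a one-way ANOVA per
trait and generation: $\sigma_E^2$ is the within-family mean square over
replicate plots, $\sigma_G^2 = (MS_B - MS_W)/n_0$ with the unbalanced-design
coefficient $n_0 = (N - \sum n_i^2/N)/(k-1)$, and
$H^2 = \sigma_G^2/(\sigma_G^2 + \sigma_E^2)$.  Negative genetic-variance
estimates are clamped to zero, so $H^2 \in [0, 1]$; a zero within-family
mean square with distinct family means reports $H^2 = 1$.  Uncertainty is a
delete-one-observation jackknife SD.  LD is composite $r^2$: the squared
Pearson correlation of unphased code vectors, computed for all
within-chromosome marker pairs against a consensus genetic map; phase is
unavailable for mother-plant genotypes, so phase-aware estimators are out
of scope.  Monomorphic markers are excluded with a count.  The decay curve
is summarized by distance-binned means (empty bins are absent, never zero)
and a cubic smoothing spline whose penalty is chosen by generalized
cross-validation.

# What the simulator emulates

`simulate_program()` generates data with the statistical structure the
analysis assumes, because the real breeding data are not public:

* **Background LD** from drift: founder haplotypes drawn with per-locus
  allele frequencies uniform on $[0.1, 0.9]$, then random mating at
  `effective_size` for `burnin_generations`.  Mean $r^2$ at distance $c$
  approaches $1/(4N_ec+1)$ once the burn-in is long relative to
  $1/(2c + 1/2N_e)$; the defaults (Ne 200, 60 generations) are chosen so
  that, together with the founder bottleneck and the selection cycles, the
  emitted adjacent-marker $r^2$ lands in the observed 0.12–0.22 band.
* **Meiosis** with Poisson crossover counts per chromosome (mean = length
  in Morgans), uniform positions, no interference (Haldane) and
  independent assortment — the simplest standard model, sufficient for LD
  structure, implemented in compiled code.
* **The selection cycle**: a polycross of 500 plants from 5 families
  (the program uses 400–600 from 4–6; single values keep the default
  deterministic in shape), each offspring uniting a maternal gamete with a
  paternal gamete from a uniformly drawn other parent (no selfing);
  120 mother-plants drawn at random (seed yield, the real selection
  criterion at this step, is not modelled); half-sib families of 50
  progeny phenotyped in 4 replicate plots; the best 5 families by index
  trait parent the next cycle.
* **Two diverged lineages** (Intermediate, observed at F11–F14, and Late,
  at F5) from independent founder draws and independent drift, which is
  what makes PC1 separate them.  The default schedule genotypes
  119/86/54/100 mother-plants in F11–F14 and 105 in F5, so the composed
  F13/INT/ALL training sets have sizes 54/259/364.  Only one unlabelled
  cycle precedes F11: simulating all eleven historical cycles at the
  scheme's small per-cycle effective size would pile up far more LD than
  the genotyped generations actually show, and the observable generations
  are all the analysis consumes.
* **Phenotypes** are purely additive (many small QTL; dominance and
  epistasis out of scope).  A family's genetic value is the mean additive
  value of its simulated progeny; plot noise is solved analytically from
  the realized genetic variance of family means so that the plot-level
  ANOVA $H^2$ equals the trait's target in expectation — no iterative
  calibration.  A target of 0 produces pure noise.

Everything is driven by R's RNG, so a `(config, seed)` pair reproduces a
dataset bit-for-bit.

What the simulator does **not** emulate: genotyping error and missing-call
structure (missingness is handled by mean imputation, but not generated),
selection on seed yield and auxiliary traits, genotype-by-environment
interaction and year effects, NIRS measurement error, and any
non-additive genetic architecture.  Passing tests therefore show that the
estimators and pipeline behave correctly on data with the assumed
covariance structure — not that real sward trials satisfy those
assumptions.

# Numerical and design choices

* Missing genotype calls are mean-imputed per marker before PCA, LD and
  every prediction model; imputed values are continuous, observed calls
  are never altered, and the operation is idempotent.  The source material
  is silent on missing-data handling; marker-mean imputation is the common
  default in genomic-selection practice.
* PCA centres but does not scale marker columns; it is a structure
  diagnostic only.
* Phenotypes are standardized within each (generation, trait) cell (mean
  0, variance 1, denominator $n-1$); pooled training sets therefore have
  variance close to but not exactly 1, and the held-out generation's
  values never enter training-generation statistics.  The test
  generation's own standardization does not affect rank correlations.
* A failed (training set × trait × method) cell is reported as missing
  with its error message; it never aborts the grid and is never filled
  with a fabricated value.
* The ANOVA requires at least two families and at least one within-family
  degree of freedom; the jackknife errors out if any leave-one-out subset
  is degenerate.
* `n_mothers` defaults to 120 rather than the program's nominal ~100 so
  the largest genotyped cohort of the default schedule (F11, 119) can be
  drawn from a single generation's mothers.

## Problem sizes used in the tests

The replicated experiments in the test suite use deliberately compact
configurations — e.g. Ne recovery at $N_e = 100$ with 100 markers on two
1-Morgan chromosomes (50 replicates), heritability recovery with 100
families × 4 plots (200 replicates per target), the RRBLUP-versus-theory
comparison at $n = 230$ individuals and 600 markers (50 replicates), and
two-lineage programs with 250 markers and 30 mothers per generation
(20–30 replicates).  These sizes give the medians enough precision for the
stated tolerances while keeping each experiment in the tens of seconds;
the estimators themselves are size-agnostic, and the default full-size
configuration (1670 markers, 500-plant polycrosses) is exercised directly
by the LD-band check.

# Known limitations

* The expected-accuracy formula assumes unrelated training individuals and
  fully captured QTL; on related material it understates achievable
  accuracy, which is exactly the argument for within-program genomic
  selection.  The package checks agreement only on unstructured simulated
  populations.
* Composite $r^2$ on codes slightly underestimates haplotype $r^2$ when
  genotype frequencies deviate from Hardy–Weinberg proportions.
* REML uses a single variance component per trait; heterogeneous marker
  variances (BayesA/B-style) are out of scope.
* The normalization of field data against control varieties practised in
  the breeding program is not reproduced; per-subpopulation
  standardization is the implemented normalization.
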