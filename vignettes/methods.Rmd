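---
title: "Models and methods behind sterolflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sterolflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolflux)
```

`sterolflux` couples two statistical machines that are usually run
separately in brain cholesterol studies: transcriptome-constrained
prediction of metabolic reaction activity on a genome-scale model, and
repeated-measures association models for targeted sterol metabolomics
across two autopsy cohorts. This vignette documents the models, their
assumptions, the tunable parameters, the numerical choices, and what the
bundled simulations do and do not establish.

## The activity-prediction arm

### Discretization

Within one dataset, every gene × sample expression value is pooled and
the empirical 25th/75th percentiles are computed
(`pooled_thresholds()`). We use linear-interpolation sample quantiles
(`stats::quantile` type 7, the R default): the pooled values 1..8 give
q25 = 2.75 and q75 = 6.25. One consequence of interpolated quantiles is
that the fraction of values strictly above q75 can exceed 25% by up to
one observation's worth (e.g. 2 of 6 values); this discreteness is
irrelevant at transcriptome scale but surfaces in tiny examples, and the
tests assert the quantile property only up to 1/n.

Pooling globally across genes and samples mirrors the idea that
"high" and "low" are dataset-wide expression classes. Because a gene's
class then depends on its overall abundance, a per-gene mode
(`quantile_mode = "per_gene"` in `predict_activity()`) is provided: each
gene is classed against its own across-sample quartiles, and the
class (−1/0/+1) rather than the value is propagated through the GPR
rules. The global mode is the default.

Expression can be residualized on metadata covariates (sex, age) before
discretization (`residualize_expression()`; the gene-wise grand mean is
retained so thresholds stay on the original scale). Whether such
correction happens before or inside the mapping is a genuinely open
choice; both orders are supported, with correction-first as the default
when covariates are supplied.

### GPR mapping and reaction states

Gene values transfer to reactions through the boolean
gene–protein–reaction rules: `or` (isoenzymes — any gene suffices) takes
the maximum, `and` (enzyme complexes — all genes required) the minimum,
recursively (`reaction_expression()`). The rule grammar is infix
`and`/`or` with parentheses and `and` binding tighter — the dominant
community convention. Reactions whose mapped value exceeds q75 go to the
high set `R_H`, below q25 to the low set `R_L`; values equal to a
threshold, reactions without gene evidence, and reactions whose GPR
mentions a gene absent from the data stay moderate and impose no
constraint.

### The activity optimization

Per sample, with stoichiometric matrix `S` (boundary metabolites — pools
outside the mass-balanced system — excluded) and flux bounds
`lb ≤ v ≤ ub`, `solve_imat()` maximizes the number of satisfied
expression indicators: a high reaction is satisfied by `v_r ≥ ε` or
`v_r ≤ −ε`, a low reaction by `v_r = 0`, subject to `S v = 0` and the
bounds.

Every indicator is a pure interval tightening of one variable, so the
mixed-integer program is solved exactly by branch-and-bound over
indicator assignments: a node's feasibility is one LP feasibility check;
an infeasible partial assignment prunes its subtree (tightenings are
monotone); and a node that cannot beat the incumbent
(`satisfied + remaining ≤ best`) is discarded. LP feasibility is decided
by the package's own phase-one simplex in standard form (shifted
variables with upper-bound slacks and one artificial per equality row),
pivoting by Bland's smallest-index rule so termination is guaranteed
under the degeneracy these sparse systems routinely produce; variables
with zero-width bounds are fixed and eliminated first, as are equality
rows that become trivial. The search order — reactions sorted by id,
satisfy-forward before satisfy-backward before relax — is deterministic,
so the returned optimum is reproducible; alternate optimal *flux vectors*
for the same objective remain possible in principle across
implementations.

`enumerate_optimum()` is the package's own oracle: it enumerates every
indicator assignment (capped at 16 indicators) and returns the maximum
feasible count; tests hold the solver to exact agreement with it on
hundreds of random networks, and an independent ground-truth construction
(systems built around a known interior point) guards the shared LP
primitive.

Parameters:

* `epsilon` (default 1 flux unit, against default bounds of ±1000): the
  minimal flux magnitude counted as "carrying flux". The objective is
  invariant to rescaling all bounds and ε jointly, so only the ratio to
  the bounds matters.
* media constraints: lower bounds forcing glucose uptake, oxygen uptake
  and macromolecule synthesis to 0.01, 0.01 and 0.0001 flux units
  respectively (`default_media_constraints()`), so every personalized
  model is obliged to run a minimal metabolism; all other reactions stay
  unconstrained. The three reaction ids are configuration, not
  hard-coded.
* `tol` (default 1e-6): `call_activity()` calls a reaction active when
  the returned optimal flux exceeds `tol` in magnitude. Because
  borderline reactions can differ between alternate optima,
  `call_activity_robust()` instead asks whether the reaction *can* carry
  `|v| ≥ ε` under the optimal indicator assignment; the vertex call is
  the default for speed.

### Group comparison

Each reaction's binary activity is tabulated against the two groups
(`a` = group-1 active, `b` = group-1 inactive, `c`, `d` likewise for
group 2). `fisher_p()` computes the two-sided Fisher exact p by direct
hypergeometric enumeration under the probability-mass rule with the
customary `1 + 1e-7` tie tolerance (a doubling rule is available);
`stats::fisher.test` serves as an independent cross-check in the tests,
not as the implementation. The odds ratio is the sample cross-product
`(a·d)/(b·c)` — the only estimator consistent with rendering exact
zeros — with the zero-cell conventions: zero numerator → `0.000`, zero
denominator → `Inf`, both → `NA`. Network-level significance uses raw
p < 0.05 (each reaction in the restricted pathway set is an a priori
hypothesis); a BH-adjusted column is emitted alongside for transparency.

## The metabolomics arm

### Ingestion

Concentrations arrive in long format (subject × cohort × region ×
metabolite) with below-LOD flags and per-metabolite LOD thresholds.
Missingness — a record with no obtained value, dominated by left
censoring — is accounted per metabolite within each cohort × region
stratum; a metabolite exceeding 30% missing in any stratum is excluded
from all analyses (exactly 30% is retained), and remaining below-LOD
records are imputed at LOD/2 (`qc_filter()`, `impute_lod()`). Single-value
LOD/2 imputation is the field's standard pragmatic choice for
not-missing-at-random censoring; its known cost is that heavy censoring
concentrated in one group pulls slope estimates away from zero, which is
why the calibration simulations below separate estimator behaviour from
censoring behaviour.

### The association model

For each metabolite, log2 concentration over both regions is modeled
jointly with all terms interacted with region: region-specific
intercepts, disease/pathology slopes, and sex and age effects (plus a
cohort indicator in pooled fits). The fit is ordinary least squares with
Huber–White cluster-robust (sandwich, HC1) standard errors clustered on
subject. With identical regressor sets per region, generalized least
squares under an *unstructured* 2×2 within-subject covariance returns the
same point estimates as equation-by-equation OLS (the
seemingly-unrelated-regressions identity), and the clustered sandwich
imposes no structure on that covariance — so this is the
unstructured-covariance, robust-variance repeated-measures model, fit
without iterative covariance estimation. p-values use the t reference of
`lmtest::coeftest`.

Disease status enters as one ordered score per region (CN = 0, ASY = 1,
AD = 2): a single coefficient per region captures the monotone
CN → asymptomatic → AD gradient, and a negative sign means lower
concentration with increasing disease severity. Pathology models
substitute the continuous CERAD (0–3) or Braak (0–6) score for disease
status (disease group is then not in the model).

### Convergence pooling and cluster FDR

Associations estimated in both cohorts with the same slope sign are
*convergent*: they are refit on the combined cohorts with a cohort fixed
effect and reported as primary results at raw p < 0.05 — replication in
two independent cohorts is the multiplicity control. The pooling
mechanism (combined refit with cohort indicator rather than
inverse-variance meta-analysis) keeps the robust-variance machinery
intact; an exactly zero cohort slope is treated as concordant with
either sign, a measure-zero tie that only synthetic data can produce.
Divergent associations stay cohort-specific and are BH-adjusted within
each a priori pathway cluster (biosynthesis / enzymatic catabolism /
non-enzymatic catabolism), separately per region × predictor × cohort
family, at FDR < 0.05. Pooled fits therefore always use at least as many
subjects as either cohort-specific fit of the same contrast.

## What the simulations emulate — and what they do not

`make_toy_network()` builds small mass-balanced pathways (chain plus
branches, one oxygen-consuming step, glucose-like and oxygen-like
uptakes, a macromolecule sink) so the media constraints apply; zero flux
is always feasible before constraints. `mini_cholesterol_fixture()` is a
fixed 12-reaction, 11-metabolite pedagogical model of the pathway this
package is aimed at: acetyl-CoA → HMG-CoA → mevalonate → lanosterol,
the two parallel post-lanosterol routes to cholesterol (Bloch via
desmosterol, Kandutsch–Russell via 7-dehydrocholesterol), enzymatic
catabolism to 24S-hydroxycholesterol and bile acid, and esterification —
with unit stoichiometry and single-gene or two-gene GPRs (ACAT2,
HMGCS1, HMGCR, SQLE/LSS, SC5D, DHCR24, DHCR7, CYP46A1, HSD3B7, SOAT1).
The bile-acid and ester pools are boundary metabolites so both exits can
drain flux.

`simulate_expression()` draws gene baselines on the log2 scale
(mean 7, SD 1.5, noise SD 0.3 — typical normalized-microarray numbers),
places planted genes at an elevated baseline (default +2.5) and shifts
them by `delta` in the disease group; with the default `delta = −5`
planted genes sit above q75 in controls and below q25 in cases, the
designed differential-activity condition. `simulate_metabolomics()`
emulates the two-cohort, two-region autopsy design: group sizes default
to 15/6/8 (AD/ASY/CN) and 31/18/22, subject random effects shared across
regions (within-subject correlation ρ = 0.5, total residual SD 0.45 on
the log2 scale), planted region-specific slopes with magnitudes 0.1–0.3
(the lanosterol MFG slope −0.278 anchors the panel), ordinal CERAD/Braak
scores rising from CN through ASY to AD, left-censoring at the 5% LOD
quantile and 2% missing-at-random records.

These generators produce normal, homoscedastic, exactly-specified data.
Passing the bundled calibration therefore shows the estimators are
correct *under the model* — unbiased slopes, nominal CI coverage and
type-I error at n = 50 subjects/cohort, ≥ 80% power for the planted
activity shutdown at n = 20/20 — not that real brain tissue data meet
those assumptions. Real data add skewed concentration distributions,
batch structure, informative missingness beyond the LOD mechanism, and
expression–flux decoupling that no steady-state model captures. The
calibration simulations are run without censoring so that they measure
the estimator; the LOD machinery is verified separately on constructed
edge cases (31% missing → excluded, 30% → retained, LOD/2 arithmetic),
because with differential censoring the LOD/2 convention itself biases
slopes — a property of the convention, documented rather than hidden.

Problem sizes used by the test and acceptance suites — 200 random
networks for solver/oracle agreement, 50 simulation seeds per pipeline
calibration arm, 200/500 replicates for the metabolite recovery and
type-I checks, all 2×2 tables with total ≤ 40 for the Fisher
comparison — were chosen to keep Monte-Carlo error well inside the
asserted bands while remaining comfortable on a single CPU.

## Numerical choices and degenerate inputs

* Feasibility tolerance: mass balance is enforced by the simplex to
  ~1e-9; returned solutions are asserted to satisfy `|S v| ≤ 1e-6`.
* A constant gene (zero residual variance) gets p = 1 and a flag in
  `differential_expression()`; a collinear design is an error, and
  constant covariates are dropped with a message.
* A model infeasible after media constraints raises an error advising
  constraint review rather than returning a bogus optimum.
* Degenerate Fisher margins (an empty row or column) return p = 1.
* Below-LOD records without a positive LOD threshold are an error, as
  are non-positive concentrations reaching the log2 transform.
* All generators are deterministic under a fixed seed, and
  `run_pipeline()` writes a manifest (config + seeds + package version)
  sufficient to reproduce every number in its reports; identical
  configurations produce byte-identical report files.

## Known limitations

* The activity arm predicts *capability under an optimality hypothesis*,
  not measured flux; alternate optima are handled by determinism plus the
  robust calling mode, but cross-implementation flux vectors may differ
  while objectives agree.
* Branch-and-bound over indicators is exact but exponential in the worst
  case; it is intended for the restricted pathway models and toy networks
  used here, not for discretizing thousands of reactions at once on a
  full genome-scale model.
* The differential-expression stage is ordinary per-gene least squares;
  it deliberately omits empirical-Bayes variance moderation, which
  matters at very small sample sizes.
* LOD/2 imputation biases group contrasts under heavy differential
  censoring; censored-likelihood (e.g. Tobit) modeling is out of scope.
* The ordered disease coding (CN = 0, ASY = 1, AD = 2) assumes a
  monotone, equally spaced severity gradient; a factor coding would cost
  one degree of freedom and is not currently exposed.
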