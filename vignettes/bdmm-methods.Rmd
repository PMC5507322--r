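---
title: "Methods: Bayesian direct multimorbidity maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian direct multimorbidity maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Pairwise comorbidity statistics — the chi-squared test, odds and risk
ratios, the phi coefficient — count co-occurrence of two diseases while
ignoring every other disease.  In a diseasome-wide analysis most
significant pairs are *apparent* comorbidities: the association is mediated
by a third disease, or confounded by sex and age.  The package separates
direct from mediated relations by modelling all diseases jointly as a
Bayesian network (BN) and averaging structural features over the posterior
distribution of network structures.  Two features are averaged for every
disease pair:

* **edge feature** — an edge in any orientation joins the pair; its
  posterior is the probability of a *direct*, unmediated dependence
  ("co=morbidity");
* **structural association** — the pair is d-connected given the empty
  set, i.e. the two diseases share an ancestor (possibly one another);
  its posterior is high for mediated and confounded relations too.

An edge implies d-connection, so the association posterior dominates the
edge posterior pair by pair; the package enforces this per Monte-Carlo
sample, not just in expectation.  Sex and age enter the network as ordinary
nodes rather than being conditioned away, so confounding by either is
represented inside the model; a configurable conditioning set in
`association_feature()` supports sensitivity analysis.

## Scoring: BDeu marginal likelihood

Structures are scored by the decomposable BDeu marginal likelihood with
equivalent sample size `ess` (default 1) and a uniform structure prior
(optionally a per-edge log penalty `kappa`).  For one family with child
arity $r$ and $q$ joint parent configurations,

$$\log p(D_v \mid pa_v) = \sum_j \left[\log\Gamma(\alpha_j) -
\log\Gamma(\alpha_j + N_j)\right] + \sum_{jk}\left[\log\Gamma(\alpha_{jk}
+ N_{jk}) - \log\Gamma(\alpha_{jk})\right],$$

with $\alpha_{jk} = \mathrm{ess}/(rq)$, $\alpha_j = \mathrm{ess}/q$.  BDeu
is likelihood-equivalent: Markov-equivalent structures score identically,
which is exactly what makes the orientation-free edge feature stable.  The
`max_parents` cap (default 4) keeps scoring tractable at diseasome scale;
it must be at least the true maximum in-degree in benchmark worlds, or the
truth is unrepresentable and the sampler is forced into compensating
modes.  The study-side choices of `ess`, cap and prior are not public;
both are exposed as configuration and echoed into every output.

## Posterior computation

Two routes compute feature posteriors, and they are never collapsed:

* `exact_feature_posteriors()` enumerates **all** DAGs on at most five
  variables (29,281 at $n=5$) and sums indicator-weighted normalized
  scores with log-sum-exp stabilisation.  This is the oracle.
* `run_chains()` runs Metropolis–Hastings **structure MCMC**: uniform
  proposals over all valid single-edge additions, deletions and
  reversals, with the exact Hastings ratio $|N(x)|/|N(x')|$ from the
  neighborhood sizes.  Thinned post-burn-in samples contribute indicator
  values of both features; posteriors are means across independent
  chains, and the maximum cross-chain absolute difference per feature is
  reported as the convergence diagnostic.

Defaults (5×10^5 iterations, 10^5 burn-in, thinning 100, 2 chains) are
engineering choices sized for one CPU; the tests validate the sampler
against the enumeration oracle to 0.02 absolute on 4-variable cohorts.

**Initialization.**  With tens of thousands of subjects the structure
posterior is extremely peaked: single-edge random-walk burn-in starting
from the empty graph can be trapped in a local mode hundreds of
log-units below the dominant one, because any escape path passes
through states whose score deficit is never accepted.  Chains therefore
start from a greedy hill-climbed structure (`hill_climb_init = TRUE`).
Initialization does not change the stationary distribution; it removes
the burn-in trap.  The cross-chain diagnostic remains meaningful because
chains still explore orientation and weak-edge uncertainty
independently.

## Pairwise battery and score transformations

The package computes the standard battery per disease pair: Yates-corrected
chi-squared (degenerate margins give statistic 0, p 1, flagged), odds and
risk ratios with 95% log-scale confidence intervals (any zero cell triggers
the Haldane–Anscombe +0.5 correction of all four cells, flagged),
the phi coefficient (undefined on zero margins), Bonferroni flags with the
family size equal to the number of disease–disease pairs actually tested
(sex/age pairs excluded), a no-interaction logistic regression on a target
disease, and Ward clustering (`hclust`, method `ward.D`) of the p-value
matrix used directly as dissimilarities.

Three transformations map heterogeneous scores onto $[0,1]$ per batch:

* $T(p) = -\log_{10}(p) / (ld^* + 1)$ with $ld^*$ the maximum of
  $-\log_{10}(p)$ over strictly positive p-values, and $T(0) = 1$.  Note
  the ceiling 1 is attained only at $p = 0$; the largest finite score is
  $ld^*/(ld^*+1)$.
* $T(\mathrm{OR})$: values outside $(0.01, 100)$ are ignored; with
  $\mathrm{OR}^*$ the batch maximum of $\max(\mathrm{OR},
  1/\mathrm{OR})$, $T = \mathrm{OR}/\mathrm{OR}^*$ above 1 and
  $1/(\mathrm{OR}\cdot \mathrm{OR}^*)$ below, so $T(x) = T(1/x)$ and the
  batch maximizer scores exactly 1.
* $T(\mathrm{RR})$: identical with RR.

Batch context ($ld^*$, $\mathrm{OR}^*$, $\mathrm{RR}^*$) is computed over
the full pair set of one run and echoed into the TSV header: transformed
scores are **not comparable across batches**.

## Classification and the map

With thresholds 0.95/0.05 the edge-posterior distribution is expected to
be bimodal, so pairs are classified: **direct** (edge posterior > 0.95);
otherwise **mediated** (Bonferroni-significant with association posterior
at or above the 0.1 floor); **parametric_only** (significant but
association posterior below 0.1 — co-occurrence too weak for the network
to capture); **none**.  The quadrant report counts (edge > 0.95) ×
significance and warns when a direct pair lacks parametric significance,
which questions the stability of the posterior landscape.  The
multimorbidity map keeps edges above the membership cut-off (default
0.05), and ego networks are induced subgraphs within an unweighted BFS
radius of a focus disease, optionally after dropping hub covariates (sex,
age) so they do not pull in unrelated nodes.

## Molecular-level scores

For cross-level comparison, `hypergeom_overlap()` computes the upper-tail
hypergeometric probability of a gene-set overlap (log-space via `phyper`;
the universe defaults to the union of genes in the loaded table,
configurable to the interactome node count — the study's own choice is not
public), and `separation_score()` the interactome module separation
$s_{AB} = d_{AB} - (d_{AA} + d_{BB})/2$, where $d_{AB}$ averages each
gene's distance to the nearest gene of the *other* set (shared genes
contribute 0) and $d_{AA}$ the distance to the nearest *distinct* same-set
gene (singleton sets contribute 0, the limiting convention).  Genes absent
from the interactome are dropped with a count; unreachable targets are
excluded from the means rather than treated as infinite.  Negative
$s_{AB}$ means topologically overlapping disease modules.

## The synthetic generator: what it emulates, and what it does not

`simulation_spec()` + `sample_random_dag()` + `sample_cpts()` +
`simulate_cohort()` emulate a large cross-sectional cohort: binary
lifetime disease indicators generated by ancestral sampling from a sparse
ground-truth DAG with logistic conditional tables, marginal prevalences
drawn log-uniformly (emulating the right-skewed prevalence spectrum of
disease registries, down to 1 per mille), sex (Bernoulli, female share
0.548 as in the emulated cohort) and a three-level age bin (raw ages
piecewise-uniform on [40, 75) with tertiles at 60 and 68, so
equal-frequency binning reproduces the canonical thresholds) acting as
confounders of a configurable fraction of diseases.  The logistic
parameterization is a choice — the real data-generating process is
unknown — adopted because it yields controllable prevalences and
OR-style effects.  `spec$max_parents` caps the *disease* parents drawn
for the random DAG; the confounder step can add sex and/or age on top,
so the effective in-degree cap is `max_parents + 2`.

Onset ages are drawn uniformly between a minimum onset age (default 10)
and the subject's age, in continuous years, then pairs in which a parent
disease and its child are both present are forced into causal order with
probability `p_order` (default 0.8, i.e. onset order reflects causal
order in 80% of affected pairs; the value is a stated property of the
world, not an estimate).  With several parents per child the per-edge
ordering probability is approximate — the last processed edge wins; the
controlled benchmarks use chain worlds where it is exact.

Not modelled: diagnosis error, selection bias, treatment effects,
questionnaire-derived phenotype definitions.  A green recovery test
therefore establishes that the pipeline recovers structure *from data
whose generating process matches the model class*; it does not establish
robustness to the biases of real self-reported cohort data.

## Benchmark worlds: parameter derivations

Two parameters of the acceptance worlds are derived rather than copied
from the emulated study, because the desk-scale sample size changes what
is identifiable:

* **Recovery world prevalence floor 0.05** (20 diseases, n = 20,000).
  The study's floor of 1 per mille at n = 117,392 guarantees at least
  118 cases per disease; at n = 20,000 a floor of 0.05 guarantees 1,000
  expected cases, giving each |log-odds| ≥ 1 edge enough information to
  be identified.  A benchmark is meant to measure structure recovery,
  not sample-size failure.
* **Onset world prevalence 0.01** (10-disease chain, n = 20,000, +2
  log-odds effects, `p_order = 1`).  After filtering occurrences that
  post-date the target's onset, the downstream neighbor's co-occurrence
  with the target is exactly zero.  Zero observed against an expected
  chance co-occurrence E must carry *less* evidence than the BDeu
  complexity penalty (≈ 0.5 log n ≈ 5 nats) for the direct edge to
  disappear rather than invert into a detectable negative dependence:
  prevalence 0.01 gives E ≈ 20000 · 0.01 · 0.011 ≈ 2 < 5, while the
  pre-filter dependence signal is ≈ 14 nats, far above the penalty.
  Both inequalities were fixed before any benchmark was run.

## Numerical choices and degenerate inputs

* Age bins are closed on the left: 60 ≤ age < 68 is bin 1; age 60 maps
  to bin 1.  Equal-frequency mode uses the (⌊n/3⌋+1)-th order statistics
  as left-closed cut points.
* Missing BMI excludes the subject from obesity coding (NA) with a
  logged count; the subject is otherwise retained.
* Subjects affected by the onset-filter target without a recorded target
  onset are left unchanged, mirroring "filter only where onset is known".
  Diseases without any onset information are kept by default
  (`keep_missing_onset = TRUE`), the convention used for BMI-derived
  obesity as a variable preceding the target.
* `exact_feature_posteriors()` refuses more than 5 variables: full DAG
  enumeration grows super-exponentially (29,281 DAGs at 5 nodes; over a
  million at 6).
* Logistic regression converges on relative deviance change < 1e-8 (100
  iterations max); constant predictors are dropped with a warning;
  separation is flagged from the glm warnings or from diverging
  coefficients (|beta| > 15).
* All randomness flows through explicit seeds; the compiled sampler uses
  its own 64-bit generator seeded from the configuration, so identical
  (cohort, config, seed) triples give bit-identical posterior matrices.

## Known limitations

* Structure MCMC with single-edge moves mixes slowly across
  score-equivalent valleys; the hill-climb initialization addresses the
  dominant-mode trap but genuinely multimodal posteriors (plausible on
  weak, near-threshold relations) are only diagnosed — via the
  cross-chain disagreement — not solved.  The sampler interface is
  pluggable by design.
* The exact taxonomy of structural relation types used by the original
  analysis is not public; marginal d-connection is the stand-in
  definition of structural association, flagged here deliberately.
* Complete data is assumed throughout scoring; missing disease
  indicators are rejected at ingest.
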