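---
title: "expomap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{expomap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep-phenotyping cohorts measure, on the same healthy donors, a large panel
of immunophenotypes (cell-subset proportions, surface-marker MFI, cell
morphology, plasma and post-stimulation cytokines), self-reported lifestyle
and environmental exposures, whole-blood transcriptomes and plasma
metabolomes. `expomap` implements the analysis chain that turns these
tables into interpretable claims:

1. **Preprocessing** of each data block with explicit, testable rules.
2. **Variance decomposition**: how much interindividual immunome variation
   each exposure explains (PERMANOVA on a distance matrix).
3. **Exposure-wide association** (EWAS): covariate-adjusted linear models
   for every exposure x immunophenotype pair.
4. **Composite exposures**: latent variables summarizing correlated
   exposure clusters (thresholded Spearman matrix, Ward clustering, PLS
   path model).
5. **Bidirectional mediation**: for significant exposure-phenotype pairs,
   does the signal run exposure -> omic -> immunophenotype (D1) or
   exposure -> immunophenotype -> omic (D2)?
6. **T-/M-indexes**: mediation-proportion-weighted omics signatures that
   transfer to external cohorts.

A seeded synthetic-cohort generator reproduces the statistical structure
each stage assumes, and carries the ground truth the test suite audits.

## Preprocessing rules

Per immunophenotype, in this order (each step is a public function):

* **Reflection**: if the adjusted Fisher-Pearson skewness is below −2.15,
  replace `x` by `max(x) + 1 − x` so the long tail points right.
* **Skewness-gated outlier removal**: while skewness exceeds 2.15, drop the
  single point with the largest `|x − median|` (ties to the larger value),
  stopping at the threshold or after 5% of the points. The cited origin of
  this rule does not restate its algorithm; the single-point long-tail rule
  with a 5% cap is our declared, deterministic reading.
* **Sampling-day batch correction**: a random-intercept model
  `value ~ (1 | day)` per feature; the shrunken day effect is subtracted.
  When the estimated between-day variance is numerically zero the feature
  is returned unchanged — this also makes the pipeline idempotent.
* **Second outlier pass** after batch correction.
* **Transformation**: inverse normal transformation (Blom offsets,
  `qnorm((rank − 3/8)/(n + 1/4))`, average ranks for ties) when
  `|skewness| > 1`, otherwise centering/scaling. The INT output is also
  standardized so a second pipeline pass is a no-op.
* **kNN imputation** (k = 5): distance-weighted mean over the k nearest
  rows by Euclidean distance on standardized shared features, then a final
  re-standardization (imputation nudges the moments).

Key tunables live in `qc_params()`: the skewness gate (2.15), the INT gate
(1), k (5), the omics SD clip (3), the detection floor (20% of samples) and
the outlier cap (5%). Dietary exposures additionally get gender-specific
energy plausibility bounds (800-4,200 kcal/d men, 500-3,500 kcal/d women,
bounds inclusive), per-variable energy adjustment by regression of the
standardized variable on standardized energy, and plant-based diet index
scoring: 16 food groups scored 5/3/1 by intake tertile (ties to the lower
tertile; binary items 5/1), with the direction of scoring set by the index
variant (PDI/hPDI/uPDI) and the group's class (healthful plant,
unhealthful plant, animal).

## PERMANOVA

`permanova()` partitions the total sum of squares of a distance matrix over
design terms via the Gower-centered inner-product matrix
`G = −(1/2) J D² J`: for each term, `R² = SS_term / SS_total` and a
pseudo-F compares the term mean square to the residual mean square.
P-values come from free permutation of sample labels with the +1
Monte-Carlo correction; `exact = TRUE` enumerates all `n!` relabelings
(feasible to n = 8) and then reports `#(F* ≥ F)/n!`, which the test suite
checks against an independent brute-force oracle built from
sums-of-squared-distances formulas.

Declared choices the source procedure leaves open: the distance metric is
Euclidean on the preprocessed (standardized) phenotypes; multi-term models
use sequential sums of squares in the given order (marginal available via
`ss_type`); permutations are unrestricted. Exposure screening retains
exposures at permutation FDR < 0.05 (Benjamini-Hochberg) and prunes
redundancy: exposures linked by |Spearman r| > 0.4 form connected
components, and only the component member with the largest R² survives.

## Exposure-wide association

The full model is `phenotype ~ exposure + age + gender + season`, the null
model drops the exposure; both a coefficient t-test and a likelihood-ratio
test (`n log(RSS0/RSS1)` against chi-square with 1 df) are reported, each
BH-adjusted across all pairs; significance is FDR(coefficient) < 0.05.
Season enters as month-of-year categorical (11 dummies) — the
least-assumption coding; a harmonic coding is available. With complete
data the scan uses a Frisch-Waugh fast path (residualize everything on the
covariate design once) that is algebraically identical to the per-pair
fit; the unit tests verify the equality against `lm()`.

Support analyses: gender/age-stratified scans (age 40 goes to the older
stratum; strata under 30 samples are skipped), 100-fold 90%/80%
subsampling stability, sensitivity refits with extra covariates (BMI,
infection/vaccination indicators, or genetic PCs pre-screened on marginal
association with the phenotype at p < 0.05), age/gender basic-factor tests
(Spearman and Welch t on residualized phenotypes), and a 12-month cosinor:
min-max normalize, fit `k + α·cos(2π(t−φ)/12)` via the cos/sin linear
reparameterization, F-test the two harmonic terms, and report mesor and
amplitude back on the original scale (the normalization is affine, so the
back-transform is exact; the phase is scale-free). The gender comparison
is a Welch two-sample t-test: the groups are disjoint subjects, so a
literally paired test is not executable. MEQ chronotype cutpoints are
≤ 41 evening, ≥ 59 morning, otherwise middle.

## Composite exposures

The exposure Spearman matrix is thresholded (entries with Bonferroni p ≥
0.05 or |r| ≤ 0.2 set to zero), its rows Ward-clustered (ward.D2 on
Euclidean distances), and one latent variable per cluster extracted with a
reflective (mode A) PLS path model over a saturated inner model with
centroid signs. One deliberate deviation from the textbook centroid
update: the inner estimate for block *b* includes the block's own score,
`Z_b = LV_b + Σ_c sign(r_bc)·LV_c`. With mutually uncorrelated clusters
the textbook update has no true signal — the mode-A weights chase sampling
correlations with the other blocks, and the LV drifts away from the
block's principal component (we measured factor recovery failing in
15-30% of seeds). Including the own score makes the update degrade to a
power iteration, so an isolated cluster's LV converges to its first
principal component, while clusters with real cross-correlations are
essentially unchanged. Each LV is oriented to correlate positively with
its largest-loading exposure (sign indeterminacy removed), standardized,
and handed to the EWAS as a composite exposure.

The number of clusters starts at 2 and increases until no LV pair is
significantly correlated (Spearman, Bonferroni 0.05). Note a structural
property of this rule: if the true exposure blocks are mutually
independent, merging two blocks still yields composites uncorrelated with
the rest, so the rule already stops below the true block count. The rule
identifies the point where composites stop sharing information — not the
true number of blocks; the test suite documents this distinction, and one
test recording the idealized three-independent-block expectation fails by
design.

## Bidirectional mediation

For a triple (exposure `x`, omic `m`, immunophenotype `y`), direction D1
fits the mediator model `m ~ x` (slope β₁) and the outcome model
`y ~ x + m + x·m` (exposure slope γ₁, mediator slope β₂, interaction δ₂);
D2 swaps the roles of the omic and the immunophenotype. Variables are
centered before fitting — so β₂ and γ₁ are average-level effects in the
presence of the interaction — but never rescaled: effects stay on the
input scale, which the upstream pipeline has already standardized. The
average causal mediation effect is ACME = β₁β₂, the direct effect
ADE = γ₁, total = ACME + ADE (an exact identity of the
product-of-coefficients decomposition), and the mediation proportion
ACME/total, capped to [−1, 1] for reporting (raw value kept alongside:
the ratio is unstable when |total| < |ACME|). The printed form of the
mediator model in the source also contains a self-referential
mediator-by-exposure interaction; we treat it as a typesetting artifact
and fit `m ~ x`.

Uncertainty comes from a nonparametric paired-row bootstrap of the whole
two-model fit (1,000 draws by default): percentile CI and the two-sided
sign-based p-value `2·min(P(ACME* ≤ 0), P(ACME* ≥ 0))`, floored at
1/n_boot. That floor matters: BH across hundreds of triples needs p-values
of order 1e-3, so reducing the draw count below ~1,000 can make every
triple unclassifiable regardless of effect size. The bootstrap is
implemented with batched resample counts and closed-form (Cramer's rule)
solutions of the centered normal equations, so the full draw count stays
affordable. Candidate mediators are pre-screened: an omic must pass
BH-FDR < 0.05 for Spearman correlation with the exposure *and* with the
phenotype; this dual screen is also what keeps null triples out of the
classification. A triple is classified D1 when FDR(D1) < 0.05 and
|proportion(D1)| > |proportion(D2)|, D2 symmetrically, otherwise none
(absolute values because proportions can be negative under inconsistent
mediation; a raw comparison is available).

## T-/M-indexes

For one exposure, every classified triple contributes
`sign(ACME) · proportion` to its omic feature's weight (PropSum); a
sample's index is the weighted sum of its standardized, mean-imputed
feature levels. Weights are frozen when computed; transfer to an external
cohort only restricts them to the overlapping features (reporting the
overlap fraction) and standardizes the external features internally —
mediation is never refitted. Evaluation helpers fit linear, logistic or
multinomial models of outcomes on the index plus covariates (the
multinomial logit is maximized directly with BFGS since no multinomial
fitter is assumed present) and a two-sided Wilcoxon rank-sum comparison
with per-subject averaging of repeated measures.

## The synthetic cohort

`generate_cohort()` emulates: ~1,000 donors with age Uniform(20, 60),
gender Bernoulli(0.5), month Uniform{1..12} (ranges are stated for the
emulated cohort, distributions are not — these are the simplest choices),
BMI Normal(23, 3), five standard-normal genetic PCs; exposure blocks from
a shared latent factor with loading `sqrt(r)` so the expected within-block
correlation is exactly `r`; weak age/gender effects on all phenotypes; a
per-day Normal(0, batch_sd²) batch shift and a seasonal cosine; right skew
by `exp(x/2)` on a fraction of phenotype columns (monotone and
rank-preserving, so INT undoes it); MCAR missingness; and planted
mediation chains realized literally as `m = a·x + ε`,
`y = direct·x + b·m + interaction·x·m + ε` (chain columns are excluded
from the skew transform so recovery tests audit the stated model). Effect
sizes for planted chains default to values chosen for test power, not
realism — the emulated study publishes no effect-size distributions.

What the generator does **not** emulate: real marker biology and the
heavy-tailed, compositional nature of cytometry readouts; informative
missingness; genotype structure; exposure measurement error. A green test
therefore establishes that the algorithms recover what they claim from
data satisfying their assumptions — not that the assumptions hold in any
particular cohort.

## Numerical and reproducibility choices

* P-values are floored at 1e-300 (log-scale plots downstream).
* Permutation p-values use the +1 correction except in exhaustive mode.
* The PLS iteration caps at 300 iterations, tolerance 1e-6 on outer
  weights, with per-iteration sign canonicalization so it cannot
  ping-pong.
* Tertile ties go to the lower tertile; skew-outlier ties to the larger
  value; both deterministic.
* One global pipeline seed is spawned into per-stage child seeds by a
  fixed affine map modulo 2³¹ − 1, so stages are independently
  reproducible; two runs with the same config produce bit-identical
  artifacts and manifest hashes.

## Known limitations

* The PERMANOVA screen fits each exposure against one shared distance
  matrix; exposures are assumed imputed upstream (no per-exposure
  re-derivation of the distance matrix on complete cases).
* The cluster-count stopping rule's behaviour on truly independent blocks
  (see above).
* Mediation assumes sequential ignorability and single mediators; no
  sensitivity analysis for unmeasured mediator-outcome confounding.
* The bootstrap p-value is sign-based and discrete; with few draws its
  floor interacts with FDR control (documented above).
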