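---
title: "Indirect pediatric reference intervals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect pediatric reference intervals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A reference interval (RI) is the central 95% range — the 2.5th to 97.5th
percentile — of an analyte in a healthy reference population, the everyday
decision tool of laboratory medicine. The classical ("direct") approach
recruits a priori healthy individuals; for children this is ethically and
practically hard, especially in narrow age bands. The "indirect" alternative
mines the hospital laboratory information system (LIS): outpatient records
are a mixture of mostly-normal and pathological results, and an unsupervised
partition can extract the presumed-healthy middle of that mixture. This
package implements two such partitions for serum creatinine, urea, and uric
acid — a three-component univariate Gaussian mixture (GMM) and a 3×1 batch
self-organizing map (SOM) — together with everything around them: record
cleaning, between-analyzer transference, nonparametric RI estimation with
90% confidence intervals, and a bias-ratio comparison against a direct
sample. Because the motivating direct (PRINCE-style healthy cohort) and LIS
datasets are not public, a synthetic generator with full ground truth stands
in for them and anchors every test.

## Cleaning

Cleaning runs per analyte in this order, and no step can increase the record
count:

1. **Missing and extreme values** are deleted. "Extreme" means outside
   configurable physiologic plausibility bounds; the source workflow states
   the deletion but not thresholds, so the shipped defaults are deliberately
   generous — creatinine (1, 2000) µmol/L, urea (0.1, 100) mmol/L, uric acid
   (10, 3000) µmol/L — and live in `default_bounds()`.
2. **Deduplication**: repeat testing is taken as a pathology signal, so only
   the earliest record per subject and analyte is kept (`dedupe_earliest()`;
   date ties break to the lower value, then input order). The stated rule is
   "within a year"; since the extraction window is a single year, earliest
   per subject over the whole window is equivalent and is what we implement.
3. **Age filter**: ages in [1, 17) decimal years, half-open, matching the "1
   to < 6 years" convention used throughout. Ages are taken as given; no
   birth-date arithmetic.
4. **Outliers**, per stratum: the sample is screened for normality by
   |skewness| > 0.5 (a pragmatic screen — the source applies Box-Cox "as
   appropriate"); when the screen fails, a Box-Cox transform
   y = (x^λ − 1)/λ with λ estimated by profile maximum likelihood over
   [−3, 3] is applied first. Tukey fences Q1 − 1.5·IQR / Q3 + 1.5·IQR
   (type-7 quartiles) then flag outliers on the working scale. Because the
   transform is strictly monotone, flags on the transformed scale equal
   flags from the back-mapped raw fences, which are reported on both scales.
5. **Strategy**: `per_analyte` removes flagged records of that analyte only;
   `radical` removes a subject from *all* analytes once flagged in *any* of
   creatinine, urea, or uric acid. Subjects missing an analyte are judged on
   the evidence present, with the partially observed count logged.

Whether fences should be computed per subgroup for the single-stratum urea
is unstated in the source; we compute them per configured stratum, so urea
uses one set of fences by default.

The published age/sex partition (creatinine: 1–<6, 6–<12, 12–<17 split by
sex; urea and uric acid: one stratum) ships as `default_strata()` and is
what the pipeline uses. `age_partition_tree()` reproduces the exploratory
decision-tree step — greedy integer-age splits maximizing within-leaf
variance reduction, with a per-leaf sex split kept when it explains at least
5% of the leaf SSE — but the pipeline deliberately does not depend on it. A
complexity threshold (`cp = 0.01` of the root SSE per split) keeps pure
noise unsplit.

## Transference

The direct cohort was measured on Roche, the LIS on Beckman; published
affine formulas exist from a common Abbott source to each. `compose_maps()`
chains them algebraically: for A→B (s₁, i₁) and A→C (s₂, i₂), the B→C map is
slope s₂/s₁ and intercept i₂ − (s₂/s₁)·i₁. For creatinine this gives
(x + 0.447) × 0.936 − 1.192 and for urea (x − 0.143) × 1.021 + 0.110 at
printed precision. Internally the slope is carried at full precision
(0.903/0.965 = 0.93575…): the published per-age-band means round correctly
under full precision in at least one row where the 3-dp slope fails, so the
original computation clearly used full precision. Verification against the
published two-platform table must respect print precision on *both* sides:
a row is checked exactly only when every source mean consistent with its
printed value maps to one printed transferred value; all rows are checked
for print-consistency.

## GMM partition

Per analyte and stratum, a three-component univariate normal mixture is
fitted to the cleaned LIS values by EM. The three components represent
pathologically low, normal, and pathologically high levels — two components
would suffice only if abnormality lived in a single tail. Initialization
follows the transferred direct sample of the same stratum: component means
at its quartiles, all SDs at its sample SD, and weights at equal thirds (the
source leaves weights unstated). The E-step is computed in log space; the
M-step uses weighted moment updates. Convergence is a relative
log-likelihood change below 1e−8 or 500 iterations (the source's "ideal
state" is unquantified); the trace is checked monotone. Component SDs are
floored at 1e−3 of the sample SD to prevent collapse. After convergence,
components are reordered by mean, which makes the fit invariant to
permutations of the initialization; the *middle fitted mean* — not the
component that started at the median — defines the potential-healthy
cluster. Assignment is hard (argmax responsibility, ties to the lower mean):
the source speaks of a "final classification", and soft weighting would
change the selected-set semantics. One consequence worth knowing: on truly
single-component data the three fitted components overlap and the middle
cluster is a *central subset*, so its percentile interval is narrower than
the whole sample's — degenerate inputs should be interpreted through the
fitted means, which stay inside the bulk.

## SOM partition

The SOM views the three renal analytes jointly. Complete
creatinine/urea/uric-acid triples are formed per subject (incomplete
subjects are dropped and counted — this matters below), each column is
centered and scaled to unit SD, and a 3×1 map is initialized by PCA: nodes
at −2.5, 0, +2.5 SD of the PC1 scores along the first principal axis. Batch
iterations then alternate nearest-codebook assignment (Euclidean, scaled
space) with neighborhood-weighted mean updates. The original work used a
proprietary locally weighted smoother; we approximate the neighborhood with
a Gaussian kernel over grid distance whose width decays linearly from 1 to 0
over the first half of the iteration budget, so the final updates are plain
cluster means — exactly the published step (4) — and with width 0 throughout
the algorithm *is* Lloyd's k-means from the same initialization, which is
how it is tested. Convergence is unchanged assignments with the kernel
fully shrunk, or 200 iterations. Nodes are ordered by the mean of their
codebook across the scaled analytes; the middle node is the normal cluster.
The proprietary cubic clustering criterion is out of scope (no published
values to compare); node counts and codebooks are reported instead. The SOM
is fitted per age/sex stratum, consistent with the per-subgroup reporting
of the source.

Selected fractions are reported against the full cleaned record count of
the analyte — the same denominator as GMM, matching the published
arithmetic. A subject without a complete triple can never be SOM-selected,
which is one concrete mechanism behind the observed pattern that SOM
partitions more strictly than GMM.

## Reference intervals and bias

Limits are the 2.5th/97.5th sample percentiles by the rank formula
r = p(n+1) with linear interpolation between order statistics (the CLSI
nonparametric convention; the source names only its software). Each limit
gets a 90% CI from the distribution-free rank method — the smallest
order-statistic window around r whose binomial coverage reaches 0.90 — with
a seeded bootstrap percentile fallback (2000 resamples) when the required
ranks fall outside the sample, as happens below n ≈ 120; n < 120 warns and
n < 20 errors. Distribution summaries report the bias-corrected sample
skewness and bias-corrected excess kurtosis, the conventions consistent
with near-zero printed kurtosis for near-normal data; they cannot be
verified against the unavailable microdata and are recorded as conventions.

The bias ratio divides the limit difference (indirect − direct) by the
between-individual SD, taken as the direct RI width divided by 3.92, and is
classified allowable (|r| ≤ 0.25), minimal (≤ 0.375), or unacceptable.
Reports round creatinine to 1 dp, urea to 2 dp, and ratios to 2 dp; full
precision is kept internally.

## The synthetic world

`default_simulation_spec()` states the world once:

* **Healthy components** use the published transferred direct-sample
  moments per stratum — creatinine 28.9 (5.6), 40.6 (5.6), 60.8 (12.7)
  boys, 52.2 (8.3) girls; urea 4.33 (0.99) — *including* their printed
  skewness (0.10, 0.23, 0.37, 0.08; urea 0.43). Skew is produced by an
  inverse Box-Cox transform of a latent normal: λ is solved so the
  population skewness matches the printed value, and the latent mean/SD are
  moment-matched to the printed mean/SD on a fixed normal quantile grid.
  This keeps `boxcox_fit()` testable against a known λ and gives healthy
  quantiles a closed form through the latent normal.
* **Correlation**: the healthy triple shares a latent Gaussian dependence
  with correlation 0.5 between analytes — a realistic order for renal
  filtration markers; uric acid parameters (means 210/250/320/280 µmol/L,
  SD 60–70, skew 0.3) are invented, since the source reports none.
* **Pathological components** are positive-truncated Gaussians 6 healthy-SDs
  from the healthy mean, mixed 20/60/20, independent across analytes given
  the subject's component label (no joint pathology model is published).
  Where mean − 6·SD would be non-positive — impossible for a concentration —
  the low mean is floored at 30% of the healthy mean and its SD shrunk to a
  third of that, keeping the component positive and well separated.
* **Messiness**: a 0.3 chance of a strictly later repeat visit per subject
  (values redrawn with 6% multiplicative log-normal noise), 0.5% missing and
  0.2% implausible values, so the cleaning chain has real work to do.

What the generator does *not* emulate: real LIS contamination is a heavily
overlapping continuum, not well-separated clusters, and the real cohort has
designed age/sex composition, pre-analytical covariates, and regional
structure. A green recovery test therefore establishes algorithmic
correctness under the stated mixture — it does not certify performance on
real hospital data, where the published fractions (e.g. ~55% GMM vs ~18%
SOM for creatinine) are far more divergent than in this idealized world.
One knock-on effect of the clean separation is worth stating: Tukey fences
prune much of the 6-SD pathological clusters, so the post-cleaning LIS no
longer carries the 20/60/20 mixing; mixing-recovery properties are
therefore measured at the partition stage, on data for which 60% healthy is
actually true.

## Numerical choices, in one place

* Box-Cox λ: `optimize()` on [−3, 3], tolerance 1e−7; |λ| < 1e−8 is treated
  as the logarithm.
* Quartiles and RI percentiles: type-7 interpolation and r = p(n+1)
  respectively; both exposed, neither silently switchable.
* EM: tol 1e−8 relative, 500 iterations, SD floor 1e−3·SD; responsibilities
  row-normalized in log space.
* SOM: Gaussian grid kernel, width 1 → 0 linearly over the first half of
  200 iterations; empty nodes held fixed with a warning; ties in assignment
  go to the first (lowest) node.
* Bootstrap CI fallback: 2000 resamples, explicit seed, percentile method.
* All generator randomness flows from a single integer seed; the pipeline
  derives direct/LIS/bootstrap seeds as seed, seed+1, seed+2.

## A worked run

```r
library(indirectRI)

run <- run_indirect_ri(ri_config(seed = 1, n_lis = 5000))
run$fractions          # selected fractions per analyte and method
run$reports$creatinine # summaries, intervals, bias ratios, density curves
plot(run, "creatinine")
```

## Limitations

The SOM neighborhood schedule approximates an unpublished proprietary
smoother, so numeric equality with the original SOM output is unattainable
by design; equivalence is established at the k-means limit and by recovery
on ground-truthed data. The published real-data summary tables ship only as
verification surfaces for the arithmetic (transference, bias ratios); the
microdata behind them are unavailable, so their raw summary statistics are
not reproduction targets. Uric acid distributions are invented. The
extraction window of the LIS data is treated as metadata only.
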