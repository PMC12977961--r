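---
title: "Methods: disconnectome metrics, reliable change and outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disconnectome metrics, reliable change and outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disconnectr)
```

# The problem

Resective epilepsy surgery removes anterior and medial temporal structures
and, with them, parts of the white-matter bundles carrying verbal-memory
signal — the fornix (hippocampus to diencephalon) and the ventral cingulum
(parahippocampal cortex to retrosplenial cortex). `disconnectr` quantifies
that structural disconnection per patient and links it to longitudinal
memory change. This vignette documents the models, the conventions and the
numerical choices, and what the simulation-based tests do and do not show.

# Geometric conventions

All geometry lives in world millimetres. A volume couples a 3-D array with
a 4×4 voxel-to-world affine; a point belongs to the voxel whose center is
nearest, implemented as round-half-up (`floor(x + 0.5)`) of the
inverse-affine image of the point. Voxel indices in the API are 0-based
(the NIfTI convention). Masks read from disk are binarized at > 0.5, which
tolerates the interpolation artefacts left by inter-space resampling.
Tractograms are MRtrix TCK only — points already in scanner mm — so no
per-dialect coordinate guessing is needed. Physical distances (e.g. the
1 mm dilation used for prior masks) are always measured in mm, never voxel
units, so anisotropic voxels behave correctly.

Streamlines are polylines. For voxel visitation, every segment is
resampled to an arc-length spacing of at most `step` mm, with the original
vertices always kept among the samples; the default step of half the
smallest voxel dimension prevents a segment from stepping diagonally across
a voxel unseen. A voxel's visitation count is the number of distinct
streamlines with at least one sample mapping to it; points falling outside
the grid simply contribute nothing (resection masks typically cover a
subvolume). The test suite checks these operations against a brute-force
oracle that samples every segment at 0.01 mm through an independent
per-point tally; run at a matching step, implementation and oracle must
agree exactly — sub-sampling-width voxel grazings are hit by neither or
both routes only when the sample sets coincide, which is why the oracle
comparisons pin the step to the oracle's spacing while production use
defaults to the half-voxel step.

# Disconnection measures

**Atlas rule.** The cohort atlas averages binary bundle masks on a common
grid; values are exact multiples of 1/n by construction. The
disconnection probability of a resection is the *maximum* atlas value over
resected voxels — deliberately independent of overlap volume — and is
binarized at 50%, a tie counting as disconnected. The unthresholded atlas
feeds the max rule; the 50% cut is applied afterwards.

**Transection.** The cavity is an exclusion mask: a streamline with any
sample in a cavity voxel is cut. `percent_cut` is the percentage of
streamlines removed; the surviving streamlines are returned as a proxy for
postoperative tractography.

**Volume and microstructure.** Bundle-mask volume is normalized to
intracranial volume and min–max rescaled across the cohort (a constant
cohort rescales to all zeros, with a warning, rather than dividing by
zero). Median FA/MD is taken over the *distinct voxels* the bundle visits,
each voxel counted once, so long or duplicated streamlines do not
overweight their voxels; taking the median over streamline sample points
instead would be a defensible alternative, but the voxel-support reading
matches how bundle masks are used elsewhere in the pipeline.

# Reliable change

Postoperative change in age-adjusted z-scores is regressed on age at
surgery, normalized resection volume and the preoperative z-score
(baseline entered as z-score, matching the scale of the response) with an
MM-estimate robust regression: S-type high-breakdown initial scale, then a
redescending bisquare M-step at 95% Gaussian efficiency. The model is fit
separately per task and postoperative timepoint. A subject is classified
−1 ("unexpected decline") when their residual falls below the lower limit
of an 80% confidence interval; we use the two-sided normal-theory limit,
−z₀.₉₀ · scale ≈ −1.2816 robust-scale units (the 10th percentile), so about
10% of a Gaussian cohort is flagged. A one-sided construction at the 20th
percentile is arguably also consistent with an "80% interval"; both are
implemented (`method = "empirical"` uses the residuals' own quantile) and
the two-sided normal-theory variant is the default, in line with
regression-based RCI practice. Observations missing a change score are
excluded from the robust fit but kept in the cohort: missing never means
"no change". The internal subsampling of the S-estimator is seeded
locally, making fits deterministic without disturbing the caller's RNG.
Because an exact (zero-residual) fit breaks the M-iteration, data that OLS
already interpolates are returned as that exact solution with scale 0 —
classification then refuses to run, since a zero-width interval is
meaningless.

# Harmonization

Scanner differences are screened per metric with a Welch two-sample t-test
(two scanners); only metrics significant at α = 0.05 are adjusted —
mirroring a gatekeeping workflow in which harmonization is a correction,
not a default transformation. The adjustment is the standard ComBat
location-scale model: features standardized on covariate-adjusted data,
per-batch additive and multiplicative effects estimated and removed, the
covariate fit restored. With empirical Bayes on, batch parameters shrink
across features under a normal/inverse-gamma prior with method-of-moments
hyperparameters; with EB off the procedure reduces to exact per-batch
alignment of residual means and variances, which is what the exactness
tests assert (with two batches and a handful of metrics the priors are
weak anyway). Age at surgery and age at onset are preserved as covariates
by default. The implementation is cross-checked against `sva::ComBat` in
the suggested-package tests.

# Outcome models

Change scores are modelled long-format (subject × task × timepoint) with a
linear mixed model: timepoint (factor, 3-month reference, so the 12-month
coefficient is the recovery relative to the early assessment), age at
surgery, age at onset, resection volume and preoperative score, plus at
most one tract term, with a random intercept per subject. Estimation is by
maximum likelihood, not REML, so that the confound-only and
confound-plus-tract fits are comparable by a likelihood ratio test:
χ² = 2(ℓ_full − ℓ_null), df = number of added fixed effects, tiny negative
statistics clamped to zero. Rows with missing outcomes are dropped;
subjects contributing a single timepoint stay in. Timepoint is coded as a
factor rather than continuous months because two postoperative assessments
cannot identify a functional form. Binary outcomes (RCI decline, seizure
freedom with ILAE class 1 versus above 1) use a logistic mixed model with
the same random-intercept structure across the two timepoints; complete
separation is detected on the fixed-effect part and answered with a
flagged Firth bias-reduced fallback (penalized likelihood, no random
intercept) rather than a silently diverging fit. Model fitting itself is
delegated to lme4; the package's contract is the variable set, the ML
log-likelihoods, the convergence flag and the LRT arithmetic.

# The synthetic cohort

The generator emulates the statistical structure the pipeline consumes,
not brain anatomy:

* **Bundle**: a fan of smooth streamlines (natural cubic splines through
  jittered knots) inside a 3 mm tube around a curved centerline; each
  streamline starts at a uniform position over the first 80% of the arc,
  mimicking fibres peeling off a trunk, and the whole bundle is rigidly
  shifted per subject (SD 0.75 mm). Knot jitter (SD 0.4 mm) is truncated
  at 2.5 SD so streamlines provably stay within tube radius + 3·SD of the
  generating centerline.
* **Cavity**: an ellipsoid (semi-axes 9 × 6 × 9 mm) whose posterior reach
  varies uniformly over a 20 mm range while its volume varies only through
  an independent ±15% size factor. Posterior reach, not volume, governs
  how much of the fan is transected; this deliberate decoupling gives the
  regression models leverage to separate the transection effect from the
  resection-volume covariate, emulating cohorts in which the two are
  correlated but not confounded. Under the defaults, transection fractions
  span the full 0–100% range.
* **Scores**: change from baseline follows
  Δz = β₀ + β_time·I(12m) + β_age·age + β_vol·resvol + β_tr·fraction +
  b_subject + ε, with β_tr = −0.5 per unit fraction, β_time = +0.25 (later
  assessments recover), β_age = −0.01/yr, β_vol = −1, ε ~ N(0, 0.25²),
  b ~ N(0, 0.2²), 8% missingness per postoperative timepoint. The mean
  change is therefore more negative at 3 than at 12 months. Raw scores
  are obtained by inverting the shipped synthetic normative table
  (plausible list-learning norms; real analyses must supply their
  instrument's published norms).
* **Maps and batches**: FA/MD maps are two-compartment (bundle vs
  background) plus Gaussian noise; scanner "B" adds +0.05 FA and
  −5·10⁻⁵ mm²/s MD offsets.

Per-subject seeds derive from the master seed by a fixed multiplicative
hash of the subject index, so a cohort can be extended without rewriting
existing subjects. Ground truth (every simulated component) is written to
a JSON sidecar sufficient to reconstruct each score exactly.

What passing simulations do **not** show: real change scores are noisier
than the generator's ε, real bundles are not tubes, real cavity/tract
correlations may be stronger, and AMIPB/BMIPB-style instrument differences
are not modelled — so power and calibration results transfer to real
cohorts only qualitatively.

# Simulation sizes and numerical choices

The test suite fixes all seeds and uses desk-scale problems chosen to keep
a full run in a few minutes while leaving Monte-Carlo error well inside
the asserted bands: oracle equivalence on 100 random bundle/mask/grid
instances (grids ≤ 18³, ≤ 8 streamlines, 0.01 mm oracle); RCI calibration
on 200 Gaussian cohorts of n = 150 (mean flagged fraction asserted inside
(0.08, 0.12) against the 10% theoretical rate); transection-effect
recovery over 100 replicate cohorts of n = 80 (mean estimate within 0.1 of
the true −0.5, LRT power above 80%) and 200 null cohorts shared between
the type-I-error check (rejection rate inside (0.02, 0.09)) and a
Kolmogorov–Smirnov comparison of the null LRT statistic with χ²₁.
Grid mismatch checks compare affines to 10⁻⁶; dilation includes voxels at
exactly the radius (≤ r + 10⁻⁹ guards float noise); the disconnection tie
at threshold counts as disconnected; likelihood ratio statistics are
clamped at zero.

# Known limitations

Registration between spaces is out of scope — all inputs are assumed
co-registered. Only the TCK dialect is read. The atlas max rule is the
literal rule, with no smoothing of the atlas. The GLMM's random-intercept
structure over two timepoints is weakly identified, which is visible in
occasionally singular fits on small cohorts; estimates remain usable and
the convergence flag reports optimizer complaints. No multiple-testing
correction across tracts is applied.
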