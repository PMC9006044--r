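---
title: "Methods: high-order network connectivity analysis and its synthetic verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-order network connectivity analysis and its synthetic verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofc)
```

# Overview

`neofc` analyses resting-state functional connectivity (FC) among the three
high-order brain networks — default mode (DMN, 6 nodes), dorsal attention
(DAN, 8 nodes) and executive control (ECN, 5 nodes) — from a 19-node sphere
parcellation of BOLD fMRI, and asks two questions of any cohort: is each
network *distinct* (more coherent internally than with the other networks),
and is the *reciprocal relationship* present (DMN–DAN connectivity lower
than either network's connectivity with the ECN)? Because the infant
datasets this kind of analysis targets are access-restricted and expensive
to handle, every stage of the pipeline is driven and verified by a
synthetic BOLD cohort generator with a known ground truth. This vignette is
the package's account of the methods, the tunable parameters, the numerical
choices, and what the synthetic verification does and does not establish.

# The processing model

## Motion scrubbing

Motion quality control works on the per-volume RMS successive intensity
difference (DVARS): `dvars[t] = sqrt(mean_c((x[t,c] - x[t-1,c])^2))`, with
`dvars[1] := 0` (no predecessor; it is excluded from the threshold
distribution and never flagged). A volume is an outlier when its DVARS
exceeds the 75th centile plus 1.5 interquartile ranges of the DVARS
distribution; quartiles use linear interpolation between order statistics
(R's default type-7 estimator — the estimator is not prescribed by the QC
regime this mirrors, so the common default was chosen). For volumetric data
the channels are voxels; for ROI-level data, the 19 ROI time-courses — the
testable analogue of an image-intensity DVARS.

Defaults in `scrub_config()` encode the acquisition regime the pipeline
targets (2300 volumes at TR = 0.392 s): discard the first 5 volumes
(equilibration), detect outliers on the remaining 2295, retain the
contiguous 1600-volume window with the fewest flagged volumes (ties broken
at the earliest start — the rule is otherwise underdetermined), and exclude
the subject when the window holds strictly more than 10% flagged volumes
(160 of 1600 tolerated; 161 excludes). Flagged volumes *inside* the window
are kept: the retained sample is continuous, and the count is used only for
the exclusion verdict. A consequence worth knowing: retained spike volumes
add shared variance and mildly inflate FC estimates; the exclusion rule
bounds, but does not eliminate, this contamination. The window search is a
sliding cumulative sum, linear in run length, and is property-tested
against exhaustive search.

## ROI extraction and filtering

Sphere extraction averages, unweighted, all voxels whose centre (0-based
indices through the volume affine) lies within the ROI radius — a
voxel-centre membership rule, chosen over partial-volume weighting as the
simplest exactly-testable convention. The shipped 19-node template uses
8-mm spheres at coordinates reconstructed from the widely used Raichle
(2011) adult landmark set; study-specific templates (e.g. after alignment
to age-specific structural atlases) are supplied as a CSV
(`name,network,x,y,z,radius`) and accepted everywhere. Two
anterior-intraparietal/superior-parietal pairs in the landmark set overlap
at this radius; validation warns, and only volumetric rendering — where
overlap would make voxel ownership ambiguous — refuses such templates.

The temporal filter is a 5th-order Butterworth low-pass at 0.08 Hz applied
forward and backward (zero phase), so filter lag cannot distort
between-channel correlations. The package performs the two passes itself
with 300-sample odd-reflection padding, which confines startup transients
to the discarded pads: a constant channel is reproduced exactly and the
channel mean is preserved. Finite zero-phase filtering still leaves edge
effects of the order of the endpoint values within roughly the pad length
of the boundaries when the signal carries stopband energy there; frequency
response is therefore verified in the settled interior against the analytic
Butterworth magnitude (passband 0.01 Hz attenuated < 5%, stopband 0.5 Hz
attenuated > 95% at TR = 0.392 s). The filter runs after scrubbing, on the
continuous retained window.

## Connectivity and summaries

FC is the Pearson correlation of pre-processed ROI time-courses,
Fisher-z transformed (`z = atanh r`); the diagonal is stored as zero and
excluded everywhere. For between-group pattern comparisons, the 171 unique
off-diagonal entries are z-scored within subject; the standard deviation
uses the population (n) denominator by default — the convention is not
fixed by the procedures this follows, so it is explicit and configurable
(`sd_type = "sample"`). Network summaries average the within-network pair
sets (15 DMN, 28 DAN, 10 ECN pairs) and between-network pair sets (48
DMN–DAN, 30 DMN–ECN, 40 DAN–ECN). The per-network "between" level used in
the two-way ANOVA pools all pairs with exactly one node in the network, so
the two pairings are weighted by their sizes; a mean-of-pairings
alternative is available by flag. The within-group verdict procedures use
raw Fisher-z summaries; normalization serves between-group comparisons of
FC *patterns*, deliberately removing overall-strength differences.

## Inference

The repeated-measures ANOVA is computed from orthonormal contrast scores:
for an effect spanned by contrast matrix `K` (orthonormal columns, `q` of
them), scores `D = Y K` give `F = (n · |colMeans(D)|² / q) / (tr(S) / q)`
with `S` the score covariance, on `(q, q(n-1))` degrees of freedom.
Sphericity is handled by the Greenhouse–Geisser estimator
`ε = tr(S)² / (q · tr(S²))`, bounded in `[1/q, 1]`, multiplying both
degrees of freedom — producing the characteristic non-integer dfs — before
the p-value is taken. The correction is applied only to effects involving a
factor with three or more levels; two-level effects keep `ε = 1` and reduce
exactly to the squared paired t-test (a tested identity). A Huynh–Feldt
variant was considered and not shipped: the Greenhouse–Geisser form is the
conservative default consistent with the reported-style dfs this mirrors.

Group comparisons adjusted for head motion are least-squares fits of
`value ~ group + motion` with a partial F for group; the motion summary is
the outlier count in the retained window (the natural scalar the QC stage
produces; any numeric covariate can be substituted). Bonferroni correction
is `min(1, m·p)` with the family size always an explicit argument — family
definitions are a reporting choice, so they are never inferred from vector
lengths. Defaults used by the verdicts: 3 (one per network) for
distinctness, 2 (the two DMN–DAN contrasts) for the reciprocal procedure,
1 for its omnibus ANOVA. `center_for_display()` removes inter-subject
variability (value − subject mean + grand mean) for plotting only.

The two verdicts are: **distinctness** — per network, a paired t-test of
within vs pooled-between FC; distinct iff corrected p < α and the mean
difference is positive; **reciprocal relationship** — a one-way
repeated-measures ANOVA over the three pairings plus the two paired
contrasts of DMN–DAN against the others; true iff the ANOVA and both
contrasts are significant with DMN–DAN lower. Both are directional by
construction: a significant effect in the wrong direction never fires a
verdict. All tests are two-sided at α = 0.05 before correction.

## Network structure

Node dissimilarity is one minus the Pearson correlation between rows of the
group-mean normalized FC matrix, excluding the two self-entries pairwise
(the similarity notion is otherwise unspecified in the procedures this
mirrors; correlation distance between connectivity profiles is the
field-standard choice). Clustering is agglomerative with average linkage
(UPGMA) by default — complete, single and Ward linkage are available — cut
at k = 3; *cluster purity* (fraction of nodes in their cluster's majority
network) quantifies how well clusters respect network identity: 1.0 for
perfect recovery, 8/19 for a single undifferentiated cluster under the
default template.

Non-metric MDS minimizes Kruskal stress-1,
`sqrt(Σ(d − d̂)² / Σ d²)`, alternating isotonic regression of configuration
distances on dissimilarity ranks (disparities `d̂`) with Guttman-transform
configuration updates; an update that would increase stress is rejected, so
the per-iteration stress trace is non-increasing by construction.
Initialization is the classical MDS solution of the *rank-transformed*
dissimilarities, making every step — initialization included — depend on
the input only through its ranks; invariance of the result under monotone
transforms of the distances is therefore exact, and tested with `d → d²`.
Additional random restarts (default 4 starts, controlled by a mandatory
seed) guard against local minima; the iteration cap (500) reports
non-convergence rather than failing.

# The synthetic cohort generator

The generator is the package's verification instrument: it produces runs
whose true network structure is known, so the pipeline's output can be
compared against what was injected.

**Covariance model.** A `covariance_spec()` fixes the 19×19 channel
correlation matrix blockwise: one within-network value per network, a
baseline between-network value, and a DMN–DAN override to inject (or
withhold) the selective decoupling. The implied matrix must be positive
semi-definite; slightly indefinite requests are repaired by clipping
negative eigenvalues at 1e-10 and renormalizing to unit diagonal, failing
(with the offending eigenvalue) when the repair would move any entry more
than 0.05 — block requests are either realizable near-exactly or rejected.

**Noise model.** Channels follow order-1 autoregression (coefficient 0.3 by
default) on correlated Gaussian innovations, initialized from the
stationary distribution; all channels share the AR coefficient, so
stationary cross-correlations equal the requested innovation correlations
while giving the series realistic low-frequency content for the 0.08 Hz
filter to act on. Motion artifacts are global additive offsets (default 10
channel SDs) on designated volumes — exactly the event class a
successive-difference metric detects: an isolated spike flags itself and
its successor. No hemodynamic response, physiological noise or
susceptibility artifact is modelled.

**Group profiles.** No usable effect sizes are published for these group
contrasts, so the profile values are generator choices, fixed once and
stated here (within DMN/DAN/ECN, between, DMN–DAN):

| profile | within | between | DMN–DAN |
|---|---|---|---|
| `term` | 0.30 / 0.35 / 0.25 | 0.10 | 0.02 |
| `preterm_tea` | 0.22 / 0.28 / 0.18 | 0.10 | 0.04 |
| `preterm_pre_tea` | 0.10 / 0.35 / 0.10 | 0.10 | 0.10 |
| `adult` | 0.50 / 0.55 / 0.45 | 0.10 | −0.05 |
| `null` | 0.10 / 0.10 / 0.10 | 0.10 | 0.10 |

The qualitative ordering encodes the findings the pipeline must be able to
recover: all networks cohesive with DMN–DAN decoupling at term and
(attenuated) at term-equivalent age; only the DAN elevated, no decoupling,
before term-equivalent age; strong blocks with mild anticorrelation in
adults; the DAN most cohesive in every profile; and a structureless null
for type-I control. Subject age metadata (gestational/postmenstrual age)
can be carried as annotation but is consumed by no operation — groups, not
ages, drive the implemented contrasts.

**Determinism.** A cohort is a pure function of its spec: per-subject seeds
are derived from the master seed, and the returned truth record (specs,
seeds, realized spike indices) regenerates every run bit-exactly.
Volumetric rendering places the ROI series into spheres on a voxel grid
(default 2.15 mm isotropic) with optional background noise; at zero noise,
rendering followed by extraction is the exact identity, which closes the
loop on the extraction rule.

# Verification scales and what they show

The test suite and `scripts/acceptance.R` run everything at sizes chosen to
give stable statistics on a single CPU: verdict recovery uses seeded
cohorts of 40 subjects × 400 volumes per profile (100 seeds in the test
suite, 50 in the acceptance script); cluster-purity recovery
uses 20-subject × 300-volume adult-like cohorts; scrubbing arithmetic runs
at the full 2300-volume scale; Monte-Carlo covariance convergence uses one
20000-volume run (sample correlations within 0.03 of target). Under these
conditions the term-like profile yields all-networks-distinct and
reciprocal verdicts in ≥ 90% of seeds, the before-TEA profile yields
only-DAN-distinct in ≥ 90%, null cohorts fire each verdict within
binomial noise of the α level, and adult-like cohorts cluster at purity
1.0 in ≥ 95% of seeds.

What passing these checks shows: the estimators, thresholds and verdict
logic recover injected structure of plausible magnitude at realistic sample
sizes, and control false positives under the null. What it does not show:
performance on real infant data — the generator has no hemodynamics, no
physiological or scanner noise structure, no spatial autocorrelation beyond
the block model, no registration error, and its group differences are
stylized. Results on real cohorts depend additionally on the upstream
preprocessing (motion/distortion correction, nuisance regression) that this
package deliberately leaves out of scope.

# Known limitations

* The shipped template is a reconstructed adult landmark set; infant
  analyses require a study-specific template (supported via CSV).
* The motion covariate for group GLMs defaults to the window outlier
  count; richer summaries (e.g. framewise displacement from realignment
  parameters) must come from upstream tooling.
* Degenerate inputs fail loudly rather than being patched: constant
  channels, perfectly correlated pairs, zero-variance normalization,
  zero-variance paired differences and collinear covariates are all
  explicit errors.
* Flagged volumes inside the retained window are kept (continuity over
  censoring), so residual spike contamination inflates FC slightly; at the
  default spike amplitude and exclusion threshold this does not change any
  verdict in the tested regimes, but heavily contaminated retained windows
  will bias FC upward.
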