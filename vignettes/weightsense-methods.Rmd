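---
title: "Models of perceived weight in weightsense: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of perceived weight in weightsense: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightsense)
```

## The scientific problem

In the size-weight illusion (SWI), the smaller of two equal-weight objects
feels heavier when lifted. Classic Bayesian cue integration predicts the
opposite: an equal-density prior should pull the smaller object's perceived
weight *down*. `weightsense` implements a family of models for perceived
weight of object *pairs* across general combinations of weight, volume and
density — not just the equal-weight stimuli of typical SWI studies — together
with everything needed to exercise those models end to end on synthetic
data: stimulus and trial construction, a magnitude-estimation cohort
generator, preprocessing, fitting, and cross-validated comparison.

## The stimulus design

The default stimulus set has 15 cubes in three subsets sharing one middle
cube (750 cm³, 375 g, 0.5 g/cm³):

* *equal density* (7 cubes, 0.5 g/cm³): volumes 550–950 cm³ in 100 cm³
  steps plus 50 cm³ steps around the middle cube;
* *equal weight* (5 cubes, 375 g): volumes 550–950 cm³, so density falls
  with size — classic SWI stimuli with pairwise density ratios 0.58–0.89;
* *increasing density* (5 cubes): density linear in volume through the
  middle cube (slope 0.045 g/cm³ per 100 cm³), so weight and density rise
  together.

Not every printed summary statistic of the original apparatus can hold
simultaneously with this step structure (the quoted pairwise extremes of
volume, weight and density differences are mutually inconsistent with the
subset step rules); the default set prioritises the subset structure, the
middle-cube values, the minimum 25 g weight step and the SWI density-ratio
range, and the whole set is configurable through `stimulus_config()` for
alternative reconstructions.

Trials: all 105 unordered pairs of distinct cubes, with the 14
middle-containing pairs entered three times (133 base entries — the only
integer reading consistent with 105 unique and 133 total pairs), each
presented twice with left/right switched: 266 trials per participant, in a
seeded per-participant random order, split evenly across two sessions (the
split rule is not dictated by the design; an even split is assumed).

## The synthetic cohort

The generator's defaults are the study conditions: 30 participants,
responses anchored to the middle cube labelled "50" (7.5 g per unit),
additive Gaussian response noise of SD 25 g, idiosyncratic response scales
(log-normal, median 1, log-SD 0.2), and a 0.4% rate of gross errors planted
at 8 noise-SDs. Where the emulated study does not state a value the
defaults are fixed once at values a psychophysicist would call realistic:

* *additive noise in grams*: no response-noise law is dictated by the
  descriptive model, and constant additive noise is the assumption under
  which unweighted least squares is the right estimator. A Weber-like
  magnitude-proportional option (`noise_model = "proportional"`) exists for
  robustness studies.
* *intercept C = 0*: the generating intercept is a free choice (only the
  non-intercept coefficients have reference values); zero keeps simulated
  estimates on the physical scale.
* *gross errors at 8 noise-SDs with random sign*: large enough to model
  misheard/misspoken magnitudes, and comfortably beyond the 5/4/3.5-SD
  removal thresholds once cell SDs are inflated by the outlier itself.
* *log-SD 0.2 for scale idiosyncrasy*: scale factors between roughly 0.7
  and 1.5 for 95% of observers, matching the spread one sees in anchored
  magnitude estimation.

Per-observer RNG streams are derived from the master seed, so enlarging a
cohort does not reshuffle existing observers.

What the generator deliberately does *not* emulate: response drift over the
session (the emulated design controls it with a repeated reference),
lift-to-lift motor variability, sequential (inter-trial) dependencies, and
any nonlinearity in the response scale. Passing recovery tests therefore
show that the pipeline is correct and well-conditioned under the stated
statistical structure, not that real observers satisfy that structure.

## Preprocessing

Raw units are converted to grams (× 7.5), then each participant's estimates
are multiplied by pooled-grand-mean / participant-grand-mean so every
participant has the same mean response. (Taken literally, the opposite ratio
would push participant means apart; the equal-mean postcondition is the
testable contract and fixes the direction.) Normalisation is idempotent and
leaves the pooled mean invariant.

Outliers are removed in three one-pass sweeps at 5, 4 and 3.5 SDs. The
condition cell is (unordered pair × judged cube), pooling left/right
position and repeats — position-resolved cells would halve the records per
cell for no modelling benefit, and the judged cube within a pair is the
quantity every later analysis conditions on. SDs use the n−1 denominator.
Survivors are re-normalised after each sweep; sweeps do not iterate to
convergence (the threshold sequence is the procedure). Cells with fewer
than 3 survivors are skipped with a warning.

One deliberate consequence of mean normalisation: the cohort's common scale
after normalisation is the *mean* of the observers' scale factors, which
for a log-normal with median 1 exceeds 1 slightly (≈ e^{0.02}) and varies
across cohorts with SE ≈ 0.2/√30. Recovered regression coefficients
therefore carry a common multiplicative wobble of a few percent — inherent
to magnitude estimation, and well inside the recovery tolerances used in
the tests. The gate SD σ is immune to it.

## Fitting the descriptive model

For fixed σ the model is linear in (C, β₁…β₅), so `fit_descriptive()`
profiles: exact linear least squares inside a one-dimensional search over
σ ∈ [1, 1000] g (16 log-spaced, seed-jittered starts, Brent refinement
around the best candidates). This replaces a generic 7-parameter gradient
descent with a search that cannot diverge and finds the global optimum of
the profiled objective up to the resolution of the start grid. Each record
is one residual; the two estimates per trial enter as independent rows with
judged/other roles swapped. Pooling is unweighted. Rank deficiency at
extreme σ (where the gate column becomes collinear with the density column)
is handled by pivoted QR with absent coefficients set to zero; the fitted σ
is flagged if pinned near a bound.

`component_ladder()` adds the five components greedily by maximal R² gain,
refitting everything (including σ once a gated term is active) at each
step; ties are broken by the fixed component order with a warning.
`loo_cv_descriptive()` leaves out each participant in turn and sums
held-out squared error; variants cover the linear reduction and the
volume-instead-of-density forms.

## The efficient-coding ratio model

The prior over (log volume ratio, log weight ratio) is a mixture of K
origin-centred bivariate Gaussians (K = 3 by default: 3 shape parameters
per component + 2 free mixture weights + the bias scale C_b = 12 free
parameters). Volume ratios are treated as noiselessly perceived, so
predictions live on the one-dimensional conditional slice at the true log
volume ratio. The slice is renormalised to a proper density before the
repulsion law b(θ₀) = C_b (1/p²)′ is applied — the law is defined up to a
constant, and renormalisation makes C_b identifiable. The derivative is
analytic (mixture of Gaussians), verified against central finite
differences at 1e−6 relative tolerance. A density floor (1e−12) keeps 1/p²
finite; stimuli inside the design's convex hull never reach it. Response
variance is predicted as variance_scale / p², with the single global scale
fitted by least squares through the origin.

Optimisation runs on an unconstrained reparameterisation (log SDs, atanh
correlations, weight logits) under L-BFGS-B with box bounds (SDs in
[0.02, 10]) and seeded multi-start. The parameter count of 12 for K = 3
counts 3×3 shape parameters, 2 weights and C_b; this is the only arithmetic
consistent with the model's degrees of freedom, and the package reports it
via `ratio_prior()$n_params`.

The single-object variant (`fit_single_object_model()`) applies the same
machinery in absolute (log volume, log weight) space with free component
means (that space is not origin-symmetric), fitting per-cube mean biases.
By construction its predictions cannot depend on the paired object — the
structural failure mode that motivates pair-level models, and an invariant
in the test suite. K defaults to 1 there: 6 free parameters against 15
per-cube biases; larger K is available but under-determined on the default
design.

## Competitor models

*Sub-prior mixture.* Three origin-centred ridge Gaussians in ratio space
(slope, along-ridge SD, across-ridge SD, weight), Gaussian likelihood
centred on the true ratios, posterior-mean readout computed in closed form
per component (responsibilities ∝ weight × marginal likelihood). The
original publication's parameterisation and fitted values are not
reproduced here; the model is reconstructed structurally and honestly
refitted to whatever bias field it is given (12 free parameters; the
across/along SD ratio is bounded below 1 so each component stays a ridge;
volume noise is fixed small to mirror the ratio model's assumption). The
posterior-mean readout (rather than model-averaged MAP) matches the
Bayesian least-squares convention used throughout the package. The closed
form is verified against brute-force 2-D numerical integration.

*Cue combination.* ŵ = β₁wˣ + β₂dʸ on the judged object only. For fixed
exponents the model is linear in (β₁, β₂); the fit profiles a bounded 2-D
search over (x, y) ∈ [0.2, 4]². Contextual invariance — predictions cannot
depend on the other object — is again a tested structural property.

## Evaluation

Bias fields orient every pair by lexicographically smaller cube id; natural
logs throughout; log symmetry makes the orientation harmless (swapping
flips all signs exactly). Per-trial log estimate ratios are pooled across
repeats and participants for the per-pair mean bias and variance; pairs
with fewer than two usable trials are excluded from variance statistics.
`compare_models()` ranks by cross-validation error when every model has
one, else by SSR. `cv_model_comparison()` compares the three pair-level
models in the two spaces where they are defined: records (grams) for
descriptive vs cue combination, per-pair bias (log ratio) for descriptive
vs sub-prior.

## Problem sizes and determinism

The package's simulation studies use the full study geometry (15 cubes, 266
trials). Cohort sizes are chosen per question: parameter recovery and
outlier-sensitivity checks run at the study's 30 participants; repeated
cross-validated model comparisons run at 10 participants per replicate
across 10 replicates, a size at which the model ordering is already stable
fold-to-fold. Every stochastic step (trial order, cohort draw, response
noise, optimiser starts) derives from explicit integer seeds, and all fits
are deterministic given their seed.

## Known limitations

* The descriptive model is a regression, not a process model: it describes
  how perceived weight depends on the pair, not why.
* Magnitude estimation identifies coefficients only up to the cohort's
  common response scale (see above); cross-study comparison of raw
  coefficient values should keep that in mind.
* The efficient-coding machinery uses the bias and threshold laws, not a
  full trial-level encoding/decoding simulation; difference-space priors
  (over weight/volume differences rather than ratios) are out of scope.
* Power-function exponents on weight and density live only in the
  cue-combination competitor; the descriptive model is linear in w and d
  with the gate as its only nonlinearity.
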