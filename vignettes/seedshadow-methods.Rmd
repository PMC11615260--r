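---
title: "Methods: step selection, activity, and mechanistic seed shadows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step selection, activity, and mechanistic seed shadows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshadow)
```

seedshadow links three data streams — a fine-resolution canopy height
model, GPS tracks of canopy frugivores, and captive-trial gut-passage
times — into spatially explicit predictions of where seeds are deposited
around a fruiting tree. This vignette is the package's account of the
models it fits, the parameters that matter, the numerical choices behind
them, and what the synthetic test bed does and does not demonstrate.

## The landscape stack

All covariates live on one projected, metre-based 10 m grid
(`LandscapeStack`): canopy height (m), a vertical complexity index,
distance to small and large canopy gaps (m), and a binary swamp mask.

**Canopy gaps.** A gap is a connected region of cells with no vegetation
above 5 m — the conventional forested/non-forested cut — detected with
4-connectivity (rook moves). Diagonal adjacency does not merge regions;
this is the conservative choice for treefall-gap delineation, and it is
what the area thresholds are calibrated against: regions of at least
50 m² are "small" gaps, at least 500 m² "large" gaps (every large gap is
therefore also a small gap, and the two distance layers share zero sets
on large gaps). Gaps are detected at the native CHM resolution and mapped
to the covariate grid by any-overlap; distances are centre-to-centre
Euclidean, computed with an exact distance transform and checked against a
brute-force all-pairs oracle in the tests. A landscape with no gaps at all
puts the distance layers at a configurable cap, defaulting to the raster
diagonal — a finite "farther than anything on the map" value that keeps
the covariate usable.

**Vertical complexity.** The vertical complexity metric is the normalized
Shannon entropy of the per-cell vertical profile of LiDAR returns,
VCI = −Σ pᵢ ln pᵢ / ln(nbins) over fixed-width height bins (default 1 m):
0 when all returns share one bin, 1 for a perfectly even profile,
invariant to the absolute return count. Entropy-based profile metrics are
the standard family for this quantity; the choice of entropy (rather than,
say, a rumple or FHD variant) is a package decision and is stated as such.

**Nodata discipline.** Nodata never enters a block mean or an entropy; a
block or profile that is entirely nodata stays nodata, and a swamp-mask
sentinel (e.g. 255) is propagated, never coerced to "not swamp".
Downstream, any step whose endpoint lands on nodata invalidates its whole
stratum.

## From fixes to strata

Tracks arrive as 5-min daytime fixes (devices off 18:30–5:45 local).
Animals qualify for analysis with at least 1000 fixes inside the study
polygon. Tracks are resampled to a 30-min fix rate with a ±5 min
tolerance by a greedy forward pass: from each kept fix, the next kept fix
is the one whose gap is closest to 30 min within the window; when no fix
qualifies, the burst ends and a new one starts beyond the window. Bursts
shorter than three fixes are dropped (a turn angle needs two consecutive
steps). The tolerance is a package default — the fix-rate target is a
study decision, the window around it is ours and configurable.

Each observed step with a defined previous heading becomes a stratum: the
used step plus K = 10 control steps sharing its origin and start time,
with lengths drawn from the fitted gamma and turn angles from the fitted
von Mises distribution applied to the previous heading. Ten controls is
the study's operating point; the tests verify that estimates move by less
than two standard errors when K is raised to 100 on the same observed
steps. Steps spanning the nightly device-off window are excluded;
covariates are read from the cell containing each endpoint (no
interpolation); station temperature is matched to the step end by nearest
record within 60 min (the station's slowest interval), earlier record
winning ties.

Continuous covariates (canopy height, VCI, both gap distances,
temperature) are centred and scaled per animal over all steps of that
animal, used and control alike, with the sample SD (n − 1). Binary swamp
is never scaled. The standardization parameters are stored with each
fitted model because the simulation must score new locations on exactly
the training scale.

## The step-selection model

Selection is the exponential habitat-selection function
w(x) = exp(βᵀx). Conditioning each used step on its stratum removes
everything constant within the stratum and leaves the conditional
log-likelihood

Σₛ [ βᵀx_used − log Σⱼ exp(βᵀxⱼ) ],

maximized by Newton ascent with step halving from β = 0, converged when
the gradient max-norm falls below 1e-8; the covariance is the inverse
observed information. The default design follows the study: the five
habitat covariates, the swamp-by-temperature interaction (standardized
temperature times raw binary swamp), and the movement terms log(SL + 1)
(SL in metres, natural log) and cos(TA), which correct the tentative
kernel within the same likelihood — the "integrated" in integrated step
selection analysis.

Failure modes are flagged, never silent: covariates constant within every
stratum raise an identifiability error naming the variable; strata with no
variation at all are dropped with a count; separation — a coefficient
drifting past 15 on standardized covariates with a non-vanishing
gradient — sets `converged = FALSE`. On problems small enough to
enumerate, the fitter matches an exhaustive grid search to 1e-3, and on
simulated strata it matches `survival::clogit` (an independent
implementation) to 1e-5.

The tentative kernel itself is fitted by maximum likelihood: the gamma
shape by the profile-likelihood Newton iteration (zero-length steps offset
by half a cell so the likelihood exists), the von Mises concentration by
inverting the Bessel ratio A₁(κ) = R̄, capped at 500 and flagged
degenerate at the cap. Collinearity is screened before fitting: covariate
pairs with Pearson |r| strictly above 0.6 over all steps are not entered
together.

## Population level

The primary population estimator is two-stage inverse-variance pooling:
β̂ = Σ(βᵢ/seᵢ²)/Σ(1/seᵢ²) with se = (Σ 1/seᵢ²)^(−1/2), over converged
individual fits. It is transparent, exactly testable, and matches the
study's secondary analysis; the random-slopes GLMM (Poisson reformulation
with the stratum intercept variance fixed large, via glmmTMB) is provided
as an optional extension and agrees with pooling within two pooled
standard errors on shared synthetic truth. Species contrasts are
weighted-least-squares ANOVA of individual coefficients on a species
indicator (weights 1/se²), computed from the explicit sums of squares so
the degenerate identical-coefficients case returns F = 0, p = 1 exactly.

The swamp-by-temperature interaction is additionally displayed by
refitting swamp selection within four temperature bins — (−∞,22),
[22,25), [25,27), [27,∞) °C, left-closed so 22 joins the second bin and
27 the fourth (the published bin labels leave the boundaries ambiguous;
half-open left-closed is our stated convention). Each bin keeps the strata
whose used step experienced a bin temperature, refits per individual, and
pools per species.

## Activity (ODBA)

ODBA of a 20-s tri-axial burst is the non-vectorial sum over axes of the
mean absolute deviation from the per-burst axis mean. The per-burst mean
is the static (gravitational) component — no running mean is needed at
20 s — making ODBA exactly invariant to per-axis constant offsets and
linear in dynamic amplitude; both properties are asserted in closed form.
Raw counts are converted to g by an explicit per-axis slope/intercept
calibration (identity for data already in g; tag-specific transformations
are a required user input, not guessed).

Candidate activity models are every subset of the supplied predictors,
fitted as linear mixed models with a per-animal random intercept by
maximum likelihood (not REML, so AICc is comparable across fixed-effect
structures) and ranked by AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with k
counting fixed effects, the intercept and two variance parameters. A
single animal degrades to ordinary least squares under the same k
convention, so the ranking is then the OLS ranking.

## The seed-shadow simulator

The dispersal model chains four ingredients:

1. **Gut passage.** A reported mean ± spread (minutes) becomes a gamma
   distribution by moments: shape = (mean/spread)², scale =
   spread²/mean. The spread is treated as the standard deviation of the
   gut-passage distribution; the source feeding trials report "standard
   errors" without the trial n, so an SE-to-SD conversion is impossible
   and this interpretation is a declared assumption of the package.
2. **Deposition weights.** With 20-min steps, step k receives
   w_k = F(k·20) − F((k−1)·20) of deposition probability; weights plus
   the tail beyond the 50-step horizon (1000 min) telescope to 1 exactly.
   The tail is reported, never silently renormalized — for fast guts it is
   numerically zero, for slow ones it is an honest loss term.
3. **The redistribution kernel.** Only coefficients significant at
   p < 0.05 (Wald) enter, mirroring the study's model reduction; the
   kernel is time-agnostic, so the temperature interaction never enters.
   At each of 50 steps, 100 candidate endpoints are drawn from the
   tentative kernel and one is kept with probability proportional to
   exp(βᵀx), movement terms included, habitat covariates standardized
   with the stored training parameters. The candidate count is a package
   default (the study does not print one); 100 balances kernel fidelity
   against runtime and is configurable. Candidates off the raster or on
   nodata score zero; if an entire candidate set is invalid the draw is
   retried up to 10 times, then the trajectory is flagged stuck and holds
   position — visible in the output, not an exception.
4. **Rasterization.** Each step-k endpoint of each of the 100 trajectories
   deposits w_k/100, smoothed by an isotropic Gaussian (default bandwidth
   30 m = 3 pixels, truncated at 4σ and renormalized over the truncated
   support) on the 10 m grid. The default extent is the endpoint bounding
   box padded by 4σ, which conserves the deposited mass to machine
   precision; a user-supplied extent may crop, and the truncated mass is
   reported. λ is total mass over pixel count — so λ falls as the mapped
   extent grows at fixed mass, which is why the extent convention is
   stated explicitly. Dispersal distances are deposition-weighted
   quantiles of endpoint distance from the source; seed points, when
   wanted, are per-pixel Poisson draws with intensity deposition ×
   expected visits, uniform within pixels.

The simulation is checked the way the study checked it: covariate
distributions at used, available and simulated endpoints are compared
(quantile tables, shared-bin histograms, and a total-variation score
between used and simulated), and a kernel built from fitted coefficients
scores closer to the used distribution than a null (β = 0) kernel on
synthetic data.

## The synthetic test bed

The generators produce every pipeline input with known truth at the
study's conditions: a 3 × 3 km landscape at 10 m (canopy height a
Gaussian random field smoothed to an 80 m range, mean 30 m, SD 8 m; gaps
carved below 5 m at requested areas; swamp discs; a VCI field correlated
≈ 0.3 with height — deliberately below the 0.6 screen), a sinusoidal diel
temperature cycle peaking mid-afternoon, 5 animals × 600 daytime decision
steps at 30 min emitted as 5-min fixes, and accelerometer bursts whose
expected ODBA equals a requested level (the finite-sample bias of
mean-centring is corrected analytically). Random fields are built by
convolving white noise with a Gaussian kernel — simple, exact to test, and
dependency-free — rather than spectral synthesis.

Tracks are simulated by the same choice-set mechanism the models assume:
candidates from the tentative kernel, one kept ∝ exp(βᵀx). That makes
recovery tests sharp — a pooled canopy-height coefficient of 0.3 is
recovered within ±0.1 by the full pipeline, Wald 95% intervals cover the
truth in ≥ 85% of 200 conditional-model replicates, and a positive
swamp-by-temperature slope reproduces the rising temperature-bin pattern.
It also bounds what passing means: the generator shares the model's
functional form, so these tests demonstrate estimator correctness and
pipeline integrity, not robustness to real-data violations (irregular fix
success, behavioural modes, temperature gradients across habitats,
autocorrelated selection). One deliberate mismatch is retained: truth is
expressed on the landscape-wide covariate scale while refits standardize
per animal, so recovery tolerances absorb realistic scale slippage.

Problem sizes throughout (300 × 300 landscapes, 5 × ~600 steps, 150–450
strata per calibration replicate, 100 trajectories) were chosen as the
smallest at which the recovery targets are stable; the full suite runs in
about two minutes on one core.

## Known limitations

- The lon/lat reader projects onto a local tangent plane; beyond a few
  tens of kilometres a proper projected CRS should be supplied instead.
- Distance-to-gap saturates at the raster diagonal on gapless rasters; the
  cap value is visible in the stack provenance.
- The redistribution kernel holds the landscape fixed and is time-
  agnostic: no fruiting phenology, multi-tree itineraries, or
  temperature-dependent simulation.
- Inverse-variance pooling treats individual fits as fixed-effect inputs;
  between-individual variance is visible in the species ANOVA but not
  propagated into pooled intervals (the GLMM extension addresses this).
- Strata are dropped whole when any endpoint leaves the raster, which
  near map edges loses data and can bias selection estimates toward the
  interior; simulate on padded rasters where possible.
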