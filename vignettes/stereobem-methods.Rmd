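---
title: "A single correlation-based mechanism for depth in mixed-correlation stereograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single correlation-based mechanism for depth in mixed-correlation stereograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(stereobem)
```

## The scientific problem

A half-matched random-dot stereogram (RDS) contains equal numbers of
binocularly matched and anticorrelated dots, so its mean binocular
correlation is zero — yet human observers reliably report the depth of a
disparity-defined disk in such stimuli.  Because the classic binocular
energy model (BEM) of V1 complex cells responds linearly to binocular
correlation, it signals no disparity at zero mean correlation, and this
has been taken as evidence for a second, "match-based" computation in
stereo vision.  This package implements the alternative hypothesis: a
*single* correlation-based mechanism — the BEM with one extra static
squaring output nonlinearity — extracts depth from half-matched stimuli
by converting *local fluctuations* in binocular correlation into a change
in mean firing rate.  The package provides the stimulus generator, the
model neurons, a noisy opponent population decision model, and the
statistics used to analyse the simulated psychophysics.

## Stimuli

`stim_params()` describes a dynamic RDS: anti-aliased black and white
dots (luminance −1/+1 on a gray 0 background) covering a disparity-defined
central disk (2.5° diameter) and a zero-disparity annulus (1° wide).
Defaults follow the standard configuration: a 292 × 292 px field at
0.03°/px, 0.09°-radius dots at 24% density (density is nominal coverage;
dots may occlude, and may exceed 100%).  Each refresh interval shows a
fresh pattern; a trial's frames are painted in a single random order so
occlusion carries no cue.  A matched dot has the same polarity in the two
eyes, an anticorrelated dot opposite polarity; `match_level` (or
equivalently `binocular_correlation = 2·match_level − 1`) sets their
proportion.  "Uncorrelated" stimuli instead use completely independent
dot patterns in the two eyes.

Numerical choices worth knowing:

* **Anti-aliasing.**  Dot edges use coverage-weighted intensity,
  `cov = clamp(r + 0.5 − dist, 0, 1)` in pixel units, composited over
  earlier dots so later dots occlude.  Both eyes use identical sub-pixel
  dot centres.
* **Disparity realization.**  The disparity is split symmetrically:
  dot centres move by +d/2 in the left eye and −d/2 in the right.
  Because dots are rendered at continuous sub-pixel centres, the split is
  applied exactly, with no rounding to the pixel grid: snapping each
  eye's half-shift to whole pixels would annihilate the ±0.03° fine
  condition (one pixel of total disparity) and make conditions such as
  ±0.075° unrepresentable.
* **Match-level rounding.**  With an odd dot count, `round(0.5·n)` would
  bias every frame toward positive correlation; the fractional dot is
  assigned at random so realized counts are unbiased.
* **Frame schedule.**  Frame k starts at k/refresh; a trial shows
  `ceiling(duration × refresh)` frames, the last one truncated to the
  remaining time (`n_complete_frames` counts the whole ones).
  `alternation_params()` flips the pattern correlation between +1 and −1
  as a square wave (the refresh rate must be an integer multiple of twice
  the alternation rate), with the start phase optionally randomized.

`binocular_pixel_correlation()` verifies the construction: it evaluates
the per-frame Pearson correlation of left vs right pixels inside the
disk, eroded by one dot footprint so correlated surround dots spilling
across the boundary do not leak into the estimate.

## Model neurons

A `bem_unit()` is a model complex cell: two binocular simple cells built
from quadrature-phase Gabor subunits,

* monocular RF: an isotropic Gaussian envelope (SD σ) times a cosine
  carrier at `f` cycles/°, offset by +Δx/2 (left eye) or −Δx/2 (right
  eye) — pure position disparity, no phase disparity;
* simple cell: `S = (V_L + V_R)²`; complex cell: `C = S1 + S2` over the
  two quadrature phases;
* output: `C` for the binocularly linear model (`exponent = 1`), `C²`
  for the model with the squaring output nonlinearity (`exponent = 2`).

Because `E[X²] = E[X]² + Var[X]`, the squared model turns the
correlation variability of half-matched patterns into a mean response:
`tuning_curve()` shows flat half-matched tuning for the linear model and
a clear peak at the preferred disparity for the squared model, and
`normalized_response()` quantifies it as
`R_norm = (⟨R_hm⟩ − ⟨R_unc⟩)/(⟨R_corr⟩ − ⟨R_unc⟩)`.

The temporal dimension uses a separable biphasic kernel: a gamma-density
envelope `t^(α−1) e^(−t/τ)/(Γ(α)τ^α)` times `cos(ωt + φ)`, with defaults
α = 2.5, ω = 8π rad/s, φ = −π, τ = 0.035 s.  The printed normalization is
read as the gamma density (envelope `t^(α−1)/(Γ(α)τ^α)`); the absolute
scale cancels downstream because population responses are normalized.
Under these defaults the on-phase (positive lobe of the cosine factor)
spans 62.5–187.5 ms, i.e. 125 ms, and the spectral peak of the sampled
kernel computes to 4.61 Hz.  (With a `t²` envelope instead, the peak
would be 4.26 Hz; the package keeps the equation as written and reports
the value its own computation yields.)  A non-oscillatory `lowpass` kind
(the same gamma envelope without the carrier) serves as a sustained,
low-pass comparison kernel; no equivalence with any specific published
low-pass kernel is claimed.  Stimulus frames are expanded to the 1 ms
simulation grid by zero-order hold and convolved causally; the kernel is
truncated where its envelope falls below 10⁻⁶ of peak.

Two numerical caveats are intrinsic to this parameter regime and worth
stating: with `f·σ = 0.3125` the Gabors hold very few carrier cycles, so
the quadrature pair's norms differ by the `exp(−(2πfσ)²)` term and
complex responses are phase-invariant only to ~10⁻³ (exact invariance is
recovered for many-cycle units); and spatial inner products are computed
at the stimulus resolution of 0.03°/px with patches truncated at ±5σ
(beyond ±4σ the envelope is < 3·10⁻⁴ of peak), which bounds the
truncation error of responses at ~10⁻⁶ relative.

## The opponent population and decision rule

`build_population()` places 40 receptive-field locations per disparity
magnitude inside the central disk, each hosting a neuron and its
antineuron (same location, opposite-sign preferred disparity): four
preferred disparities (±0.03°, ±0.48°), 160 cells.  RF size follows the
size-disparity correlation `σ = 0.023 + 0.41·|Δx|` and the carrier
frequency the physiological scaling `f = 0.3125/σ`.  Locations within a
group keep ≥ 2σ centre spacing ("non-overlapping"); where 40 such
locations cannot be packed (the coarse group), the spacing relaxes
geometrically by factors of 0.85 until placement succeeds, and the
realized spacing is stored in the population object.

Each unit's responses are divided by its normalization constant — the
mean response to 100% correlated stimuli at its preferred disparity at
the 21.25 Hz reference refresh — so all cells peak at 1
(`estimate_norm_constants()`).  Gaussian noise with variance
proportional to the instantaneous normalized response
(`P_k = c_k + κ·ε_k`, `ε_k ~ N(0, c_k)`) is added independently per unit
and per 1 ms time point; summed over a trial, that noise is exactly one
Gaussian per unit with variance `κ²·Σ_k c_k`, which is how the bulk
simulator draws it (the literal per-time-point path is
`noisy_response()` and `decide_trial()`).  Opponent pairs are differenced
and summed over time and pairs; the readout reports "far" iff the grand
sum is strictly positive, so an exact zero tie reads out "near", exactly
as the decision equation is written (ties have measure zero once noise
is present).

`calibrate_kappa()` sets the noise to a behavioural anchor: accuracy
0.95 for fully correlated stimuli at the reference condition.  Because
the noise enters the decision variable as a single Gaussian of known
variance, the expected accuracy at any κ is
`mean(Φ(g_j·S_j/(κ√V_j)))` over simulated stimulus trials, a smooth
monotone function solved by root finding — no Monte-Carlo re-decisions
are needed inside the search.  κ is calibrated separately per refresh
rate (at fixed duration, faster refresh averages more patterns and
reduces stimulus-driven variability).

## Simulated experiments and their scale

All psychophysics harnesses balance trials between the two disparity
signs and report exact (Clopper-Pearson) binomial 95% intervals.

* `correlation_disparity_experiment()`: correlation −1…+1 (step 0.2) at
  fine (±0.03°) and coarse (±0.48°) disparity, 21.25 Hz, 1.5 s, with the
  static (space-only) population.  Fine beats coarse around zero
  correlation because the fine cells' small RFs see larger correlation
  fluctuations; both show reversed depth (accuracy < 0.5) at
  correlation −1.
* `correlation_refresh_experiment()`: the same task at 5.3 vs 42.5 Hz
  with the biphasic kernel and per-rate κ; slow refresh wins at zero
  correlation because the kernel integrates fewer independent patterns.
* `dot_size_experiment()`: half-matched vs correlated at dot radii
  0.025/0.05/0.075°, ±0.075°, 21.25 Hz, 500 ms.  κ is the smallest value
  holding every *reachable* correlated condition at the 0.95 target.
  Note a genuine property of the model in this condition: ±0.075° lies
  beyond the fine cells' quarter-cycle limit (1/(4f) ≈ 0.028°), and for
  the smallest dots the population's summed opponent signal reverses
  sign for correlated patterns — the model then cannot reach high
  correlated accuracy at 0.025° dots at any noise level, so that
  condition is excluded from calibration with a warning.  The
  half-matched decline with shrinking dots is robust to this.
* `alternation_experiment()`: alternating-correlation stereograms
  (120 Hz refresh, density 200%, surround following the centre,
  randomized start phase, 500 ms) at alternation rates 3.75–60 Hz, for
  the biphasic or low-pass kernel and for the binocularly linear control
  (`exponent = 1`), which is at chance at every rate because its signal
  flips sign with the correlation and the start phase is random.
* `sweep_density_rf()` / `sweep_refresh_rf()`: `R_norm` grids over dot
  density (0.01–5.12) or refresh rate (1–100 Hz) against RF size
  (σ 0.01–0.3°, relative size σ/r with r = 0.09°).  The three stimulus
  classes share dot layouts per pattern (common random numbers), which
  substantially tightens the delta-method standard error of `R_norm`
  reported per cell.

Default problem sizes are desk-scale choices: 3×3 subgrids for the
`R_norm` sweeps (the full grids are 11×30 and 11×30); the acceptance
checks run 20 000 patterns per density cell (the full-scale value —
static patterns are cheap) and 2 500 trials of 2 s per refresh cell
(full scale: 5 000 × 10 s), and 1 000 trials per psychometric point
(full scale: 10 000).  The sweep subgrids sample the steep part of the
response surface; toward high density × large σ/r (and toward high
refresh rates) the surface saturates at 0 and differences between
neighbouring cells vanish below any fixed Monte-Carlo resolution, while
below σ ≈ 0.05° the σ-direction plateaus.

## Statistics

* `binomial_ci()`: exact Clopper-Pearson intervals via beta quantiles.
* `mc_proportion_test()`: a resampling analogue of one-way ANOVA for
  binomial proportions — under the null all groups share the mean
  proportion; the across-group variance of resampled proportions is
  compared to the observed one, with the (+1)/(+1) small-sample
  correction.
* `fractional_area()`: odd-symmetry of a proportion-correct vs
  correlation curve, `A₋/A₊` with `A± = ∫|fit − 0.5|` over the negative
  / positive half of the correlation axis.  The fit is a monotone
  shape-preserving spline through the condition means (reversed-depth
  curves are not sigmoid, so no parametric family is imposed), clipped
  to [0, 1]; both the fitted-curve and raw-points variants are returned.

## What the simulations do and do not show

The generator reproduces the *statistical* structure of the experimental
stimuli — dot geometry, match level, refresh and alternation schedules —
but not display physics (gamma, monitor timing, optics) or human factors
(eye movements, vergence noise, attention).  Passing simulations
therefore show that the single-mechanism model accounts for the
qualitative pattern of psychophysical results under matched stimulus
statistics, not that it predicts absolute human thresholds; the noise
magnitude κ is a free parameter anchored to one behavioural ceiling per
condition family.  Reversed depth in this model is stronger than in
human reports (a higher output exponent would reduce it), and no
account is taken of the surround-correlation dependence of reversed
depth — the model sees only the population at one retinal location.

## A worked example

```{r tuning, eval = FALSE}
u <- bem_unit(dx = 0.1, sigma = 0.1)
tc <- tuning_curve(u, stim_params(), n_patterns = 2000, seed = 1)
plot(tc)
normalized_response(tc)
amplitude_ratio(tc)
```

Reproducible batch runs go through the config layer:

```{r config, eval = FALSE}
cfg <- run_config(experiment = "correlation_disparity", seed = 1,
                  scale = 0.1, out_dir = "results")
run_experiment(cfg)   # writes CSV + JSON manifest
```
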