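---
title: "Models and methods behind tirfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tirfkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(tirfkin)
```

# The measurement

In single-molecule TIRF microscopy of a supported lipid bilayer (or of a
cell's plasma membrane), only fluorophores within the evanescent field are
visible, so the appearance and disappearance of a diffraction-limited spot
report membrane association and dissociation of one molecule. Three
quantities summarize the binding behaviour of a peripheral membrane
protein:

* the **dwell time** distribution — how long molecules stay bound, modeled
  as a one- or two-component exponential mixture;
* the **step-size** distribution — how fast bound molecules diffuse,
  modeled as a one- or two-species 2D Brownian (Rayleigh) mixture;
* the **association rate constant** `kON` — how often molecules bind per
  unit membrane area, time and solution concentration.

tirfkin implements the full analysis chain for these quantities and, just
as importantly, a ground-truthed simulator of the same generative process,
so every fitted parameter can be validated by parameter recovery.

# The simulator

`simulate_trajectories()` composes four stochastic layers:

1. **Arrivals.** Molecules appear on the membrane as a homogeneous Poisson
   process with intensity `kon * C * A` (events/s over field area `A`,
   concentration `C` in uM). `simulate_arrivals()` exposes this layer
   alone.
2. **Dwells.** Each molecule stays bound for a time drawn from
   `alpha * Exp(tau1) + (1 - alpha) * Exp(tau2)`; `alpha` is the fraction
   of the fast-dissociating population and `tau1 <= tau2`. An optional
   photobleaching rate `b` censors the observed dwell by an independent
   `Exp(1/b)` time; for single-exponential dwells this yields observed
   dwells that are exponential with rate `1/tau + b` (a closed form the
   test suite checks). Bleaching is simulated but never corrected for in
   the analysis — long-dwelling species are therefore systematically
   underestimated when bleaching is on, exactly as in the real assay.
3. **Motion.** Each mobile molecule performs 2D Brownian motion: x and y
   increments per frame are independent Gaussians with variance
   `2 * D * dt`. Two mobile species (`D1 <= D2`, mixing fraction
   `frac_species1`) plus an immobile fraction are supported. Boundaries
   reflect; the field-edge filter removes the residual boundary artifacts,
   so no density is lost at the edges.
4. **Observation.** A molecule is detected in a frame if it is bound at
   that frame's midpoint; reported positions are the true positions plus
   Gaussian localization error `localization_sigma`. `render_movie()`
   optionally rasterizes detections as pixel-integrated 2D Gaussian PSFs
   with Poisson photon and background noise, producing 16-bit TIFF stacks
   that the detection module can consume.

Frame intervals of 0.052 s (19 fps) and 0.102 s (10 fps) are the two
acquisition settings the package defaults mirror; all dimensioned
parameters are in um, s and um^2/s.

All randomness flows through R's default Mersenne-Twister generator from
the single `seed` in `sim_config()`; sub-processes draw in a fixed,
documented order (arrival count, arrival times, dwell components, dwell
times, species labels, start positions and increments per molecule,
localization noise), so a fixed seed gives bit-identical output on any
platform.

**What the simulator does not emulate:** photophysics beyond a single
bleaching rate (no blinking, no green-to-red photoconversion kinetics),
EMCCD gain noise, drift, out-of-focus light, and any spatial
heterogeneity of the bilayer. Passing recovery tests therefore show that
the *analysis* is correct for data obeying its model, not that real
movies obey the model.

# Detection, linking and filtering

`detect_spots()` convolves each frame with a scale-normalized
Laplacian-of-Gaussian kernel (`sigma = radius / sqrt(2)` pixels, the
standard blob-radius relation), keeps 8-neighbour local maxima whose
response amplitude (the spot "quality") clears a user threshold, and
refines centers to sub-pixel precision with an intensity-weighted centroid
over a 5x5 window of the clipped response. On noiseless renders the
round-trip error is about 0.01 pixel; the quality threshold is a user
input that depends on the imaging conditions and has no universal
default.

`link_spots()` matches spots in consecutive frames by solving the optimal
bipartite assignment (a Jonker–Volgenant shortest-augmenting-path solver,
validated against permutation enumeration) on squared displacements, with
links beyond `max_link_distance` forbidden and an alternative "no link"
cost of `1.05 * gate^2`, the standard linear-assignment-problem
formulation of frame-to-frame tracking. The default gate of 0.5 um per
frame covers >99.9% of Brownian steps for `D <= 0.5 um^2/s` at ~50 ms
frames. There is no gap closing and no split/merge, so trajectories
occupy strictly consecutive frames; ties are broken by ascending spot
index, making linking fully deterministic.

`filter_trajectories()` applies the standard censoring and quality rules:
tracks beginning in the first frame or present in the last frame (their
dwell is cut by the movie limits), tracks with fewer than 3 detections,
immobilized tracks whose maximum displacement from their start stays
below 0.1 um, tracks entering a 1 um edge margin, and optionally tracks
exceeding a maximum duration (for removing singular extra-long tracks;
off by default). The displacement rule is interpreted as *maximum
displacement from the first position, in um* — the natural reading given
that step-size histograms use 0.01 um bins — and both the threshold and
the interpretation are exposed as parameters. Filtering is idempotent and
audited (per-rule removal counts).

# Dwell-time analysis

A track's dwell is `(detections - 1) * dt`. `build_survival()` evaluates
the empirical survival `S(t) = 1 - CDF` at the frame-grid edges
`0, dt, 2*dt, ...` (the frame interval is the bin size) and stores
`log10 S`, the scale on which such curves are plotted.

A convenient exactness property drives the whole recovery design: if
continuous dwells are quantized upward to the frame grid
(`ceiling(d/dt)*dt`), then at every grid edge `P(quantized dwell > k*dt)`
equals the *continuous* survival `alpha e^{-k dt/tau1} + (1-alpha)
e^{-k dt/tau2}`. Fitting the continuous model to the gridded survival
curve therefore introduces no discretization bias at any frame interval.

`fit_survival()` minimizes least squares against
`S(t) = alpha e^{-t/tau1} + (1 - alpha) e^{-t/tau2}` (or the order-1
special case) with box constraints (`tau > 0`, `alpha` in `[0, 1]`) using
Levenberg–Marquardt, from a moment-based start
(`tau1 = median/ln 2`, `tau2 = 5 tau1`, `alpha = 0.8`) plus three
deterministically jittered starts; the best of the converged starts wins.
After fitting, components are sorted so `tau1 <= tau2` and `alpha` always
names the fast fraction. Standard errors come from the Jacobian;
non-convergence returns an explicit failure object.

Two objectives are offered. The default fits the survival curve on the
**linear** scale; fitting `log10 S` instead (also available) weights the
sparse tail heavily — single tail molecules then dominate the loss. The
recovery suite runs on the default. Neither objective claims to replicate
any particular commercial implementation bit for bit, and published fits
of this kind rarely state their weighting.

Censoring is handled structurally, not statistically: the movie-limit
filters remove every track whose dwell the acquisition window truncates,
so the fitted sample is uncensored by construction. The cost is a bias
against dwells longer than the movie, which is a documented limitation
(and the reason extremely slow dissociators need longer acquisitions, not
a censored likelihood).

## Model-order selection

`select_model()` accepts the second exponential component only when both:

* a **likelihood-ratio test on the binned dwell counts** rejects the
  single-exponential model at `p < 0.01`. The statistic
  `G2 = 2(ll2 - ll1)` uses the multinomial likelihood of each *fitted*
  survival model on the per-frame counts, referred to chi-square with 2
  df. Because dwells are independent draws, this test is calibrated; the
  classical extra-sum-of-squares F-test computed on the survival-curve
  points is wildly anticonservative there (neighbouring curve values
  share molecules, so residuals are strongly serially correlated, and
  nominal F "p-values" below 1e-40 occur under the null). The F statistic
  is still reported as a diagnostic, but it does not drive the decision.
* the two-component fit is **non-degenerate**: `tau2/tau1 >= 2` and
  `alpha` in `[0.01, 0.99]`. This rejects refits of a single-exponential
  sample that park a ~0% component somewhere or split one time constant
  in two.

Measured on simulated data at `n = 10^4`, the rule picks order 1 for pure
exponentials and order 2 for well-separated mixtures in well over 95% of
replicates (the test suite re-measures both rates). Never more than two
components are considered.

`classify_transient()` reports the fraction of dwells below a threshold
(default 0.104 s = two frames at 52 ms). `per_cell_summary()` fits one
model per cell, tabulates cell-level time constants, and compares two
groups with the unpaired two-tailed pooled-variance Student's t-test.

# Diffusion analysis

`compute_steps()` pools lag-1 displacements (one fixed lag; multi-lag MSD
analysis is out of scope), `build_step_density()` histograms them in
0.01 um bins normalized to probability density, and `fit_step_density()`
fits the Rayleigh mixture
`f(r) = alpha r/(2 D1 tau) e^{-r^2/(4 D1 tau)} + (1-alpha) r/(2 D2 tau)
e^{-r^2/(4 D2 tau)}`
with the same constrained multi-start machinery (`D1 <= D2` after
sorting; `alpha` is the species-1 fraction). Zero-count bins enter the
fit with density 0, and the first bin is included. There is no immobile
term: immobilized particles are expected to have been removed by the
displacement filter. For a single species the closed form
`E[r] = sqrt(pi D tau)` links the mean step to the fitted coefficient and
is used as a consistency check.

Localization error inflates apparent diffusion: with independent noise
sigma on each coordinate of both endpoints, the expected squared step
grows from `4 D tau` to `4 D tau + 4 sigma^2`, so the apparent
coefficient is `D + sigma^2/tau` (the property test verifies this form
to 10%). Fits on real data therefore report *apparent* D unless sigma is
known and subtracted by the user.

# Association kinetics

`binding_frequency()` regresses the cumulative event count on event time
by ordinary least squares and divides the slope by the observation area;
`estimate_kon()` then regresses the per-area frequencies on concentration
with the **intercept fixed at zero**, because the binding frequency must
vanish at zero concentration; a free-intercept fit is retained as a
diagnostic for surface artifacts. With a single concentration the ratio
`frequency / concentration` is returned and flagged. kON is reported both
per uM and per nM (a factor of exactly 10^3), since both conventions are
common. When events are taken from tracked movies
(`events_from_trajectories()`), the movie-limit filters stay on but the
immobile-displacement filter is off by default: an immobile nonspecific
particle is still a binding event, and the choice is exposed as a flag.

The simulator's study conditions for kON recovery are a 1000 um^2
observation area and 100 s observation per stream — a field of view and
acquisition length typical of sCMOS/EMCCD TIRF at these magnifications —
with three technical replicates per concentration, matching the n >= 3
replicate convention of bulk single-molecule work; the imaging field used
for frequency normalization is a parameter, not a constant, since it is
instrument-specific.

# Bulk kinetics

`reaction_half_time()` smooths the trace with a centered moving average
(default width 5 samples; published analyses rarely state their
smoothing, so the width is a parameter), takes the initial and final 10%
of samples as plateau levels, and interpolates the earliest midpoint
crossing; multiple crossings are flagged and the first reported. The
half-time is measured from the first sample of the series (injection
offsets, if any, are the caller's bookkeeping). The estimate is invariant
to affine intensity rescaling. `fold_change()` divides the terminal
plateau (longest terminal window, at least 10% of the trace, whose linear
trend moves the signal by <2% of its range; fallback final 10% with a
warning) by a reference level. `lipid_density()` converts molar fraction
to lipids/um^2 on one leaflet via `fraction / (0.72e-6 um^2)`, the
standard 0.72 nm^2 DOPC footprint; the conversion is linear in the
fraction.

`simulate_bulk_trace()` provides a phenomenological Hill-shaped sigmoid
(default coefficient 4) for round-trip testing of these estimators. It is
deliberately *not* a mechanistic model of product-feedback lipid
phosphorylation kinetics — only a monotone curve with a controllable
half-time and plateau.

# Numerical choices

* All fits use `minpack.lm::nlsLM` (Levenberg–Marquardt with box
  constraints), 200 iterations max, four deterministic starts; the
  lowest-RSS converged start wins, with ties resolved toward the earlier
  start. No randomness enters any fit, so results are reproducible
  without seeding the analysis.
* Survival points with `S = 0` are excluded from fitting and from the
  log curve; a curve with no point strictly inside (0, 1) — e.g. from
  all-identical dwells — is flagged unfittable.
* Degenerate inputs are rejected with messages rather than propagated
  (`n < 1` molecules, nonpositive intervals, single-frame tracks, fewer
  than 10 dwells or 100 steps, unknown lipid species, flat traces).
* Assignment ties in linking are broken by ascending spot index; the LAP
  solver is exact, not greedy.
* Quantities of magnitude ~1e-12 use absolute guards (1e-9, 1e-12) only
  to absorb floating-point grid error, never to change a decision
  materially.

# Problem sizes and what the tests show

The recovery suites simulate at the sample sizes the fitted parameters
arise at in practice (about 15,000, 13,000 and 4,000 dwells; 10,000 to
30,000 displacement steps; hundreds to thousands of binding events per
concentration series) — sizes at which all fits run in well under a
second each. Property suites use 40–200 seeded replicates per claim.
Parameter recovery within a few percent at these sizes demonstrates
correctness of the estimators under the generative model; it cannot
certify detector linearity, labeling stoichiometry or bilayer quality in
any particular experiment.

# Known limitations

* No censored-likelihood dwell estimation and no bleaching correction:
  dwells approaching the acquisition length are excluded, not modeled.
* At most two mixture components for both dwell and diffusion fits; no
  hidden-Markov state switching.
* No gap closing in linking: a single missed detection splits a track,
  which shortens apparent dwells on noisy movies. Use detection
  thresholds with a margin of safety.
* Apparent diffusion coefficients include the localization-noise term
  `sigma^2/tau`.
* The bulk-trace simulator is phenomenological; fold-change and
  half-time estimators assume the trace actually reaches a plateau.
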