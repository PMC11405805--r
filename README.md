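# tirfkin

Simulation and analysis of **single-molecule TIRF membrane-binding
experiments** in R.

When a fluorescently labeled peripheral membrane protein is imaged on a
supported lipid bilayer (or a cell's plasma membrane) by TIRF microscopy,
each appearing/disappearing diffraction-limited spot is one molecule
binding to and releasing from the membrane. Three statistics summarize
the interaction:

* **Dwell times.** The time a molecule stays bound, modeled as an
  exponential mixture. The empirical survival `S(t) = 1 − CDF` of the
  dwell sample, built on the frame grid and plotted as `log10 S`, is fit
  to
  `S(t) = α e^(−t/τ₁) + (1 − α) e^(−t/τ₂)` with `τ₁ ≤ τ₂`,
  where `α` is the fraction of the fast-dissociating population (order 1
  is the single-exponential special case).
* **Step sizes.** Frame-to-frame displacements `r` of bound molecules,
  histogrammed in 0.01 µm bins as a probability density and fit to the
  two-species 2D Brownian (Rayleigh) mixture
  `f(r) = α · r/(2 D₁ τ) e^(−r²/4 D₁ τ) + (1 − α) · r/(2 D₂ τ) e^(−r²/4 D₂ τ)`.
* **Association rate constant.** Binding frequencies (cumulative events
  vs time slope, per µm²) regressed on solution concentration with zero
  intercept give `k_ON` in events/(µM·µm²·s).

The package provides the complete pipeline — spot detection
(Laplacian-of-Gaussian + sub-pixel refinement), linear-assignment
particle linking, the standard trajectory filters, survival and
step-size fitting with statistically calibrated model-order selection,
k_ON estimation, and bulk-recruitment summaries (fold change, reaction
half-time, lipid surface density) — **plus a ground-truthed simulator**
of the same generative process (Poisson arrivals, exponential-mixture
dwells with optional photobleaching censoring, two-species Brownian
diffusion, Gaussian-PSF movie rendering), so every fitted parameter can
be validated by parameter recovery. See the methods vignette
(`vignettes/tirfkin-methods.Rmd`) for the models, assumptions and design
choices.

## Worked example

Simulate 15,000 dwell times from a two-exponential mixture, quantize
them at 52 ms frames, and recover the generating parameters through the
survival-fit pipeline:

```r
library(tirfkin)

model <- binding_model(kon = 184, concentration = 5e-5,
                       alpha_fast = 0.95, tau_fast = 0.815,
                       tau_slow = 3.09)
set.seed(42)
dwells <- simulate_dwell_times(15000, model, frame_interval = 0.052)
curve  <- build_survival(dwells$quantized, frame_interval = 0.052)
sel    <- select_model(curve)        # likelihood-ratio order selection
sel$fit
#> <exp_mixture_fit> two exponentials: tau1 = 0.8102 s, tau2 = 2.758 s,
#>   alpha = 0.9382 (n = 15000)
classify_transient(dwells$quantized)   # fraction of dwells < 104 ms
#> [1] 0.0616
```

The selected order is 2 (the fast component dominates with `α ≈ 0.94`),
and the fitted time constants recover the generating 0.815 s / 3.09 s
within sampling error. The same round trip for the association rate
constant, from Poisson event streams at 10–50 pM with three replicate
streams per concentration:

```r
logs <- lapply(rep(c(10, 20, 30, 40, 50) * 1e-6, each = 3), function(C)
  simulate_arrivals(184, C, area = 1000, duration = 100))
estimate_kon(logs)
#> <kon_estimate> kON = 180 /(uM um^2 s) = 0.18 /(nM um^2 s)
#>   [SE 2.4, 15 concentrations]
```

Trajectory tables are exchanged as TrackMate-dialect CSV
(`TRACK_ID, POSITION_X, POSITION_Y, FRAME`), movies as 16-bit multi-page
TIFF, and ground truth / audits as JSON, so the package interoperates
with standard tracking tools.

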