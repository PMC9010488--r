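# crcestr

Creatine CEST (CrCEST) MRI analysis of skeletal-muscle oxidative capacity in
R.

## What it does, and for whom

Chemical exchange saturation transfer (CEST) MRI measures free creatine in
muscle: saturating the creatine amine protons at +1.8 ppm from water reduces
the water signal in proportion to creatine concentration. After a short
in-magnet plantar-flexion exercise, free creatine rises and then decays as
mitochondrial oxidative phosphorylation (OXPHOS) regenerates phosphocreatine.
The exponential time constant of that decay, τCr, is an index of
muscle-group-specific OXPHOS capacity — longer τCr means slower oxidative
recovery. This is the measurement used to study mitochondrial impairment in
conditions such as Friedreich's ataxia, muscle-by-muscle (lateral
gastrocnemius LG, medial gastrocnemius MG, soleus Sol).

`crcestr` is for imaging scientists and analysts working with (or validating
methods for) exercise-recovery CrCEST at 3 T. It implements the whole chain:

1. **Phantom generator** — synthetic acquisitions with known ground truth:
   three-muscle anatomy, a two-pool Lorentzian z-spectrum forward model,
   smooth B0/B1 inhomogeneity fields, exercise-driven creatine kinetics,
   and noise. Every downstream stage is testable by parameter recovery.
2. **z-spectrum processing** — per-voxel B0 mapping from a WASSR stack
   (maximum-symmetry centre search), symmetry-constrained resampling of the
   ±1.5/1.8/2.1 ppm offsets to the nominal ±1.8 ppm pair, B1 correction via
   a saturation-efficiency curve, and MTR asymmetry maps

   MTR_asym(%) = 100 · (S(−1.8 ppm) − S(+1.8 ppm)) / S(−1.8 ppm).

3. **Kinetics** — muscle-ROI time series; resting CrCEST (baseline mean);
   ΔCrCEST (first post-exercise value minus resting); τCr from a bounded
   least-squares fit of v(t) = asymptote + amp·e^(−t/τ) to the
   post-exercise frames, with plausibility filtering (τ < 24 s or
   τ > 1000 s excluded).
4. **Cohort statistics** — Shapiro–Wilk and Kruskal–Wallis tests,
   mixed-effects models with a per-subject random intercept, disease ×
   muscle interaction screens, per-muscle linear model suites, and a
   synthetic cohort generator for CI-coverage and power calibration.

Everything tabular flows as tibbles with `tidy()`/`glance()`/`autoplot()`
methods; volumetric data are plain arrays written as NIfTI with JSON
sidecars.

## Worked example

```r
library(crcestr)

cfg <- pipeline_config(protocol = list(matrix = 64),
                       phantom  = list(b0_amplitude_ppm = 0.15,
                                       b1_amplitude = 0.1),
                       seed = 42)
sim <- simulate_session(cfg)          # phantom acquisition, healthy-control kinetics
res <- process_session(sim, cfg)      # B0/B1 correction, MTR_asym, ROI fits
res$fits[, c("muscle", "resting_pct", "delta_pct", "tau_s", "status")]
#> # A tibble: 3 × 5
#>   muscle resting_pct delta_pct tau_s status
#>   <chr>        <dbl>     <dbl> <dbl> <chr>
#> 1 LG            6.20      8.90  138. ok
#> 2 MG            5.90      5.00  184. ok
#> 3 Sol           6.60      3.40  254. ok
```

The phantom injected LG resting CrCEST 6.2 %, ΔCrCEST 8.9 % and
τCr = 138 s (and the MG/Sol analogues); the pipeline recovers them through
0.15 ppm of B0 shim error and ±10 % B1 inhomogeneity. `autoplot()` on a ROI
series or fit draws the recovery curve.

Cohort layer on a synthetic study (22 controls, 10 patients):

```r
tab <- simulate_cohort(seed = 42)
m <- fit_mixed_model(tab, "resting_pct", model = 1)
m[m$term %in% c("diseaseFRDA", "muscleSol"),
  c("term", "estimate", "conf.low", "conf.high", "p.value")]
#> # A tibble: 2 × 5
#>   term        estimate conf.low conf.high p.value
#> 1 diseaseFRDA  -0.0991   -0.986     0.788 0.827
#> 2 muscleSol     0.695     0.221     1.17  0.00402
detect_interaction(tab, "tau_s")
#> [1] 0.0129
```

The soleus sits higher in resting CrCEST than the LG reference, there is no
disease effect on resting creatine, and the disease effect on τCr differs
between muscles — the pattern the generator was parameterised to carry.

A thin CLI wraps the same functions: `Rscript inst/cli/crcest.R
simulate|process|cohort ...` (see `--help`-style usage at the top of that
file).

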