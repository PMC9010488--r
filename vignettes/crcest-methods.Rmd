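---
title: "CrCEST exercise-recovery analysis: models, corrections and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CrCEST exercise-recovery analysis: models, corrections and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcestr)
```

This vignette is the package's account of its science: the forward model
behind the phantom, the correction and fitting procedures, the parameters
that matter and why their defaults are what they are, and what the synthetic
data do and do not establish about real scanner data.

## The measurement

Saturation pulses applied at the creatine amine resonance (+1.8 ppm from
water) transfer saturation to bulk water through chemical exchange, so the
water signal drops in proportion to free creatine. The contrast is the
magnetization-transfer-ratio asymmetry at the creatine offset,

$$\mathrm{MTR_{asym}}(\%) = 100\,\frac{S(-1.8\,\mathrm{ppm}) - S(+1.8\,\mathrm{ppm})}{S(-1.8\,\mathrm{ppm})},$$

computed per voxel and frame. A short in-magnet plantar-flexion bout raises
free creatine; its post-exercise decline is modelled as a single
exponential, and the time constant τCr indexes the muscle's oxidative
phosphorylation capacity. The protocol emulated by default: saturation
offsets ±1.5, ±1.8, ±2.1 ppm; 3 µT, 500 ms saturation; 128×128 matrix over
a 160 mm field of view; five baseline frames at 24 s temporal resolution,
two minutes of (un-imaged) exercise, then eight minutes of post-exercise
frames. Frame times are referenced to the end of exercise: baselines at
−120…−24 s, first post-exercise frame at t = 0.

## Two-pool forward model and phantom

The generator evaluates, per voxel and frame,

$$Z(\Delta\omega) = 1 - d_w L_{\Gamma_w}(\Delta\omega - b_0)
  - s(b_1)\,A\,L_{\Gamma_c}(\Delta\omega - b_0 - 1.8),$$

with $L_\Gamma(x) = \Gamma^2/(\Gamma^2 + x^2)$ a unit-amplitude Lorentzian,
clipped to [0, 1]. This is an analytic stand-in for the saturated
steady-state, not a Bloch–McConnell integration: it reproduces the features
the pipeline must handle (a broad direct-saturation water line, a symmetric
creatine line riding on it, field-dependent shifts and scalings) at
negligible cost, which is what parameter-recovery testing needs.
Pulse-level fidelity, relaxation and motion are out of scope.

Defaults, chosen once as field-plausible for 3 T and 3 µT/500 ms
saturation:

| parameter | default | meaning |
|---|---|---|
| `water_depth` $d_w$ | 0.85 | water line depth (Z = 0.15 at centre) |
| `water_width_ppm` $\Gamma_w$ | 1.0 | water HWHM under CEST-power saturation |
| `cr_width_ppm` $\Gamma_c$ | 0.8 | exchange-broadened creatine HWHM |
| `cr_center_ppm` | +1.8 | creatine amine offset |
| WASSR width / depth | 0.3 / 0.8 | low-power water line for B0 mapping |
| WASSR grid | ±1 ppm, 21 points | fine-offset sampling (not fixed by the emulated protocol; a documented default) |
| `noise_sd` | 0 (phantom default) | Gaussian sd as fraction of unsaturated signal |

B1 enters as a saturation-efficiency factor $s(b) = b^2/(b^2+1)$ normalised
so $s(1) = 1$ — monotone, bounded, invertible; the exact physics of the
B1 dependence is not the point, an invertible monotone curve is. Noise is
Gaussian, not Rician: at the simulated SNR (signal fractions 0.6–0.95,
noise sd ≤ 0.01) the distinction is negligible and Gaussian noise keeps the
residual-sd tests exact. B0 and relative-B1 fields are seeded low-order 2-D
polynomials scaled to a prescribed peak amplitude — smooth, shim-error-like
morphology.

The phantom's creatine amplitude is not set directly: `calibrate_cr_amplitude()`
inverts the asymmetry algebra exactly (including the creatine tail at
−1.8 ppm), so an injected "6.2 %" produces a measured asymmetry of 6.2 % to
machine precision under nominal fields. Muscle kinetics default to the
healthy-control cohort medians carried by `crcest_reference_medians()`
(LG 6.2 / 8.9 / 138 s; MG 5.9 / 5.0 / 184 s; Sol 6.6 / 3.4 / 254 s), with
the patient set available via `default_kinetics("FRDA")`.

## B0 mapping and offset correction

**WASSR centre search.** Each voxel's fine-offset spectrum is interpolated
with a monotone (Fritsch–Carlson) cubic — it cannot overshoot the sampled
dip — and the water centre $c$ minimises the reflection residual
$\sum_k (\hat Z(c+\delta_k) - \hat Z(c-\delta_k))^2$, coarse grid 0.01 ppm
then golden-section refinement to 10⁻³ ppm, search bounded to ±0.5 ppm.
Flat spectra (depth < 0.05) are flagged invalid. The tests check this
estimator against an independent dense grid-search oracle.

**Resampling to ±1.8 ppm.** Given the voxel's $b_0$, the acquired
±1.5/1.8/2.1 ppm points must be resampled so the pair sits at the nominal
creatine offsets. A plain per-side quadratic — the obvious choice — cannot
deliver the accuracy the rest of the pipeline holds itself to (0.1 %
absolute end-to-end): the residual of a parabola through three points of a
Lorentzian-shaped line reaches a few tenths of a percent in asymmetry
units at intermediate shifts — the same order as the effects of interest —
and simple transformed variants (reciprocal, log space) do not change that
order. The package therefore uses a symmetry-constrained, Lorentzian-aware
scheme built only from the six measured points and $b_0$:

* the **water line** is symmetric about $b_0$ and single-Lorentzian, so its
  reciprocal saturation $1/W$ is quadratic in offset; it is estimated from
  the *negative* (creatine-free) side and evaluated at the target radius
  1.8 ppm;
* the **creatine line** is symmetric about the evaluation offset itself, so
  its reciprocal is linear in the squared distance; its three positive-side
  samples determine the peak value $C(0)$ and the far-tail value $C(3.6)$;
* a short fixed-point loop absorbs the creatine far tail under the negative
  side, and the corrected pair is $S(\mp 1.8) = 1 - W(1.8) - C(3.6\,/\,0)$.

No generator pool parameters are assumed: widths and depths are implied per
voxel by the measured points. Ill-conditioned voxels (no creatine, heavy
noise) fall back to per-side reciprocal-quadratic interpolation, which is
exact for a single Lorentzian; voxels with $|b_0| < 10^{-6}$ ppm bypass
resampling. Voxels with $|b_0| > 0.3$ ppm (outside the acquired support)
are flagged and excluded from ROI averages, as are voxels whose reference
signal drops to $S(-1.8) \le 0.05$ (division instability) or whose relative
B1 leaves (0.5, 1.5).

**Denominator convention.** The asymmetry is normalised by $S(-\Delta\omega)$;
normalisation by the unsaturated signal is available as
`denominator = "s0"` and recorded in the output metadata. The contrast is
evaluated at the interpolated ±1.8 ppm pair only — the ±1.5/±2.1
acquisitions exist to make that resampling B0-robust.

**B1 correction** divides the measured asymmetry by the normalised
saturation-efficiency curve at the voxel's relative B1. The functional form
matches the generator's curve by construction; it is a documented,
swappable choice (`saturation_efficiency()`), which is the honest position
when the true B1 dependence is not being simulated at pulse level.

## Kinetics endpoints

Per muscle, the ROI series is the mean MTR_asym over unflagged voxels per
frame; frames with no unflagged voxels are dropped and logged, and fits
simply omit them. Resting CrCEST is the arithmetic mean of the baseline
frames. ΔCrCEST is the value at the *first* post-exercise frame minus
resting — if QC dropped that frame, the pipeline errors rather than
substituting a later one, since the endpoint would silently change meaning.

τCr comes from bounded least squares (Levenberg–Marquardt via
`minpack.lm`) of $v(t) = \text{asymptote} + \text{amp}\cdot e^{-t/\tau}$ on
the post-exercise frames only; baselines inform resting/Δ, not the decay.
Initialisation: asymptote from the mean of the last three frames, amplitude
from the first post-exercise value minus that, τ from a log-linear
regression of the positive residuals; τ is bounded to [1, 5000] s. The
asymptote is a free parameter by default — creatine need not return exactly
to baseline within the 480 s window — with `pin_asymptote=` available to
fix it. The first post-exercise point is included in the fit (it is also
the ΔCrCEST definition point; including it uses all information and the
noiseless recovery tests confirm it introduces no bias). Fits are
unweighted by default; per-frame voxel-count weighting is a switch.
Non-convergence or a non-positive fitted amplitude yields
`status = "fit_failed"` with a diagnostic message.

The plausibility filter is applied *after* fitting, not as fit constraints,
so excluded values remain reportable: τ below one inter-scan interval
(24 s) cannot be resolved at the temporal resolution, and τ above 1000 s —
beyond the post-exercise window — indicates an insufficient exercise
response. The filter is idempotent and leaves retained fits untouched.

## Cohort statistics

The statistical layer mirrors a two-group observational study design:
Shapiro–Wilk for normality, two-group Kruskal–Wallis for univariate
comparisons, and linear mixed-effects models with a per-subject random
intercept (REML, `lme4`) for the adjusted analyses. Resting CrCEST models
1–4 adjust for age, sex, disease status and muscle (LG reference) plus,
per model, BMI or height with leg lean or fat mass. For ΔCrCEST and τCr
the mixed model is a disease × muscle interaction screen (likelihood-ratio
test of the interaction block, ML); when the interaction is present,
per-muscle ordinary least-squares suites follow (Δ: + total physical
activity, + waist circumference; τ: + ΔCrCEST and resting CrCEST, + total
physical activity). τ models use only `status == "ok"` rows, mirroring the
exclusion accounting. Fixed-effect p-values and CIs use the Wald z
approximation — the degrees-of-freedom method behind published tables of
this kind is rarely stated, so the package picks the simplest documented
convention and isolates it in one helper so a Satterthwaite or
Kenward–Roger variant can be swapped in. No multiple-testing adjustment is
applied; significance is two-sided p < 0.05 throughout. Rank-deficient
designs and singular random-effect fits raise classed warnings rather than
failing silently.

### The synthetic cohort generator

`simulate_cohort()` produces one row per subject × muscle with outcomes
centred on the per-(group, muscle) medians and spreads reproducing the
interquartile intervals of `crcest_reference_medians()`. τCr and ΔCrCEST
are generated log-normally (positive, right-skewed, matching the observed
IQI asymmetry; the log-sd is `log(q75/q25)/1.349`); resting CrCEST is
normal. A subject-level random intercept induces correlation across a
subject's three muscles with intraclass correlation `icc = 0.65`. The ICC
is not derivable from printed marginal summaries; 0.6–0.8 is the range
reported for test–retest and within-subject correlation of muscle
metabolic indices, and the three calf muscles share the exercise bout,
perfusion and subject physiology, so a value in the middle of that band is
the realistic choice — it is also the regime consistent with a
muscle-specific disease contrast of the observed size being detectable at
n = 32, as the power checks require. Covariates (age, sex, BMI, waist,
activity, height, leg masses) follow the published group summaries where
printed and plausible adult values otherwise.

Calibration properties verified by the acceptance suite: on null cohorts
(patient medians replaced by control medians) the 95 % Wald CI for the
disease coefficient covers zero at nominal rate (95 % ± 3 % over 500
replicates), and the τ interaction screen detects the observed LG/Sol
median gaps in ≥ 80 % of replicates at n = 32.

## What passing tests do and do not show

The phantom exercises every pipeline stage with known truth: smooth fields,
exact exponential kinetics, Gaussian noise, perfect segmentations. Passing
means the implementation is correct and the corrections are accurate under
those conditions. It does not establish robustness to what the generator
does not emulate: motion, segmentation variability (inter-observer CV for
calf-muscle tracing is substantial), Rician noise at low SNR, pH effects on
the CEST signal, magnetization-transfer background, partial-volume mixing
at muscle boundaries, or non-exponential recovery. Conclusions about real
scanner data need those effects addressed separately.

## Numerical choices and problem sizes

Degenerate inputs are errors, not guesses: fewer baseline frames than the
protocol promises, a missing first post-exercise frame, < 4 post-exercise
frames, empty muscle labels, constant input to the normality test, and
lo ≥ hi plausibility bounds all raise classed conditions. Ties in the
coarse WASSR grid resolve to the first minimum and are then refined;
`optimize()` tolerance is 10⁻⁴ ppm.

The test and acceptance runs use sizes chosen to make the checks sharp but
quick: 128² phantoms with 5 baseline + 5 post-exercise frames for the
end-to-end field-correction recoveries, full 25-frame protocols for
kinetics, 200 noisy series for τ recovery, 500 replicates for CI coverage
and 100 for interaction power. The acceptance script completes in a few
seconds; the full test suite in about a minute.

## Known limitations

Single-slice, voxel-index geometry (no world affine); the B1-correction
curve is generator-matched rather than physically derived; the forward
model is analytic two-pool (no relaxation, no MT pool, no pulse shape);
the anterior compartment is out of scope; and the per-muscle linear suites
assume the interaction screen has already justified stratification.
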