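---
title: "Calibration and uncertainty model of the LDR fluorescence reader"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration and uncertainty model of the LDR fluorescence reader}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ldrquant)
```

## The measurement chain

The reader detects on-paper fluorescence with a cadmium-sulfide light
dependent resistor (LDR) whose resistance follows a power law in the incident
light intensity,

$$R = A \, I^{-\gamma},$$

where $\gamma$ is a device-specific exponent (of order 1, but different even
between LDRs of one part number). The LDR sits in a voltage divider against a
reference resistor $R_\mathrm{ref}$ (750 kΩ by default, half the dark
resistance, which maximises the usable dynamic range), and a 10-bit ADC reads
the divider voltage $U$ in integer counts from 0 to $U_0 = 1023$. Inverting
the divider gives

$$R = R_\mathrm{ref}\left(\frac{U_0}{U} - 1\right),$$

implemented by `counts_to_resistance()`. One *data point* of the device is
the aggregate of 50 reads taken at 50 ms intervals (`aggregate_readings()`:
mean, SEM with the $n-1$ sample variance, $n$), after 30 s of LED warm-up so
that the LDR — which responds to light changes over several seconds — has
equilibrated. With ~1% per-read noise the 50-read average keeps the relative
statistical uncertainty of the count reading below 0.2%, the design bound of
the acquisition protocol. Aggregation converts each read to resistance
*before* averaging; the alternative (average counts, then convert) differs
only at second order, and the per-read noise model lives naturally in the
resistance domain.

## Calibration model

Fluorescence emitted by the sample adds light linearly in the fluorophore
concentration $c$ on top of the blank background,
$I(c) = I_b \,(1 + k c)$. Anchoring the power law at the blank
($I = I_b \mapsto R_b$) makes the proportionality constant drop out and
yields the two-parameter calibration function

$$\frac{R(c)}{R_b} = (1 + k c)^{-\gamma},$$

with $k$ (per nM) capturing the spectral overlap of LED, filter foils,
fluorophore and sensor as well as scattering by the paper — but not the
excitation intensity — and $\gamma$ the LDR exponent. `calibration_model()`
evaluates it, `invert_calibration()` applies the algebraic inverse
$c = ((R/R_b)^{-1/\gamma} - 1)/k$. Resistances above the blank would map to
negative concentrations; they are clipped to zero and flagged rather than
hidden, because a drifting blank is diagnostic information.

The blank is a *wet* blank (water on the paper): wet and dry paper scatter
differently, so a dry blank would bias $R_b$.

## Fitting a dilution series

A calibration run follows the automated routine
blank–blank–(1 nM)–(1 nM)–(2 nM)–(2 nM)–…–blank–blank per replicate, on a
1–2–5 decade ladder from 1 nM to 10 µM (`calibration_ladder()`), in
triplicate. Each sample is measured twice in direct succession to confirm
LDR equilibration; both measurements are retained as observations.
`relative_resistance()` pools *all* blank measurements into
$R_b \pm \delta R_b$ (mean and SEM) and propagates, to first order,

$$\delta\!\left(\frac{R}{R_b}\right) = \frac{R}{R_b}
\sqrt{\left(\frac{\delta R}{R}\right)^2 +
      \left(\frac{\delta R_b}{R_b}\right)^2}.$$

`ldr_calibrate()` then fits $(k, \gamma)$ by nonlinear least squares with
inverse-variance weights $1/\delta^2$ (Levenberg–Marquardt via
**minpack.lm**, which also handles the exactly-zero-residual synthetic
case). Reported standard errors are the asymptotic errors scaled by
$\sqrt{\chi^2_\mathrm{red}}$ — the convention of common fitting tools — so
scatter beyond the per-point SEMs (sample-to-sample paper variability, in
practice the dominant effect) inflates the errors honestly. Starting values
are $\gamma = 1$ and $k$ from the slope of
$\log(R/R_b) \approx -\gamma k c$ over the three smallest concentrations;
the fit is insensitive to them in all tested conditions. Zero per-point
uncertainties trigger an unweighted fall-back with a warning.

Two estimator properties are worth knowing:

* **Weight-scale invariance.** Multiplying all uncertainties by a common
  factor leaves the estimates unchanged (only $\chi^2_\mathrm{red}$ moves).
* **Blank-normalisation bias.** Because every ratio shares the *estimated*
  $R_b$, a per-run error in $\hat R_b$ acts as a common scale factor on the
  whole curve. The model is pinned to 1 at $c = 0$, so a low blank is
  absorbed by a larger $k$ while a high blank cannot be absorbed
  symmetrically; at realistic blank scatter (~5% between samples) this
  biases $\hat k$ upward by a few percent — comparable to one asymptotic
  standard error at the default design. The package's simulation tests
  measure exactly this. More blank measurements shrink the bias
  quadratically faster than the SE, so calibration runs should not skimp on
  blanks.

## Uncertainty budget and confident range

`concentration_uncertainty()` propagates five independent one-sigma sources
through the divider equation and the inverted calibration:
the one-digit ADC accuracy of the divider reading $\delta U_\mathrm{LDR}$
and of the supply reading $\delta U_0$ (each 1 count, treated as a standard
deviation following the instrument's "1 digit" accuracy statement), the
blank uncertainty $\delta R_b$, and the fit errors $\delta k$,
$\delta\gamma$. With $y = 1 + kc$,

$$\left|\frac{\partial c}{\partial R}\right| =
  \frac{y^{1+\gamma}}{k\gamma R_b},\qquad
\left|\frac{\partial c}{\partial R_b}\right| = \frac{y}{k\gamma R_b},\qquad
\left|\frac{\partial c}{\partial k}\right| = \frac{c}{k},\qquad
\left|\frac{\partial c}{\partial \gamma}\right| =
  \frac{y\ln y}{k\gamma},$$

and the digit errors enter through
$|\partial R/\partial U| = R_\mathrm{ref}U_0/U^2$,
$|\partial R/\partial U_0| = R_\mathrm{ref}/U$. The total is the root sum of
squares; the returned budget keeps the per-source contributions so the
dominant error is visible at a glance. The resulting relative uncertainty
$\delta c / c$ is U-shaped: toward the blank the absolute floor set by
$\delta R_b$ and the ADC digit dominates a vanishing $c$; at high
concentration the divider saturates and the $\delta\gamma$, $\delta k$ and
digit terms grow.

The first-order budget is validated against brute-force Monte-Carlo
propagation (`mc_concentration_uncertainty()`, $10^5$ Gaussian draws pushed
through the exact chain); the test suite requires 5% agreement at 10, 100
and 1000 nM. Note that the *endpoints* of any interval derived from such a
budget depend on the exact closed form chosen — which derivative terms are
retained, whether parameter correlations are included, SEM versus SD for the
blank. This package deliberately uses the transparent uncorrelated
first-order form above, states it fully, and checks it against Monte-Carlo
rather than against any particular closed-form variant.

`confident_range()` returns the contiguous interval where
$\delta c/c \le$ 15% (the conventional threshold for this device class;
tunable). It evaluates the budget on a 2000-point logarithmic grid over
$[10^{-2}, 10^{6}]$ nM, keeps the run containing the curve's minimum, and
refines both crossings by bisection on $\log c$ to about three significant
digits. An empty interval is an explicit result, not an error. The range is
antitone in every uncertainty input: inflating any source can only shrink
it.

## Detection limits

`detection_limits()` applies the IUPAC convention: the limit of detection is
the blank level shifted by $3\sigma$ of the blank measurements, the limit of
quantification by $10\sigma$. Because fluorescence *lowers* the resistance,
the thresholds lie below the blank:

$$\mathrm{LOD}_R = R_b - 3\sigma,\qquad \mathrm{LOQ}_R = R_b - 10\sigma,$$

each converted to concentration through the calibration inverse. $\sigma$ is
the sample SD of the blank mean-resistances; when only $(R_b \pm
\mathrm{SEM}, N)$ is available it is reconstructed as
$\sigma = \mathrm{SEM}\cdot\sqrt{N}$. At the package's reference fluorescein
calibration ($R_b = 1650 \pm 22$ kΩ over $N = 18$ blanks, $k = 0.0283$ /nM,
$\gamma = 1.054$) this places the LOD near 1370 kΩ ≈ 6.8 nM and the LOQ
near 717 kΩ ≈ 43 nM, as the worked example in the README shows.

## The simulator

`simulator_config()` + `simulate_reading()` / `simulate_dilution_series()` /
`simulate_assay_trace()` generate synthetic data with the statistical
structure the analysis assumes, so every stage is testable without hardware:

1. intensity $I = (1 + kc)\cdot f$, with a per-sample factor
   $f = e^{\varepsilon}$, $\varepsilon \sim N(0, 0.05)$ representing
   pipetting and paper-placement variability — the 5% default is set from
   the observed blank-to-blank resistance scatter of the reference device
   (≈5.7% in resistance, i.e. ≈5.4% in intensity at $\gamma \approx 1.05$);
2. target resistance $R = R_b I^{-\gamma}$ (blank-anchored power law, so the
   calibration function emerges exactly by construction);
3. first-order equilibration from the dark resistance with time constant
   3 s (equilibrium well within ~10 s), sampled at the read times after the
   30 s warm-up;
4. ideal counts from the divider inverse, multiplied by per-read Gaussian
   noise of 1% relative — chosen so the aggregated 50-read count SEM
   respects the 0.2% design bound — then rounded to integers and clipped to
   $[1, 1023]$ (quantization can be disabled to test exact limits).

Duplicate successive measurements re-measure the *same* physical sample:
they share the sample draw $f$ and differ only in read noise. Time traces
run on one sample throughout, so a single $f$ applies to the whole trace.
Identical seed and configuration give bit-identical output, and seeded calls
restore the caller's RNG state.

Assay traces emulate two on-paper chemistries at the concentration level
(not mechanistically): transcription of a fluorogenic aptamer as a
saturating rise $c(t) = A(1 - e^{-\lambda t})$ whose initial rate scales
with the DNA template, and a collateral-cleavage nucleic-acid assay with the
same form — fast $\lambda$ (default 0.05/min) for a cognate target, slow
background $\lambda$ (0.002/min) for a non-cognate one. What passing tests
on these traces show is that the *quantification chain* resolves the
designed kinetics; they say nothing about real enzyme kinetics, paper
chemistry, temperature drift, or photobleaching, none of which the simulator
models.

## Numerical and design choices

* ADC conversions operate on real-valued counts; quantization is applied
  only where it physically happens (the simulator). This keeps the analysis
  code exact and testable.
* A count of 0 (total darkness) raises an error instead of returning an
  infinite resistance: the divider cannot report it meaningfully.
* The divider equation is used as printed for the device, without a
  correction for the microcontroller's 100 MΩ input impedance; at
  megohm-scale LDR resistances the correction is below the digit accuracy.
* The range solver's domain $[10^{-2}, 10^{6}]$ nM comfortably brackets any
  physically measurable range of the device; 2000 grid points put adjacent
  points ~0.9% apart, and bisection then reaches three significant digits.
* Degenerate inputs are explicit: identical blanks give $\sigma = 0$ and a
  degenerate-limits warning; an unattainable threshold gives an empty range;
  thresholds below the divider's floor give an infinite concentration limit.
* `quantify_timetrace()` combines the systematic budget with the per-point
  statistical SEM in quadrature and assigns LOD/LOQ flags in *resistance*
  space, where they remain well-defined for points at or above the blank.
* The contamination check of `run_calibration_workflow()` compares trailing
  against leading blanks at $3\times$ the leading-blank SD; with `strict =
  TRUE` it aborts (exit code 3 in the CLI) instead of warning.

## Problem sizes used in the tests

The packaged simulation studies use the design of the reference calibration:
13-concentration ladder, 3 replicates, duplicate reads, 50 reads per point;
parameter-recovery studies run 20 seeded series, Monte-Carlo validation uses
$10^5$ draws, and coverage properties use 200–1000 seeded repetitions. These
sizes give sub-percent Monte-Carlo error on every asserted quantity while
keeping the whole suite fast.

## Known limitations

* The error budget is first-order and uncorrelated: the $k$–$\gamma$
  covariance of the fit is available (`vcov()`) but deliberately not folded
  into the default budget, and strongly non-Gaussian regimes (counts near
  the ADC rails) are outside its validity.
* The calibration assumes intensity linear in concentration; inner-filter
  effects at very high fluorophore concentrations break this upstream of
  anything the package can detect.
* The simulator's noise model (log-normal sample factor, Gaussian read
  noise) is a stylised stand-in for real paper/optics variability; it
  reproduces observed blank scatter and read-noise magnitudes, not their
  physical mechanisms.
* Blank-normalisation bias (above) is a property of the measurement
  protocol itself; the package measures and documents it rather than
  correcting it.
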