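---
title: "EDTA-aware QC and blood ionome quantification from 1D 1H NMR: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EDTA-aware QC and blood ionome quantification from 1D 1H NMR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plasma is usually collected into EDTA tubes. EDTA chelates the divalent
cations of blood -- essentially all Ca^2+^ and Mg^2+^ and the much
scarcer Zn^2+^ -- and both the free ligand and each metal complex give
intense, sharp ^1^H signals in the 2.5--3.7 ppm region of serum/plasma
spectra. For untargeted metabolomics these signals are contamination;
for clinical chemistry they are information, because each complex's
integral is proportional to the concentration of its metal ion. `edtaqc`
implements both readings: it finds and deconvolutes every EDTA-related
spin system automatically, converts the integrals into absolute
Ca^2+^/Mg^2+^/Zn^2+^ concentrations with a field-independent
calibration, and can then excise the EDTA signals and reconstruct the
baseline so the spectrum is ready for multivariate analysis.

Everything is exercisable without real data: a first-class synthetic
generator renders serum/plasma-EDTA-like spectra with full ground truth.

## Chained chemical-shift prediction and anchored assignment

Chemical shifts in blood are not constants; they drift with the
physicochemical state of the sample (ionic strength, pH, protein
content), and they drift *together*. The assignment engine exploits
this: linear models `delta_response = a * delta_predictor + b` are
trained across a cohort and applied as a chain, each step anchored on a
peak that has just been observed, not merely predicted:

1. the glucose anomeric doublet is located by a J-coupling-constrained
   pair search on a derivative-enhanced trace (sharp peaks are amplified
   relative to broad macromolecule background, so the anchor search
   ignores the baseline);
2. glucose predicts the free-EDTA singlets and the Ca--EDTA AB quartet
   (model A); the quartet predicts the Ca--EDTA singlet (model B); the
   Ca singlet predicts the Mg singlet (model C); glucose predicts both
   Zn--EDTA systems (models D) and the asparagine CH~2~ multiplet.

Within each search window the assigned position is the qualifying local
maximum (3 sigma above a background interpolated from flanking
segments) nearest to the prediction, refined by 3-point parabolic
interpolation. Multiplets are searched at their strongest line -- the
center of an AB quartet is a trough, not a peak -- and the fixed Hz
offset of that line is removed to recover the system center. Lines
already attributed to an earlier species in the chain are excluded from
later searches (a candidate within half a line width of an assigned
asparagine line is not a Zn-EDTA peak); this is why asparagine is
assigned before the Zn systems, and why a strongly merged Zn singlet is
reported `below_detection` rather than mis-assigned.

Numerical choices that matter here:

* **Window width.** The half-width is `min(max(5 * rRMSE, 0.5 * LW),
  0.95 * LW)` where LW is the line width (FWHM) measured on the
  free-EDTA reference singlet of the current spectrum. Five model-sigmas
  make missing a present peak vanishingly rare, while the total window
  stays below two line widths so a neighbor cannot be captured. A
  narrower rRMSE-sized window is statistically guaranteed to miss a few
  peaks per hundred spectra, which contradicts the validation target of
  assigning every system in every spectrum.
* **Fallback.** If the primary window contains no qualifying maximum
  (the Ca singlet obscured, say), the glucose-anchored fallback model is
  applied with a 2.5-line-width window and the result is flagged
  `fallback_assigned`. Failures are statuses, never errors; a species
  with no peak is reported `below_detection`.
* **"Line width"** is operationalized as the measured FWHM of the
  free-EDTA reference singlet, falling back to 1.5 Hz / field; the
  reference peak is always present in an EDTA sample.

## Template-constrained Voigt deconvolution

Each species is a `spin_system` template: component offsets in Hz (so
patterns scale correctly with field), relative areas summing to one, and
a proton count. Fitting is local nonlinear least squares
(`minpack.lm::nls.lm`) over the template span plus three line widths,
with exactly five free parameters: total area (bounded at zero), a
center shift bounded by half a line width (assignment already localized
the system; the bound prevents peak stealing), one shared width scale,
and a local linear baseline. Component ratios are therefore preserved
exactly. The Voigt profile is evaluated through the real part of the
Faddeeva function (Weideman's rational approximation, order 32),
validated in the test suite against a brute-force Gaussian-Lorentzian
convolution; pure limits use the closed forms.

The package-wide lineshape convention assigns one third of the FWHM to
the Lorentzian component (`voigt_widths_from_fwhm()`); generator and
fitter share it, so the only shape freedom during fitting is the width
scale. Integral uncertainty is a white-noise propagation of the fit
residuals, `rms * sqrt(region_width * point_spacing)` -- deliberately
conservative.

The Zn--EDTA singlet overlaps the asparagine CH~2~
doublet-of-doublets. Before the Zn fits, the asparagine template is
fitted (with the predicted Zn window *masked* from its residual, so the
foreign peak cannot inflate the asparagine area) and its fitted peaks --
not the baseline -- are subtracted. The AB quartets are modeled as four
Voigt components with roof-effect intensities computed from the
configured J and delta-nu; quartet and singlet of one complex are fitted
separately, sharing only the assignment.

## Sensitivity-normalized universal calibration

Integrals from different spectrometers live on arbitrary intensity
scales. Three quantities harmonize them:

* instrument sensitivity `S_f = Int_EDTA,peak1,f / sigma_f`, the
  reference free-EDTA peak integral over the spectral noise (the sd of
  the signal-free 13.0--14.0 ppm region);
* the normalized integral
  `I_norm = (Int_M / Int_EDTA,peak1,f) * (S_ref / S_f)`;
* one calibration line per ion, `C_M = a_M * I_norm + b_M`, fitted on
  standards and applied regardless of field.

`Int_EDTA,peak1,f` is measured once per spectrometer on a metal-free
EDTA reference acquisition (`synth_reference()` /
`measure_field_reference()`); the downfield free-EDTA singlet is the
reference peak. Normalizing by the *in-sample* free-EDTA integral would
make `I_norm` nonlinear in `C_M` (free EDTA is total minus the chelated
pools, which vary per sample) and caps the achievable agreement with
truth well below what the method demonstrably reaches. `S_f` is computed
per spectrum, pairing the per-field reference integral with the
*current* spectrum's noise: noise-level fluctuations then enter as
per-sample scatter -- visible in the calibration's small non-zero
intercept, whose 95% CI is reported together with a
passes-through-origin flag -- rather than as a per-spectrometer bias.

The sensitivity ratio corrects residual scale differences between
instruments; it is exactly field-invariant when the spectrometers
operate at matched sensitivity, which is what standardized acquisition
protocols aim for and how the synthetic instruments are configured (see
below). Detection limits use the ICH-style convention on this
parameterization, `LOD = 3.3 * blank_sd * a_M` and
`LOQ = 10 * blank_sd * a_M`; spike recovery is
`100 * (spiked - base) / added`. Cross-cohort agreement is tested with
an extra-sum-of-squares F-test of regression coincidence, either
between two fitted lines or against the fixed 1:1 line.

For the EDTA mass-balance check a pooled per-proton curve (concentration
against normalized integral per proton, pooled over the three ions'
singlets) converts any EDTA species -- including free EDTA -- into mM, so
that free + Ca + Mg + Zn complexes can be compared with the total EDTA
dispensed into the tube (2.8 mmol/L for a 5.649 mM buffer diluted 1:1).

## Signal removal and QC analytics

`remove_edta_signals()` excises either the free-EDTA singlets alone or
all EDTA-related systems. Each targeted system's region (components
plus three line widths) is replaced by a smooth monotone cubic through
baseline anchors -- medians of 0.01 ppm windows flanking the region.
Points outside removed regions are bit-identical to the input, and a
second pass finds nothing above three sigma (idempotence). A target
whose region overlaps a fitted non-target system (the Zn singlet inside
the asparagine multiplet) is removed by subtracting its fitted model
instead, flagged in the report, so the co-resonating metabolite
survives. Noise re-injection into reconstructed regions is available
behind a flag and off by default: cleaned spectra are smooth there, and
whether downstream statistics prefer re-noised regions is a user
decision, not a package one.

The QC analytics are deliberately plain: 0.02 ppm binning with
mean-centering, PCA by SVD (scores, loadings, percent explained
variance), and feature-wise Pearson correlation against an external
target (binned by default, full-resolution optional). The
region-chopping comparator used in the fidelity analysis zero-fills the
same regions the cleaner reconstructs -- the automatable stand-in for
manual region exclusion.

## What the synthetic generator emulates

`generate_spectrum()` renders, on a 32,768-point grid over -0.5 to
14.5 ppm (a desk-scale stand-in for 98k-point production acquisitions),

* Voigt multiplets for: glucose anomeric doublet (J = 3.8 Hz), two
  free-EDTA singlets (3.60 / 3.17 ppm; acetate and ethylenic protons,
  8 and 4 H), Ca--EDTA singlet (2.55) + acetate AB quartet (3.08,
  J = 16 Hz, delta-nu = 12 Hz), Mg--EDTA singlet (2.70), Zn--EDTA
  singlet (2.88) + quartet (3.30), and the asparagine CH~2~
  doublet-of-doublets (2.90, two protons, J = 16.9 / 7.0 / 4.3 Hz).
  The Zn singlet is deliberately placed inside the asparagine span to
  reproduce the overlap that makes Zn the hard case. Default centers
  are template entries, not contracts -- only the relative geometry
  matters;
* areas proportional to concentration x proton count x a spectrometer
  response that scales as field^1.5^;
* a latent per-sample condition variable u in [-1, 1] that displaces
  every center by a species-specific slope (0.003--0.006 ppm per unit),
  plus 3 x 10^-4^ ppm independent jitter -- this induces the
  inter-species shift covariation the prediction models are trained on;
* a broad macromolecule baseline (three Gaussians at 1.5 / 3.0 /
  3.8 ppm, sd 0.5--0.8 ppm, amplitudes varying 20% sample to sample);
* white Gaussian noise. The `snr` setting is referenced to the apex of
  the Zn--EDTA singlet at 6 uM -- the weakest species the pipeline
  quantifies -- evaluated at the 500.13 MHz lineshape, so noise scales
  with the spectrometer response and the virtual 500 and 600 MHz
  instruments operate at matched sensitivity, as multicenter protocols
  intend. The implied free-EDTA peak SNR is of order 10^4^, typical of
  cryoprobe serum spectra.

Concentrations are in-tube values (after the 1:1 dilution with EDTA
buffer): total EDTA 2.8 mM; cohort draws span physiological blood
ranges halved by dilution (Ca 1.0--1.4 mM, Mg 0.35--0.55 mM, Zn 3--9 uM,
glucose 2--3 mM, asparagine 20--60 uM), with a 6% fraction of samples
given zero zinc to emulate the minority of real samples whose Zn signal
is below detection. Line width defaults to 1.5 Hz FWHM. One master seed
derives per-sample seeds deterministically.

What it does *not* emulate -- and hence what passing tests do not show
about real data: strong coupling beyond the AB approximation, residual
water and urea artifacts, lipoprotein lineshape structure, pH-driven
*nonlinear* shift behavior, field inhomogeneity (shim) variation, and
chemical-exchange broadening. The delta covariation is exactly linear
by construction, so the shift models' R^2 on synthetic cohorts
(~0.98) mirrors the design, not an empirical discovery.

## Problem sizes and runtime choices

The validation analyses run at deliberately modest sizes: shift models
trained on 60 synthetic spectra; calibration from 8 standards per ion;
parameter recovery on 40-sample cohorts; assignment validation on 100
spectra; cross-field coincidence over 50 seeds with 6 compositions
each; cleaning fidelity on 16-sample matched cohorts. These sizes give
stable statistics in minutes on a single CPU while exercising every
code path.

## Known limitations

* The shift models shipped by `train_shift_models()` are trained on
  synthetic cohorts; for real data, train on an assigned cohort and
  load the JSON model store.
* Quantification uses each complex's singlet only; the quartets serve
  assignment and removal.
* The calibration assumes the metal-free EDTA reference and the samples
  are acquired under one protocol per spectrometer; a changed receiver
  gain is normalized away at load, but a changed scan count is not.
* Asparagine is the only co-resonating metabolite that is explicitly
  modeled; other overlaps are absorbed by the local linear baseline of
  each fit, which is adequate for sparse overlap but not for a crowded
  region.
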