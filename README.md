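# edtaqc

EDTA-aware quality control and blood ionome quantification from routine
1D ¹H NMR spectra of serum and plasma.

Plasma collected in EDTA tubes shows intense ¹H signals from free EDTA
and its Ca-, Mg- and Zn-EDTA complexes throughout the 2.5–3.7 ppm
region. They obscure endogenous metabolites — but each complex's
integral is proportional to its metal ion's concentration. `edtaqc`
turns this interference into a measurement and then removes it:

* **Automated assignment.** Chained linear chemical-shift models,
  anchored on the glucose anomeric doublet (located via a
  J-coupling-constrained search on a derivative-enhanced trace),
  predict and assign every free-EDTA and metal-EDTA spin system inside
  sub-2-line-width windows, with a wide-window glucose-anchored
  fallback when a primary model underperforms.
* **Voigt deconvolution.** Template-constrained fits (fixed multiplet
  geometry and ratios; free area, bounded shift, shared width scale,
  local linear baseline) extract integrals with residual-based
  uncertainties. The asparagine CH₂ multiplet is fitted and subtracted
  before the overlapping Zn-EDTA singlet is quantified.
* **Absolute quantification across spectrometers.** Instrument
  sensitivity S_f = Int_EDTA,peak1,f / σ_f (reference free-EDTA
  integral over spectral noise) and normalized integrals
  I^norm = (Int_M / Int_EDTA,peak1,f) · (S_ref / S_f) feed one
  universal calibration per ion, C_M = a_M·I^norm + b_M, valid at 500
  and 600 MHz alike; LOD/LOQ, spike recovery and a regression-
  coincidence F-test complete the analytical validation toolkit.
* **Smart cleanup.** Free-EDTA-only or all-EDTA signal removal with
  smooth baseline reconstruction (model subtraction where a target
  overlaps a genuine metabolite), plus binning/PCA and feature-wise
  correlation analytics for QC.
* **Synthetic ground truth.** A generator renders serum/plasma-EDTA-like
  spectra — multiplet fingerprints, latent-variable shift covariation,
  macromolecule baseline, noise — so the whole pipeline is testable
  without real cohorts. Bruker processed-data directories, JCAMP-DX and
  two-column text spectra are supported for real data.

## Worked example

```r
library(edtaqc)

# study setup: shift models, per-field reference, calibration standards
models <- train_shift_models(60, seed = 1)
ref    <- measure_field_reference(synth_reference(seed = 2)$spectrum)
cal    <- calibrate_from_standards(ref, seed = 3)
cal$curves$ca
#> <calibration_curve ca: C = 5.7 * I + -0.01253, intercept CI95 [-0.04028, 0.01521] (through origin), n 8>

# a synthetic serum-EDTA sample with known composition
g <- generate_spectrum(synth_config(ca = 1.18, mg = 0.42, zn = 0.0065), seed = 4)
q <- quantify_spectrum(g$spectrum, models, cal$curves, ref, s_ref = ref$sensitivity)
q$report[, c("ion", "i_norm", "conc_mM", "uncertainty_mM", "status")]
#>   ion   i_norm  conc_mM uncertainty_mM status
#> 1  ca 0.205189 1.157039      3.904e-05     ok
#> 2  mg 0.073037 0.415802      3.897e-05     ok
#> 3  zn 0.001116 0.006338      3.138e-05     ok

# EDTA removal with baseline reconstruction
cl <- remove_edta_signals(g$spectrum, q$processed$fits, "all_edta")
cl$report$max_residual_sigma
#> [1] 0.79
```

The report gives, per ion, the normalized integral, the absolute
in-tube concentration in mM (true values here: Ca 1.18, Mg 0.42,
Zn 0.0065 — estimates land within a few percent, with Zn recovered
despite sitting inside the asparagine multiplet) and a status
(`ok`, `below_detection`, `below_LOD`). The clean report shows the
Zn-EDTA singlet was removed by model subtraction (it overlaps
asparagine) and that residues at removed peak centers stay below one
noise standard deviation.

A thin command-line front end is installed with the package
(`inst/cli/edtaqc.R`): `simulate` writes tsv spectra plus a
ground-truth CSV, `quantify` writes a per-sample report CSV, `clean`
writes cleaned spectra plus a JSON clean report.

## Package layout

| Area | Functions |
| --- | --- |
| Spectra & I/O | `nmr_spectrum`, `load_spectrum`, `write_spectrum`, `estimate_noise`, `bin_and_center` |
| Synthesis | `synth_config`, `generate_spectrum`, `generate_cohort`, `synth_standard`, `synth_reference` |
| Assignment | `find_glucose_anchor`, `fit_shift_model`, `assign_peak`, `assign_all_species`, `train_shift_models` |
| Deconvolution | `voigt_profile`, `fit_spin_system`, `subtract_asparagine`, `deconvolute_all` |
| Quantification | `spectrometer_sensitivity`, `normalized_integral`, `fit_calibration`, `quantify_ions`, `lod_loq_recovery`, `regression_coincidence_test`, `edta_mass_balance` |
| QC / cleanup | `remove_edta_signals`, `pca_scores`, `feature_correlation` |

The methods vignette (`vignettes/edta-aware-qc.Rmd`) documents the
models, the numerical choices and what the synthetic data do and do not
emulate.
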