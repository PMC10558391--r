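# glycoscope

Multimodal quantification of collagen glycation in decellularized
pericardium-like tissue. Ribose-driven glycation forms advanced glycation
end products — notably the fluorescent crosslink pentosidine — that make
collagen fluoresce, weaken its second-harmonic response, perturb its Raman
fingerprint and roughen its fibril surface. `glycoscope` implements the
three quantitative readouts of that process, plus seed-deterministic
synthetic generators that emulate untreated and glycated tissue so the
whole pipeline is testable without instrument data. It is intended for
researchers analyzing two-channel multiphoton images, Raman grid scans or
AFM height maps of collagenous tissue, and for anyone who needs a
reference implementation of the underlying chemometrics.

## What it computes

**Multiphoton (TPEF/SHG) ratios.** Ten 100 × 100-px regions of interest
are sampled per image; the per-ROI mean channel intensities are averaged
into *I*<sub>TPEF</sub> and *I*<sub>SHG</sub> and combined as

> TPEF ratio = *I*<sub>TPEF</sub> / (*I*<sub>SHG</sub> + *I*<sub>TPEF</sub>),  SHG ratio = *I*<sub>SHG</sub> / (*I*<sub>SHG</sub> + *I*<sub>TPEF</sub>).

The two ratios sum to one and rise/fall as glycation transfers collagen
signal from the SHG into the TPEF channel (≈0.5 for untreated tissue,
≈0.63 fully glycated).

**Raman chemometrics.** Spectra are cropped to the 800–1750 cm⁻¹
fingerprint, baseline-corrected by extended multiplicative signal
correction (EMSC: least-squares fit *s* ≈ *b*·reference + Σ *aᵢ*·basisᵢ
with five linear background functions, then (*s* − Σ *aᵢ*basisᵢ)/*b*),
normalized at the 1451 cm⁻¹ CH₂/CH₃ band, and classified by a
from-scratch PLS-LDA (NIPALS PLS2 followed by Fisher LDA in score space)
with stratified 5-fold cross-validation, per-class sensitivity/
specificity, and discriminant loading spectra.

**AFM topography.** Plane, scan-line and second-order polynomial
flattening; RMS roughness as the population second central moment of the
heights; and collagen D-period measurement as the distance between
maximum heights of adjoining crests along fiber-direction line profiles.

## Worked example

```r
library(glycoscope)

## a glycated (200 mM, 30-day) image pair, 512 px, and its ROI ratios
cfg  <- image_gen_config(size_px = 512, seed = 1)
img  <- generate_image_pair(cfg, glycation_preset(200, 30))
rois <- sample_rois(img, n = 10, size = 100, seed = 0)
compute_ratios(img, rois)
#> <ratio_result: TPEF 0.6311, SHG 0.3689 (n ROI = 10)>

## five-class Raman classification at 30 days (40 spectra per class)
rcfg <- raman_gen_config(seed = 1)
ds   <- generate_raman_dataset(rcfg, lapply(c(0, 5, 50, 100, 200),
                                            glycation_preset, day = 30), 40)
pp   <- preprocess_dataset(ds, collagen_reference_spectrum(rcfg))
kfold_cv(pp, k = 5, n_components = 6, seed = 1)
#> <5-fold CV: accuracy 94.5%>
#>      predicted
#> true   0  5 50 100 200
#>   0   40  0  0   0   0
#>   5    3 37  0   0   0
#>   50   0  0 38   2   0
#>   100  0  0  2  35   3
#>   200  0  0  0   1  39

## AFM: flatten a D-banded topography, roughness and D-period
topo <- flatten_topography(generate_topography(topo_gen_config(seed = 1)),
                           c("plane", "line", "zero"))
rms_roughness(topo)
#> [1] 1.10        # nm; banding + 0.3 nm background on this surface
ends <- fiber_profile_endpoints(topo, n = 6)
dps  <- lapply(ends, function(e) d_periods(extract_profile(topo, e)))
mean_d_period(dps)
#> [1] 63.8        # nm, the configured D-band period
```

The TPEF ratio 0.63 is the fully glycated level (the preset's transfer
fraction is calibrated so the expected ratio of a 200 mM/30-day pair is
0.63); the confusion matrix shows the characteristic pattern that only
neighbouring ribose concentrations are ever confused; and the pooled
D-period recovers the 63.8 nm banding to a tenth of a nanometre.

`run_all(run_config(seed = 1))` wires all stages together and writes a
combined JSON/CSV report; `inst/cli/glycoscope.R` exposes the same stages
as shell subcommands (`generate`, `preprocess`, `classify`, `ratios`,
`afm`, `run-all`, `validate`).

## Package layout

* `R/` — generators (`generate_*`), Raman preprocessing
  (`crop_fingerprint`, `build_emsc_basis`, `emsc_correct`,
  `normalize_at`, `preprocess_dataset`), chemometrics (`fit_pls`,
  `fit_lda`, `fit_plslda`, `kfold_cv`, `confusion_metrics`,
  `ld_loadings`), multiphoton ratios (`sample_rois`, `roi_means`,
  `compute_ratios`, `ratio_series`), AFM (`*_flatten`, `rms_roughness`,
  `extract_profile`, `d_periods`, `mean_d_period`) and the pipeline
  (`run_config`, `validate_config`, `run_all`).
* `vignettes/glycoscope-methods.Rmd` — the models, their assumptions,
  parameter choices and limitations.
* `tests/testthat/` — unit, property and end-to-end suites.
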