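---
title: "Methods: quantifying collagen glycation from multiphoton, Raman and AFM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying collagen glycation from multiphoton, Raman and AFM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscope)
```

## The measurement problem

Nonenzymatic glycation of extracellular-matrix collagen — the Maillard
reaction of reducing sugars with protein, producing advanced glycation end
products (AGEs) such as the fluorescent crosslink pentosidine — stiffens
and destabilizes collagenous tissue. In a typical in-vitro model,
decellularized pericardium is incubated in ribose (0, 5, 50, 100 or
200 mM) for 10, 20 or 30 days, and the progress of crosslinking is read
out with three label-free modalities:

* **Multiphoton imaging.** Fibrillar collagen is non-centrosymmetric and
  generates a second-harmonic (SHG) signal; elastin and pentosidine-
  glycated collagen fluoresce under two-photon excitation (TPEF).
  Glycation therefore *transfers* collagen signal from the SHG channel to
  the TPEF channel.
* **Raman microspectroscopy.** Glycation perturbs band intensities in the
  800–1750 cm⁻¹ fingerprint region without creating a strong crosslinker
  marker band; a multivariate classifier is needed to read the effect.
* **Atomic force microscopy.** Crosslinking roughens the fibril surface
  while leaving the ~63–67 nm axial D-band period of collagen intact.

`glycoscope` implements the three quantitative pipelines plus a
seed-deterministic synthetic generator for each modality, so every stage
is testable end to end without instrument data.

## TPEF/SHG intensity ratios

For each two-channel image, `n = 10` square regions of interest (ROIs) of
100 × 100 px are placed uniformly at random (overlap allowed; a
no-overlap option exists). The per-ROI mean intensities are averaged
across ROIs into $I_{TPEF}$ and $I_{SHG}$, and

$$\mathrm{TPEF\ ratio} = \frac{I_{TPEF}}{I_{SHG} + I_{TPEF}}, \qquad
  \mathrm{SHG\ ratio} = \frac{I_{SHG}}{I_{SHG} + I_{TPEF}}.$$

Both ratios are dimensionless, sum to one, lie in $[0,1]$ for
non-negative images, and are invariant under any common rescaling of the
two channels — all properties the test suite asserts. Because the ratio
equations operate on *mean* intensities, the package's primary statistic
is the **ratio of ROI-averaged means**; the per-ROI ratios (a mean of
ratios) are returned alongside as diagnostics. For balanced channels the
two coincide in expectation, but the ratio of means is the less noisy
estimator and the one consistent with the equations above.

### The image generator

`generate_image_pair()` renders a collagen field (wavy ridges with
Gaussian cross-section, sinusoidally perturbed centre lines) and an
elastin field (straight, rectilinear ridges), both as jittered regular
arrays of parallel fibers — matching the aligned, densely fibrous
morphology of pericardium, where elastin is described as parallel and
evenly arranged. A diffuse background (default 30 % of each field's mean)
stands in for unstructured matrix signal. Glycation enters through one
number, the fluorescence-transfer fraction $g \in [0,1]$:

$$\mathrm{SHG} = (1-g)\,C + \varepsilon, \qquad
  \mathrm{TPEF} = E + g\,C + \varepsilon,$$

with $C$ the collagen field, $E$ the elastin field and $\varepsilon$
additive Gaussian noise (default sd 5 % of the fiber amplitude), clamped
at zero like a photon-counting detector. Signal is transferred, never
created: at zero noise, $\mathrm{TPEF} + \mathrm{SHG} = E + C$ exactly
for every $g$. With the default channel calibration ($E$ rescaled so
$\bar E = \bar C$) the expected ratio has the closed form

$$\mathbb{E}[\mathrm{TPEF\ ratio}] = \frac{\bar E + g \bar C}{\bar E + \bar C}
  = \frac{1+g}{2},$$

whose inverse `g_for_ratio(r) = 2r − 1` lets a target ratio fix $g$
directly. The preset table sets $g = 0.26$ at 200 mM/30 days — the value
whose expected ratio is 0.63, the fully glycated level — and scales it
down by the severity function below. Untreated tissue has $g = 0$ and an
expected ratio of exactly 0.5.

Fiber density matters for the statistics: with sparse Poisson-placed
fibers, ten 100-px ROIs sample the field so unevenly that the per-image
ratio wanders by several hundredths. The jittered-grid placement and the
default spacing (one collagen fiber per ~7 px, one elastin fiber per
~10 px of image height) keep the ROI estimator's spread well below the
0.01 level at 2048², which is what repeated measurements of a
homogeneous, densely fibrous sample look like.

## Raman preprocessing

Spectra are cropped to the closed fingerprint interval
[800, 1750] cm⁻¹, baseline-corrected by **extended multiplicative signal
correction (EMSC)** against an untreated reference spectrum, and
normalized to the CH₂/CH₃ deformation band at 1451 cm⁻¹, which is common
to collagen and elastin and insensitive to glycation.

EMSC solves, by ordinary least squares,

$$s \;\approx\; b\,r + \textstyle\sum_{i=1}^{5} a_i\,h_i,$$

where $r$ is the reference and $h_i$ are five background components, and
returns $\hat s = (s - \sum_i \hat a_i h_i)/\hat b = r + e/\hat b$: the
chemical residual $e$ is preserved (rescaled), not discarded. The
background design uses five *linear* functions; since several readings of
that phrase are possible, the default is a linear-spline ("hat") basis on
an equal four-interval partition — five genuinely linear pieces whose
span contains every constant-plus-slope baseline, so the generator's
linear drift is removed exactly — with monomials of degree 0–4 available
via `basis_type = "poly"`. The chosen basis is recorded in the output's
metadata. A fit with $|\hat b| < 10^{-8}$ (e.g. an all-zero spectrum) is
a degenerate-fit error, reported with the spectrum's id.

Normalization divides by the *maximum* intensity within 1451 ± 5 cm⁻¹
rather than a single-point lookup, which makes the anchor robust to axis
discretization; the operation is idempotent. If a dataset's axis differs
from the reference axis, the reference is linearly interpolated onto the
dataset's cropped axis.

### The spectral generator

Spectra are sums of Lorentzian lines. The base model holds the eleven
collagen/elastin bands at 816, 856, 873, 922, 938, 1002, 1244, 1272,
1451, 1640 and 1666 cm⁻¹ (FWHM 12 cm⁻¹, except the sharp phenylalanine
mode at 8 cm⁻¹ and the broad water band at 25 cm⁻¹), with relative
amplitudes ordered like a typical collagen spectrum
(`collagen_band_table()` lists them). Glycation with effect scale
$s \in [0,1]$ perturbs the discriminant bands linearly: 938 and the
1634/1643 region (carried by the 1640 band) gain intensity; 922, the
amide-III flank at 1272 and amide I at 1666 lose intensity; and a broad
(FWHM 30 cm⁻¹) marker band appears at 1372 cm⁻¹ with amplitude
$0.25\,s$. The 1451 anchor is never touched. Each spectrum adds a random
linear baseline and i.i.d. Gaussian noise (default sd 1 % of the maximum
band amplitude).

The severity mapping from condition to effect scale is saturating in
concentration and linear in time,

$$s(c, d) = \frac{\log(1 + c/5\,\mathrm{mM})}{\log(1 + 40)}\cdot\frac{d}{30\,\mathrm{days}},$$

so 200 mM at 30 days has $s = 1$ and untreated tissue exactly $s = 0$.
No quantitative concentration–effect relation is available for this
system; this mapping is a calibration choice of the generator, fixed once
and documented here, not a measured fact.

One generator feature deserves emphasis: **per-spectrum glycation
heterogeneity**. A grid scan samples 100 spots of a piece of tissue in
which crosslinking is not homogeneous, so the generator jitters each
treated spectrum's effect scale by an additive Gaussian of sd 0.05
(clamped to $[0,1]$; untreated spectra stay exactly at zero). Without it,
the band model plus 1 % noise is almost noiselessly separable and every
classifier saturates at ~100 % for all incubation times, which is not how
the real measurement behaves. The value 0.05 was fixed a priori from a
Gaussian-overlap calculation on the severity spacings: adjacent 30-day
classes sit 0.17–0.46 apart (predicting ~95 % five-class accuracy), while
10-day spacings shrink threefold (predicting ~65 %), reproducing the
qualitative accuracy ordering of the real experiment. Heterogeneity of
this kind is the feature of real data the generator *does* emulate;
instrument drift, cosmic rays, water-band interference and focus
variation are features it does not — so a passing test suite shows the
pipeline's statistics behave correctly, not that the instrument model is
complete.

## PLS-LDA classification

The classifier is written from scratch. Stage one is **NIPALS PLS2**
against the one-hot class-indicator matrix: predictors and responses are
column-centred (no variance scaling — spectra are already
band-normalized), components are extracted by the classical NIPALS
iteration, and new observations are scored through the rotation
$R = W (P^\top W)^{-1}$. Training scores are mutually orthogonal; a
deflation collapse truncates the component count with a warning. Stage
two is **Fisher LDA** on the PLS scores: the between-class vs pooled
within-class generalized eigenproblem, solved via a Cholesky-whitened
symmetric eigendecomposition, returning at most $c-1$ unit-norm
discriminant directions ordered by eigenvalue. For two classes LD1
reduces to the closed form $S_w^{-1}(m_1 - m_2)$, which the tests use as
an oracle (alongside `MASS::lda` as an independent implementation).
A numerically singular $S_w$ is ridge-regularized
($10^{-8}\,\overline{\mathrm{diag}}$) with a warning.

Classification assigns the nearest class mean in LD space (Euclidean;
ties go to the lowest class index). The number of PLS components defaults
to 10. Performance is estimated by **stratified 5-fold cross-validation**:
each class is shuffled with the given seed and dealt round-robin into
folds, the full PLS-LDA fit (including centring) is recomputed inside
each training fold, and out-of-fold predictions are pooled into a single
confusion matrix with rows as true classes. Per-class sensitivity
$TP/(TP+FN)$ and specificity $TN/(TN+FP)$ and the overall accuracy
(trace/total) follow; per-fold accuracies are reported too, and their
fold-size-weighted mean equals the pooled accuracy. Discriminant
**loading spectra** are obtained by composing the LD directions with the
PLS rotation back onto the wavenumber axis, with the sign convention that
each loading's largest-magnitude element is positive. Loadings come from
the full-data model by default (per-fold loadings are computable by
refitting on any subset).

## AFM topography analysis

Height maps are flattened in the conventional order — least-squares
**plane** subtraction, per-scan-line offset removal (**line** flattening,
row medians by default since the median is robust to fibril crests; mean
available), full second-order **polynomial** background subtraction
(terms $1, x, y, x^2, xy, y^2$ on centred, scaled coordinates), then the
minimum height is set to zero. The order is configurable and recorded.
Every operator is idempotent, and roughness is invariant under the final
zero shift.

**RMS roughness** is the square root of the population second central
moment of the heights (divisor $N$) within an image; across a set of
repeated scans the summary is the mean and *sample* sd (divisor $n-1$) of
the per-image values.

**D-periods** are measured on line profiles drawn along the fiber axis
(`fiber_profile_endpoints()` builds six parallel chords), sampled by
bilinear interpolation at half-pixel spacing. Crests are local maxima
with topographic prominence at least 10 % of the profile's peak-to-peak
range and at least 30 nm apart — below any plausible 56–67 nm D-period,
above the noise scale. Two numerical details matter: the profile is first
boxcar-smoothed over ~10 nm (short against the period, so crest positions
are preserved, but enough to stop half-period noise bumps in the troughs
from passing the prominence filter), and each crest is localized to
sub-sample precision with a three-point parabolic fit (bilinear
interpolation otherwise flattens crests and quantizes their positions).
Each D-unit is the distance between adjoining crest maxima; the reported
statistic pools unit lengths across profiles.

### The topography generator

`generate_topography()` superposes (i) a raised-cosine banding of period
`d_period_nm` along the fiber direction — raised cosine so the waveform
is non-negative and its crest maxima are unambiguous; (ii) a tilt plane
$a x + b y + c$; (iii) per-scan-line Gaussian offsets (slow-axis drift,
exactly what line flattening removes); and (iv) i.i.d. Gaussian roughness.
The period must exceed twice the pixel size (Nyquist) or the config is
rejected. Defaults emulate a 2.5 µm, 512 × 512 scan (4.88 nm/px) of
untreated fibrils: 63.8 nm period, 3 nm band amplitude, 30° fiber angle.

## Determinism and problem sizes

Every generator draws from a single integer seed; objects inside a run
get sub-stream seeds through a fixed congruential hash (`sub_seed()`), so
adding an object never perturbs existing ones, and equal seeds give
bit-identical datasets, images and topographies — the pipeline report is
reproducible end to end. The test suite exercises the study-scale
problems directly: 500-spectrum five-class cross-validations, 2048² image
pairs with ten 100-px ROIs, and 512² topographies; the packaged demo
configuration (`run_config()`) uses reduced sizes (25 spectra per class,
256² images, 256² scans) so a complete `run_all()` finishes in seconds.

## Known limitations

* The generators model measurement statistics, not physics: no point
  spread function, no photon-counting statistics beyond additive
  rectified noise, no water-band hydration effects, no AFM tip
  convolution (which biases real D-period measurements and is the reason
  crest-to-crest distances, not band widths, are the unit measure).
* The concentration–severity mapping and the heterogeneity sd are
  calibration choices of the generator, not measured quantities; only the
  end-member anchors (untreated ratio 0.5, fully glycated expected ratio
  0.63, roughness 11.64 → 21.78 nm) are tied to reported tissue values.
* PLS component count is a genuine model-selection issue: 10 components
  are well supported at the study scale (100 spectra per class; pooled
  out-of-fold accuracy is flat between 6 and 10), but at demo scale a
  10-component model memorizes its small training folds and collapses in
  cross-validation, so `run_config()` pairs its 40-spectra-per-class demo
  with 6 components. No inner selection loop is run by default; the used
  value is logged in every report.
* The EMSC background basis is one reading of "five linear functions";
  the polynomial alternative is provided, and results carry the choice in
  their metadata.
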