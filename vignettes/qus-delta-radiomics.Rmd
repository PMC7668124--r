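---
title: "Quantitative ultrasound delta-radiomics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound delta-radiomics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Radiotherapy response in node-positive head-and-neck cancer is normally
assessed months after treatment ends, when anatomical change has accumulated.
Quantitative ultrasound (QUS) probes the tissue *microstructure* instead: the
backscattered radiofrequency (RF) signal carries information about the size,
concentration and spatial organisation of sub-resolution scatterers, which
change within days of the first radiation fraction as cells die and nuclei
fragment. `qusdr` implements the full analysis chain that turns serial RF
scans of a metastatic lymph node into a response prediction: spectral
parameter maps, texture features, changes from baseline ("delta-radiomics"),
group statistics, survival curves, and machine-learning classifiers. Because
clinical RF data of this kind are not publicly deposited, the package also
contains a first-class RF simulator with known ground truth, so that every
estimator and the classification layer are testable end to end.

## The RF simulation model

Each scan line is modelled as a 1-D superposition of echoes from point
scatterers, constructed in the frequency domain:

* the transmit pulse has a Gaussian magnitude spectrum centred at 8 MHz with
  a fractional −6 dB bandwidth of 0.6 (the protocol states the centre
  frequency only; the bandwidth is a package default, configurable in
  `acq_geometry()`);
* an echo from depth $z$ (cm) is delayed by $2z/c$ and multiplied by the
  two-way attenuation response $10^{-\alpha f (2z)/20}$, with $\alpha$ in
  dB/MHz/cm and $f$ in MHz — i.e. $\alpha$ is a one-way loss in dB, so
  received *power* decays at $2\alpha f z$ dB. This is the standard clinical
  convention for quoted coefficients such as the 0.576 dB/MHz/cm reference
  phantom, and all estimators below invert exactly this factor of 2. (The
  factor 4 that appears in parts of the literature belongs to the
  neper/amplitude convention and is the same physics.);
* scatterers of effective diameter $D$ multiply the echo amplitude by the
  spherical Gaussian form factor $\exp(-0.827 k^2 a^2 / 2)$ with
  $a = D/2$, so backscattered power carries $\exp(-0.827 k^2 a^2)$;
* echo amplitudes scale with the square root of the acoustic concentration,
  making mean RF power proportional to concentration;
* white Gaussian noise is added 30 dB below mean signal power by default.

Attenuation is applied per echo in the frequency domain rather than by bulk
filtering, which makes the attenuation-compensation round trip analytically
exact and testable. There is no diffraction or elevational beam model: every
downstream estimator consumes per-line spectra, for which the 1-D model is
sufficient and fully checkable against closed forms.

Scatterer fields come in two flavours. `"random"` draws a homogeneous planar
Poisson field (diffuse scattering). `"quasi_periodic"` adds, per lateral
column, an axial lattice with mean spacing $d$ and multiplicative jitter,
which imprints a ripple of period $\Delta f = c/2d$ on the backscatter
spectrum — the physical basis of scatterer-spacing estimation. Simulated
fields are deliberately sparse (hundreds of scatterers per cm² rather than
the thousands per resolution cell of fully developed speckle); spectral
expectations are unaffected, but first-order envelope statistics are not
Rayleigh. This is one of the stated gaps between the simulator and real
tissue.

## The seven spectral parameters

All spectra are mean Hann-tapered periodograms over the scan lines of a
2 × 2 mm analysis window, normalized by a reference-phantom spectrum taken
from the same window position:

$$\mathrm{NPS}(f) = 10\log_{10} \frac{S_\text{sample}(f)}{S_\text{ref}(f)},$$

which cancels the system and transducer responses. The reference phantom is
modelled after a glass-bead-in-gelatin calibration medium: attenuation
0.576 dB/MHz/cm, speed of sound 1540 m/s, and a Rayleigh ($f^4$) backscatter
law appropriate for sub-resolution beads.

* **ACE** (attenuation coefficient estimate, dB/MHz/cm): the common slope of
  $\mathrm{NPS}(f, z)$ against $fz$ over all in-ROI windows, with a free
  intercept per frequency bin, equals $-2(\alpha_s - \alpha_r)$. ACE is
  estimated once per frame and used for point compensation of every window
  (the package treats attenuation as a frame-level tissue property; only the
  mean ΔACE is used downstream and no ACE texture is computed, so the ACE
  map is constant by construction). Estimates are clamped to the physical
  range [0, 3] dB/MHz/cm.
* **MBF, SS, SI** (mid-band fit dB, spectral slope dB/MHz, spectral
  intercept dB): ordinary least squares on the compensated NPS over the
  analysis band; MBF is the fitted value at the band centre, so
  MBF = SI + SS·f_c holds as an exact identity on every window and is
  asserted as such in the tests.
* **ASD, AAC** (average scatterer diameter µm, average acoustic concentration
  dB): the backscatter coefficient is reconstructed as
  $\mathrm{BSC}(f) = \mathrm{BSC}_\text{ref}(f)\,10^{\mathrm{NPS}_c(f)/10}$
  and the Insana–Hall Gaussian form-factor model
  $\mathrm{BSC} = C f^4 e^{-0.827 k^2 a^2}$ inverted by a linear fit of
  $\ln \mathrm{BSC} - 4\ln f$ on $k^2$: the slope gives $a$ (ASD $= 2a$),
  the intercept gives AAC $= 10\log_{10} C$. The multiplicative Insana–Hall
  constant is absorbed into $C$; since only baseline-subtracted deltas are
  used downstream, it cancels identically. A positive (non-physical) slope
  yields ASD 0 with a warning flag; such windows are masked in maps.
* **SAS** (scatterer spacing, mm): the mean-removed, detrended window
  spectrum is treated as a pseudo-time series sampled every d$f$ MHz and
  fitted with an order-10 autoregressive model by Burg's recursive
  algorithm; the dominant AR spectral peak at quefrency $q$ cycles/MHz gives
  $\Delta f = 1/q$ and SAS $= c/2\Delta f$. Order 10 is the smallest order
  that resolved the lattice ripple reliably at the default geometry;
  it is configurable. Peaks below twice the median AR spectrum are flagged
  unreliable.

**Bands.** The protocol does not state the analysis bandwidth. The package
uses the band where the reference spectrum is within 10 dB of its peak for
the linear and form-factor fits (a wider lever arm stabilises the $k^2$
regression against speckle noise), and the −20 dB band for the spacing
analysis (more ripple cycles in view). Both are configurable in
`build_parametric_maps()`.

**Sliding window.** Parametric maps use a 2 × 2 mm window; the protocol's
94% overlap (0.12 mm step) is the default of `window_spec()`. Simulation
studies in this package usually use coarser overlaps (50% or none):
overlapping windows share speckle, so they add resolution but not
statistical information, and window medians over *independent* windows are
far more stable. Windows are kept when their centroid is inside the ROI;
non-finite or out-of-bound window estimates are masked and excluded from
means and texture.

## Texture features

Each of the six informative maps (MBF, SS, SI, SAS, ASD, AAC — ACE is
constant) is quantized to 16 grey levels between its in-ROI extremes
(per map, per scan, so each time point is self-contained — a requirement for
meaningful delta features). Sixteen co-occurrence matrices are built (four
distances 1–4 pixels × four directions 0/45/90/135°, diagonal offsets using
the chessboard convention, both pixels required in-ROI, pairs counted
bidirectionally so the GLCM is symmetric and sums to 1), and four Haralick
statistics — contrast, correlation, energy, homogeneity — are averaged over
the 16 with equal weight (the aggregation rule is not stated in the
protocol; the unweighted mean is the common choice). Correlation on a
zero-variance marginal is defined as 0. The quantization depth of 16 is a
package default.

This yields 7 spectral + 24 texture = 31 features per scan; delta features
are formed by subtracting the pre-treatment baseline, giving identically
zero vectors at baseline by construction.

## Statistics

Group comparisons (complete vs partial responders) are routed by a
Shapiro–Wilk test at α = 0.05 *in each group*: only if neither group rejects
is a two-sided Welch t-test used (unequal group sizes argue for the
unequal-variance form), otherwise a two-sided Mann–Whitney U-test. A
zero-variance group falls back to Mann–Whitney with a warning. Group
summaries are mean ± SEM. No multiple-testing correction is applied across
the 31 features — matching the raw-p-value reporting convention of the
clinical setting, and a documented limitation. Survival uses the
Kaplan–Meier product-limit estimator and the two-group log-rank test from
the `survival` package.

## Classification

Delta features at one time point feed two classifiers:

* **K-NN** with k = 3 (k is not stated in the source protocol; 3 is the
  package default and configurable), Euclidean distance on z-scored
  features, with standardization statistics fitted on the training fold
  only. A vote tie takes the class of the single nearest neighbour
  (deterministic and local). The ROC score is the fraction of neighbours
  voting for the positive class.
* **Gaussian naive Bayes** with empirical priors and a per-feature variance
  floor of 1e−9 × the pooled variance.

The **positive class is CR** (complete responder) for sensitivity,
specificity and AUC; this is a package convention, stated here because the
clinical tables it mirrors do not define one, and it is configurable
(`positive =`). Feature subsets of size 1–3 are chosen by sequential forward
selection in a leave-one-out wrapper — at each step the feature that
maximises LOO accuracy joins the subset, ties broken by column order. The
cap of three features follows the subjects/10 rule of thumb at n = 36.
Reported metrics come from the same LOO predictions the wrapper optimised,
which matches the protocol wording but carries selection bias; the null
calibration below quantifies that inflation rather than hiding it. AUC is
computed by the tie-aware rank (trapezoid) form.

## Simulation studies and their sizes

Three study layers back the package's claims, all regenerated from seeds at
test time:

* **Exact identities** (machine precision): analytic form-factor inversion,
  MBF identity, GLCM oracles, hand product-limit survival, posterior
  symmetry, distance-sort and exhaustive-search oracles.
* **Estimator recovery** at the full scan geometry (40 MHz, 256 lines,
  3.8 × 5 cm): planted attenuation 1.0 dB/MHz/cm, diameter 30 µm, and a
  0.30 mm zero-jitter lattice, each summarised as the median over 128
  non-overlapping 2 × 2 mm windows in a 1.6 × 3.2 cm region. Tolerances:
  15% (ACE), 25% (ASD), 10% (SAS). Per-window ASD estimates are extremely
  dispersed (the form-factor signal across the band is a fraction of the
  speckle noise per window); the window *median* is the stable quantity,
  which is why recovery is defined on it and why independent windows are
  used.
* **Classification calibration** at a reduced "study scale" (48 lines over
  1.44 cm, 2.2 cm depth — `study_geometry()` — with an elliptical node ROI
  holding ~50 windows at 50% overlap; 20 patients per cohort at the 14/36
  CR fraction; 5 Monte-Carlo cohorts per arm; baseline + 24 h scans). Null
  cohorts (identical group trajectories) check that a fixed single-feature
  naive-Bayes LOO accuracy sits near the majority-class rate, and measure
  the realized between-patient SD of each knob-linked delta feature
  (ΔAAC, ΔACE, ΔSAS, ΔASD). Planted cohorts shift each knob by **two of
  those realized SDs** in the CR group — i.e. the planted effect size is
  defined in units of the variability the full pipeline actually produces,
  estimator noise included, which is what "a 2-SD effect" means for any
  real measurement — and require the wrapper-selected single-feature
  naive-Bayes LOO accuracy to reach 80% in the median cohort. The
  selection-inflated null accuracy is also reported, as the measure of
  wrapper optimism at this sample size. Note two opposing small-sample
  artifacts the calibration exposes rather than hides: leave-one-out with an
  *uninformative* feature is pessimistically biased (holding a point out
  tilts the training statistics against it, so null accuracy tends to fall
  somewhat below the majority rate), while wrapper selection over 31
  features is optimistically biased.

The cohort generator's clinical defaults are fixed: 36 patients, 14 CR / 22
PR, four scan times (baseline, 24 h, week 1, week 4), exponential
recurrence hazards matching 3-year recurrence-free survival of 84% (CR) and
72% (PR), and uniform 12–57 month censoring. Baseline tissue defaults
(attenuation 0.7 dB/MHz/cm, 30 µm scatterers, 0.30 mm spacing with 15%
jitter) are in the soft-tissue range for nodal tissue and are documented in
`generate_cohort()`.

## What passing tests do and do not show

The simulator shares the estimators' physics (1-D, per-line, Gaussian form
factor), so recovery tests validate the *inversion chain*, not the adequacy
of that physics for real nodes: diffraction, elevational compounding,
non-Gaussian scatterer populations, fully developed speckle statistics,
motion and operator variability are all outside the model. Likewise the
planted-effect calibration shows the classification layer can detect a
2-SD microstructural change through the full pipeline at n = 20 — it does
not reproduce, and cannot be compared numerically with, accuracies measured
on patients.

## Known limitations

* One representative 2-D frame per time point; volumetric scans and their
  aggregation across planes are not modelled (the acquisition protocol
  sweeps the full node volume but does not state the aggregation rule).
* Frame-level ACE; genuinely heterogeneous attenuation inside a node would
  bias the point compensation of deep windows.
* No multiple-testing correction in the 31-feature comparison table.
* Wrapper metrics carry selection bias at n of a few dozen; the package
  reports the null-cohort inflation alongside rather than providing a
  nested outer loop by default.
* The HDF5 RF container of scanner exports is replaced by a portable
  TSV + JSON text container (`write_rf_frame()`).
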