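---
title: "Bone marrow dosimetry for Lu-177 therapy: model, protocols, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone marrow dosimetry for Lu-177 therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowdose)
```

## The dosimetric model

The red (active) bone marrow is a principal organ at risk in
Lu-177-Octreotate therapy of neuroendocrine tumours and Lu-177-PSMA-617
therapy of metastasised castration-resistant prostate cancer. `marrowdose`
computes the total marrow absorbed dose at the organ level, in the MIRD
tradition: every contribution is the product of a time-integrated activity
(TIA) in a source region and an S value, the absorbed dose to the marrow per
unit TIA in that source,

$$D_{BM \leftarrow source} = S_{BM \leftarrow source} \cdot \tilde{A}_{source},
\qquad \tilde{A}_{source} = \int_0^\infty A_{source}(t)\,dt .$$

Three source compartments are modelled:

* **Blood (marrow self-dose).** In the absence of specific binding to
  marrow or blood cells the marrow activity concentration follows the
  plasma concentration. The dose is
  $[\tilde{A}_{blood}] \cdot \mathrm{RMBLR} \cdot m_{BM,pat} \cdot
  S_{BM \leftarrow BM} \cdot (m_{BM,ph}/m_{BM,pat})^a$, where
  $[\tilde{A}_{blood}]$ is the TIA *concentration* (Bq h/ml) from the
  bi-exponential fit to five blood samples. For PSMA-617,
  $\mathrm{RMBLR} = \mathrm{RMECFF}/(1-\mathrm{HCT})$ with the red-marrow
  extracellular fluid fraction fixed at 0.19 and the patient haematocrit
  HCT; for Octreotate, $\mathrm{RMBLR} = 1$ (see `rmblr()`).
* **Major organs.** Kidneys for both therapies; liver and spleen
  additionally for Octreotate (`default_organs()`). Organ TIAs come from
  mono-exponential fits to the sequential quantitative SPECT activities at
  24/48/72 h; each cross-dose is
  $\tilde{A}_{organ} \cdot S_{BM \leftarrow organ} \cdot
  (m_{organ,ph}/m_{organ,pat}) \cdot (m_{BM,ph}/m_{BM,pat})$.
* **Remainder of body (ROB).** The whole-body TIA minus the blood term and
  the organ TIAs (`rob_tia()`), converted with a three-term bracket that
  removes the marrow self and organ shares from the whole-body S value,
  with non-linear mass-scaling exponents $a, b, c$ (male: 1.001, 0.896,
  0.963; female: 0.992, 0.894, 0.970). All tumour activity deliberately
  stays in the ROB: per-lesion S values cannot be tabulated for arbitrary
  tumour geometry, so the ROB S value is applied to the pooled lesion
  burden. Liver metastases are the one exception: their activity is removed
  from the *healthy liver* VOI (via the `exclude` mask of
  `voi_activity()`), which returns it to the ROB.

Percentage contributions of the constituents and the mGy/GBq normalisation
are part of the `dose_report` assembled by `total_bm_dose()`.

### Assumptions worth stating

* Measured activities are **not** decay-corrected: the fits describe
  effective (biological + physical) kinetics, so the analytic integrals are
  effective TIAs, which is what the dose integral wants.
* Times are hours post-injection with $t = 0$ at injection; activities are
  Bq internally. Inside the blood and ROB equations, 1 ml of blood is
  treated as 1 g and marrow masses enter in grams, making the blood term a
  TIA in Bq h.
* The patient marrow mass is rarely known. It defaults to linear body-mass
  scaling of the phantom marrow mass,
  $m_{BM,pat} = m_{BM,ph} \cdot m_{WB,pat}/m_{WB,ph}$, overridable per
  patient. The ROB mass is defined as whole body minus marrow minus
  modelled organs. Patient organ masses default to VOI volume times
  1.05 g/ml (`organ_mass_from_voi()`).
* S values are configuration, not code: published phantom tabulations are
  licensed data and are not reproduced here. The packaged
  `phantom_synthetic.yaml` is an **illustrative synthetic set** with
  Lu-177-realistic magnitudes (beta-dominated marrow self-irradiation of
  order $10^{-10}$ Gy/(Bq h), photon-dominated whole-body cross-irradiation
  of order $10^{-12}$), chosen once so that simulated cohorts land at
  total doses of order 10 mGy/GBq. Clinical use requires a real tabulation
  in the same file format.

## The two imaging protocols

The **reference protocol (RP)** uses all three whole-body planar scans: the
whole-body TIA is the analytic integral of a mono-exponential fit to the
calibrated planar activities at 24, 48, 72 h.

The **hybrid protocol (HP)** replaces the planar series by a single planar
image at $t^* \in \{24, 48, 72\}$ h and borrows the washout rate from the
abdominal SPECT series: with $\lambda_{SPECT}$ from a mono-exponential fit
to the SPECT field-of-view totals (organs and tumours included),

$$\tilde{A}_{WB,pseudo} = \frac{A_{WB}(t^*)\,e^{\lambda_{SPECT} t^*}}{\lambda_{SPECT}} .$$

Only the ROB component changes; blood and organ components are identical
between protocols by construction. When the abdominal washout is slower
than the whole-body washout — the typical situation, since the abdomen
holds the strongly retaining organs and most lesions — an early base point
overestimates the TIA, and the error shrinks as $t^*$ moves late. The
diagnostic identity

$$\frac{\tilde{A}_{RP}}{\tilde{A}_{HP}} =
  \frac{A_{0,RP}}{A_{0,HP}} \cdot \frac{T_{1/2,RP}}{T_{1/2,HP}}$$

(`tac_parameter_ratios()`) separates the intercept and half-life parts of
that mismatch. For measured data the base-point activity is the *measured*
calibrated planar activity at $t^*$ (the default); synthetic studies can
instead place the base point on the reference fit to isolate the
protocol error from measurement noise.

## Quantitative planar processing

The planar chain mirrors routine practice on a dual-headed camera with the
208 keV photopeak (15% width) and 170/240 keV scatter windows (15%/10%):

1. **TEW scatter correction** with the trapezoidal estimator on absolute
   window widths (25.5/31.2/24.0 keV); negative pixels are floored at zero.
2. **Attenuation**: a bilinear HU-to-mu calibration at 208 keV constrained
   to be continuous at HU = 0 and clamped outside [-688, 1127] HU (no
   calibration support in the air/metal regimes); the mu volume is
   integrated along the ventral axis; segments outside the CT footprint
   (arms, legs, part of the head) take per-segment default optical depths;
   the map is blurred with a Gaussian of FWHM 11 mm approximating the
   camera resolution.
3. **Conjugate view**: geometric mean of the two views divided by the
   square root of the transmission $e^{-\mu d}$.
4. **SPECT-anchored calibration**: each planar image is calibrated
   (Bq/cps) against the same-session quantitative SPECT field-of-view
   activity; the planar ROI is the rows spanning the SPECT axial field of
   view at full transverse width.

Organ activities come from percent-isocontour VOIs of the regional maximum
(defaults: 35% kidneys/spleen, 12.5% liver — lower because metastatic
livers are heterogeneous — and 40% for tumours), summed as concentration
times voxel volume. Partial-volume and dead-time corrections are
deliberately not applied.

## Numerical choices

* **Mono-exponential fits** are unweighted linear least squares on
  log-transformed values: deterministic, exact for two points, and the
  standard clinical treatment of three-point series. A fitted decay that is
  zero to round-off over the observed span (lambda times span below
  1e-10) is reported as a non-physical-kinetics error rather than an
  absurd half-life. A weighted variant is available but off by default.
* **Bi-exponential fits** are bounded Levenberg-Marquardt on the linear
  scale. Five-point fits are ill-conditioned, so the fitter starts from a
  curve-peeling estimate (slow phase from the late points, fast phase from
  the early residuals) plus a fixed 3 x 2 grid of fallback starts
  (fast half-life 0.5/2/6 h, slow 20/50 h); the best converged run wins.
  A collapsed amplitude is flagged `degenerate`, not an error: a
  mono-exponential blood curve is physiology.
* **Analytic integrals** ($A_0 T_{1/2}/\ln 2$; $\sum A_i/\lambda_i$) are
  property-tested against adaptive quadrature to below 0.01%.
* **Negative ROB TIA** signals a calibration fault; the default is a
  strict error reporting every term, with an opt-in clamp-to-zero mode.
* The Gaussian blur is a separable discrete kernel truncated at 6 sigma
  and normalised to unit sum, with zero padding.
* Images are indexed (row, column), volumes (row, column, ventral); masks
  are plain logical arrays.

## The synthetic cohort generator

No clinical images or blood counts are public, so validation runs on
virtual patients (`virtual_patient_spec()`, `generate_virtual_patient()`)
whose ground truth is analytic: mono-exponential whole-body, abdominal and
organ washout, bi-exponential blood clearance, and a tumour-load descriptor.
Two presets encode the typical cohort structure: `"octreotate-like"`
(whole-body half-life 43 h, abdominal 61 h, blood slow phase 25 h, medium
tumour load) and `"psma-like"` (31/42/14 h, high tumour load, haematocrit
0.37). Blood amplitudes were chosen once so that the blood dose lands near
60% (Octreotate) or 30% (PSMA) of a total of order 10-14 mGy/GBq with the
packaged synthetic S values. Cohorts (`make_virtual_cohort()`) jitter body
mass (62-88 kg), haematocrit (0.34-0.44), half-lives (within 15%), the
abdominal-to-whole-body half-life ratio (within 5% of the preset's ~1.4)
and uptake fractions, all under one seed.

Measurement noise is multiplicative lognormal (default sigma 5%,
`meanlog = -sigma^2/2` so the noise is mean-one): at therapy activities,
quantification uncertainty dominates count statistics, so lognormal on
activities is the honest model; Poisson noise is available for the planar
image fixtures. The planar phantom generator places each pixel's activity
at a single known depth so that the conjugate-view correction is exact in
the noiseless limit, and populates the scatter windows consistently with
the TEW estimator - the round trip therefore isolates implementation error
rather than model mismatch.

What the generator does **not** emulate: anatomically realistic activity
distributions, SPECT projection/reconstruction physics, co-registration
error, camera dead time, or kinetics beyond two exponentials. Passing the
synthetic recovery tests therefore demonstrates the correctness of the
formulae and their composition, not the clinical accuracy of planar or
SPECT quantification on real patients.

## Validation problem sizes

The shipped tests and the acceptance script use: 1000 random curves for
the quadrature property; 200 random fit pairs for the intercept/half-life
identity; two noiseless five-patient cohorts (worst-case recovery below
0.5%); 200 noisy five-patient cohorts at sigma = 5% for the
reference-protocol bias (observed well within +/-2%); 30 noisy cohorts for
the hybrid-vs-reference deviation ordering; and one noiseless planar
phantom round trip (2% tolerance). Published per-patient cohort tables
(ten patients) validate the comparison statistics end to end.

## Known limitations

* Organ-level S values cannot represent patient-specific 3D anatomy or the
  heterogeneous lesion distribution inside the ROB; photon cross-dose
  errors of tens of percent against Monte-Carlo voxel dosimetry are
  documented in the field. The hybrid-vs-reference comparison is robust to
  this because both protocols share the same S-value machinery.
* The marrow-mass derivation (linear body-mass scaling) is an assumption;
  when a patient-specific marrow mass estimate exists, pass it via
  `patient_context(m_bm_kg = ...)`.
* Base points later than 72 h are not supported: the acquisition schedule
  ends there and extrapolating the protocol beyond it is unvalidated.
* The bi-exponential blood fit reports what five samples can support; no
  attempt is made to stabilise it with priors or weighting beyond the
  multi-start strategy.
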