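# marrowdose

Organ-level red bone marrow dosimetry for Lu-177 radionuclide therapy
(Lu-177-Octreotate for neuroendocrine tumours, Lu-177-PSMA-617 for
metastasised castration-resistant prostate cancer), written for medical
physicists who run per-cycle dosimetry and want to know whether a
single whole-body planar scan can replace the full sequential series.

## The model

The total marrow dose is a sum of MIRD-style source terms, each a
time-integrated activity (TIA) times a mass-scaled phantom S value:

- **blood self-dose** (blood method):
  `D = [Ã_blood] · RMBLR · m_BM,pat · S_BM←BM · (m_BM,ph/m_BM,pat)^a`,
  with `RMBLR = RMECFF/(1−HCT)` for PSMA-617 (RMECFF = 0.19) and
  `RMBLR = 1` for Octreotate; `[Ã_blood]` comes from a bi-exponential fit
  to five blood samples (30 min, 80 min, 24 h, 48 h, 72 h) integrated to
  infinity;
- **organ cross-doses** (kidneys; plus liver and spleen for Octreotate):
  `D = Ã_organ · S_BM←organ · (m_organ,ph/m_organ,pat) · (m_BM,ph/m_BM,pat)`,
  with organ TIAs from mono-exponential fits to sequential quantitative
  SPECT at 24/48/72 h;
- **remainder of body (ROB)**, which pools all tumours:
  `Ã_ROB = Ã_WB − [Ã_blood]·RMBLR·m_BM,pat − Σ Ã_organ`, converted with a
  three-term S-value bracket using non-linear mass-scaling exponents
  (a, b, c).

Two protocols produce `Ã_WB`: the **reference protocol** fits the three
calibrated whole-body planar scans, while the **hybrid protocol** uses one
planar scan at `t*` ∈ {24, 48, 72} h and the abdominal SPECT decay
constant: `Ã_WB,pseudo = A_WB(t*) · exp(λ_SPECT · t*) / λ_SPECT`. The
package also implements the supporting planar chain (triple-energy-window
scatter correction, bilinear HU→μ calibration, projected attenuation maps,
conjugate-view quantification, SPECT-anchored calibration,
percent-isocontour VOIs), the protocol-comparison statistics, and a
synthetic virtual-patient generator with analytic ground truth.

## Worked example

Simulate an Octreotate-like five-patient cohort (whole-body half-life
around 43 h, abdominal washout ~40% slower, 5% quantification noise), run
both protocols, and compare:

```r
library(marrowdose)

phantoms <- read_phantom_reference(
  system.file("extdata", "phantom_synthetic.yaml", package = "marrowdose"))
cohort <- make_virtual_cohort(5, "octreotate-like", phantoms$male, seed = 42)
hr <- run_hybrid(cohort, phantoms$male)

hr$reference$reports$S1
#> Bone marrow dose report [S1, RP]
#>   total: 14.0 mGy/GBq (102.3 mGy)
#>   blood 57% | organs 7% | ROB 35%

round(hr$doses[, -(1:2)], 1)
#>     rp hp24 hp48 hp72
#> 1 14.0 14.8 14.4 14.2
#> 2 16.2 16.5 16.2 16.3
#> 3 15.3 17.1 15.7 15.3
#> 4 16.6 16.8 17.2 16.5
#> 5 13.4 13.9 14.3 13.3
```

The totals are in mGy per GBq injected; the blood dominates for
Octreotate, and every hybrid variant tracks the reference closely. The
percentage deviations (median and range over the cohort) shrink as the
base point moves late — the central finding the comparison machinery is
built to expose:

```r
s <- hr$comparison$summaries
s[s$metric %in% c("pd_hp24", "pd_hp48", "pd_hp72"), ]
#>      therapy  metric median  min  max
#> 5 octreotate pd_hp24   4.17 1.25 11.9
#> 6 octreotate pd_hp48   2.77 0.07  7.1
#> 7 octreotate pd_hp72   0.66 0.14  1.4
```

The same comparison stage applied to the packaged published ten-patient
cohort tables reproduces the printed cohort medians, e.g. reference 12.1
and HP72 12.3 mGy/GBq for Octreotate:

```r
tab <- lu177_cohort_tables()
cmp <- protocol_comparison(tab$protocol_doses)
cmp$summaries[cmp$summaries$metric %in% c("rp", "hp72"), ]
#>       therapy metric median min  max
#> 1  octreotate     rp   12.1 9.6 15.6
#> 4  octreotate   hp72   12.3 9.6 15.7
#> 8     psma617     rp   10.2 6.7 16.8
#> 11    psma617   hp72   10.1 7.0 16.8
```

A thin command-line front end (`inst/cli/marrowdose.R`) wraps the same
functions as `simulate`, `reference`, `hybrid` and `compare` subcommands.

Note that the shipped `phantom_synthetic.yaml` is an illustrative,
synthetic S-value set (see the vignette); clinical use requires a real
phantom tabulation in the same format.

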