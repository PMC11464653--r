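# cralekit

Quantification of CPR-associated lung edema (CRALE) from multimodal
physiological data, for researchers studying lung injury caused by chest
compressions in large-animal resuscitation models.

Prolonged cardiopulmonary resuscitation drives fluid and blood into the
lung: weight rises, gas volume falls, the lung stiffens and oxygenation
deteriorates. cralekit implements the four measurement modalities that
characterize this syndrome, plus seeded synthetic-data generators with
exact ground truth so every stage is testable without animal data:

- **CT densitometry** — voxel gas/tissue decomposition
  (`gas = -HU/1000`), the four aeration compartments (hyper −1000…−901,
  normal −900…−501, poor −500…−101, non-aerated −100…+100 HU), lung
  volume/gas volume/weight, area-normalized mean density, the CRALE
  criterion (mean density ≥ −500 HU), three sterno-vertebral bands with
  the ventro-dorsal gradient `(V − D)/V × 100`, and a ten-slice
  whole-lung extrapolation.
- **Respiratory mechanics** — occlusion-test validation of the
  esophageal catheter (ΔPes/ΔPaw in [0.8, 1.2]), compression-cycle
  detection on band-passed Pes, per-epoch ΔPes, occlusion plateaus, and
  partitioned compliance/driving pressure with the identity
  `1/Crs = 1/CL + 1/Ccw` enforced; per-cycle coronary perfusion
  pressure.
- **Oxygen transport** — contents (`1.34·Hb·SO2 + 0.003·PO2`), the
  alveolar gas equation, `DO2 = CO·CaO2·10`, `VO2 = CO·(CaO2−CvO2)·10`,
  and the Berggren shunt `Qs/Qt = (CcO2 − CaO2)/(CcO2 − CvO2)`.
- **Stereology** — 100-point counting grids on histology class maps,
  alveolar-tissue percentage, wet-to-dry and lung/body ratios.

The methods vignette (`vignettes/crale-methods.Rmd`) documents the
models, conventions, parameter defaults and limitations.

## Worked example

Generate a post-CPR-regime phantom (edema shift 225 HU over a −549 HU
baseline) and quantify it:

```r
library(cralekit)
ph <- gen_ct_phantom(phantom_ct_params(edema_shift = 225, vd_slope = 410,
                                       seed = 8))
quantify(ph$ct, ph$mask)
#> <aeration_report> volume 658.7 mL, gas 210.4 mL, weight 448.3 g, mean -319 HU [CRALE]
#>   compartments: hyper 0.0% normal 1.4% poor 98.6% non 0.0%
```

The mean density of −319 HU sits in the post-resuscitation regime and
trips the CRALE flag (≥ −500 HU); gas volume plus weight reproduces the
658.7 mL lung volume exactly, the built-in conservation check. A
zero-noise blood-gas panel generated with a true shunt of 0.30 inverts
exactly through the Berggren equation:

```r
g <- gen_bloodgas_panel(gas_exchange_params(qs_qt = 0.3, co = 2, hb = 9,
                                            fio2 = 1, vo2 = 60))
transport_panel(g$panel, co = 2)
#> <o2_transport> [cpr] CaO2 12.76 CvO2 9.76 CcO2 14.05 mL/dL
#>   DO2 255 VO2 60 mL/min  Qs/Qt 0.300
```

## Analysis workflow

The numbered drivers under `analysis/` reproduce the full study-shaped
analysis on a deterministic five-animal synthetic cohort (seed 42) and
write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort + ground truth
Rscript analysis/02_ct_densitometry.R     # aeration reports, bands, 10-slice
Rscript analysis/03_respiratory_mechanics.R
Rscript analysis/04_oxygen_transport.R
Rscript analysis/05_stereology.R
Rscript analysis/06_cohort_report.R       # associations + cohort report
```

On this cohort the drivers print, among others: mean density
−549 → −312 HU, lung weight 295 → 449 g, CRALE 5/5 post-CPR (0/5 at
baseline), and cross-modality associations r = 0.950 (ΔPes vs lung
weight), r = −0.945 (lung weight vs Crs), r = 0.954 (CT vs ex-vivo
weight) — severity links the modalities by construction, and the
pipeline recovers them.

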