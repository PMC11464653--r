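---
title: "Quantifying CPR-associated lung edema: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CPR-associated lung edema: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cralekit)
```

## The problem

Prolonged chest compressions during cardiopulmonary resuscitation can
drive fluid and blood into the lung, producing CPR-associated lung edema
(CRALE): the lung gains weight, loses gas volume, stiffens, and its
ability to oxygenate blood falls. cralekit implements the four
measurement modalities through which this syndrome is quantified in a
supine large-animal preparation — quantitative CT densitometry,
esophageal-pressure-partitioned respiratory mechanics, oxygen-transport
physiology, and point-counting stereology — together with seeded
synthetic-data generators that provide exact ground truth for every
stage. Because each analysis can be run against data whose true answer
is known by construction, the whole pipeline is testable end to end
without any animal data.

## Quantitative CT densitometry

CT attenuation in Hounsfield units decomposes each voxel linearly into
gas and tissue: -1000 HU is pure gas, 0 HU pure tissue of density
1 g/mL. For a voxel with attenuation $h$ (clipped to $[-1000, 0]$ for
gas and $[-1000, +100]$ for tissue),

$$f_{gas} = -h/1000, \qquad f_{tissue} = 1 + h/1000 ,$$

with the tissue fraction capped at 1 so voxels denser than water count
as pure tissue. Summing over the lung mask gives gas volume and lung
weight; by construction $f_{gas} + f_{tissue} = 1$, so gas volume plus
weight (at 1 g/mL) reproduces the anatomical lung volume exactly — the
package asserts this conservation on every report.

Voxels are classified into the standard aeration compartments:
hyper-aerated ($-1000$ to $-901$ HU), normally aerated ($-900$ to
$-501$), poorly aerated ($-500$ to $-101$), non-aerated ($-100$ to
$+100$). The printed integer ranges leave sub-integer values (possible
after interpolation or added noise) undefined; internally the bins are
half-open at the midpoints ($-900.5$, $-500.5$, $-100.5$), which leaves
every integer example unchanged and makes the classification total. HU
values outside $[-1000, +100]$ inside the mask are excluded from the
compartment fractions but enter gas/weight via clipping, with a logged
count: imperfect masks (unexcluded vessels, effusion) should not
silently corrupt compartment statistics.

Mean lung density is the per-slice in-mask mean weighted by slice area.
With uniform voxel spacing this equals the plain voxel mean, and the
implementation asserts that equivalence rather than trusting it. CRALE
is flagged when mean density is $\ge -500$ HU, inclusive at the
threshold.

**Gravitational profile.** Each cranio-caudal slice's in-mask
ventro-dorsal extent is split into three equal-height bands (ventral,
ventro-dorsal, dorsal); remainder rows are assigned by where their
centre falls. The bands are defined per-slice on the mask extent rather
than on a fixed thoracic box — for a supine subject this follows the
lung as its shape changes along the chest, which is the reading we
adopted where the convention was ambiguous. The gradient
$(\mathrm{ventral} - \mathrm{dorsal})/\mathrm{ventral} \times 100$ is
applied to signed HU: a denser (less negative) dorsal lung with a
negative ventral mean yields a positive percentage.

**Ten-slice mode.** The sampled-slice protocol takes the most cranial
and caudal mask slices plus eight evenly spaced between them
(fractional positions round half toward the cranial end; collapsed
duplicates are backfilled with the nearest unused indices). Per-slice
linear densities (mL gas per mm, g per mm, mL volume per mm) are
interpolated linearly between slice centres and integrated by the
trapezoid rule over the full span, extending the end segments linearly
(clamped at zero) to the mask boundaries. The estimate is exact for
constant or linear cranio-caudal profiles; on smooth ellipsoidal
phantoms it stays within about 1% of the full-volume computation (3% is
the tested bound). A regression-based extrapolation variant exists in
the literature; we chose interpolation because it is exact on the
verifiable cases and has no free parameters. Whole-volume analysis is
the default; the ten-slice path is opt-in.

## Partitioned respiratory mechanics

Esophageal pressure (Pes) is the pleural-pressure surrogate that
separates lung from chest-wall mechanics. From an inspiratory and an
expiratory occlusion (each at least 5 s):

$$\Delta P_{rs} = P_{plat} - PEEP_{tot}, \quad
  \Delta P_{cw} = Pes_{insp} - Pes_{exp}, \quad
  \Delta P_L = \Delta P_{rs} - \Delta P_{cw},$$

and compliances $C = V_T/\Delta P$ per partition, so
$1/C_{rs} = 1/C_L + 1/C_{cw}$ holds identically — asserted on every
panel at $10^{-9}$. Plateau values are means over the final 0.5 s of
the occlusion, accepted only if consecutive 0.5-s blocks drift less
than 0.5 cmH2O/s (both defaults configurable; the protocol only
specifies the 5-s minimum).

**Compression cycles.** Chest compressions at ~102/min are separated
from ventilation at 10/min by a zero-phase 0.5–5 Hz Butterworth
band-pass (the compression fundamental is ~1.7 Hz, ventilation
0.17 Hz). Peaks above a prominence threshold — the larger of 1 cmH2O
and 25% of the band-passed IQR-based swing — delimit trough-to-trough
cycles; an apparent rate below 50/min is treated as "no compressions
detected" (nothing in a CPR protocol compresses that slowly; such peaks
are ventilation harmonics or filter transients), while a rate above
150/min sets a warning flag. Per-cycle minimum, maximum and swing of
raw Pes are computed after a gentle 10 Hz zero-phase low-pass so
broadband sensor noise does not bias the extrema; the reported ΔPes is
the epoch mean of per-cycle swings (the epoch display convention shows
one value per 5-min epoch; the aggregation itself is a package choice,
recorded here).

The occlusion test for catheter placement compares Pes and airway
pressure swings during compressions against a closed airway; the ratio
must fall in $[0.8, 1.2]$ as printed (the accompanying "10–20%"
phrasing is internally inconsistent; the numeric interval is what we
implement). The first second of the window is skipped so the resistive
settling transient does not enter the swing. Coronary perfusion
pressure is the time-coincident difference between diastolic aortic and
right-atrial pressure; during compressions the diastolic instant is the
aortic minimum in the decompression half of each cycle (the duty cycle
of the device), a choice we document because "diastole" has no ECG
definition during VF.

## Oxygen transport

Blood oxygen content is $1.34 \cdot Hb \cdot SO_2 + 0.003 \cdot PO_2$
(mL/dL); end-capillary blood is assumed fully saturated at the alveolar
oxygen tension $P_AO_2 = FiO_2(P_b - P_{H_2O}) - PaCO_2/RQ$ with
defaults $P_b = 760$, $P_{H_2O} = 47$ mmHg, $RQ = 0.8$. The source
protocol cites the venous-admixture equation without printing its
constants, so all six are explicit parameters recorded in every output.
The shunt fraction is

$$Q_s/Q_t = \frac{C_cO_2 - C_aO_2}{C_cO_2 - C_vO_2},$$

clipped to $[0,1]$ with a flag when measured panels are inconsistent
(rather than erroring: real panels can be). Delivery is
$DO_2 = CO \times C_aO_2 \times 10$ and uptake
$VO_2 = CO \times (C_aO_2 - C_vO_2) \times 10$. Reported hemoglobin
values of ~7–9 labelled g/L are read as g/dL (the printed unit is not
survivable; porcine-physiologic values are 7–9 g/dL), with the unit
recorded.

The blood-gas generator inverts this model exactly: given true shunt
$s$, cardiac output, Hb, FiO2 and true VO2, the linear pair
$C_aO_2 = s\,C_vO_2 + (1-s)\,C_cO_2$ and
$C_vO_2 = C_aO_2 - VO_2/(10\,CO)$ has a closed-form solution, and the
emitted saturations/tensions are chosen to reproduce those contents
exactly at zero noise — so analysis-side recovery of the shunt to
$10^{-9}$ is a guaranteed property, tested as such.

## Stereology

Histology class maps (airspace, acinar tissue, non-acinar tissue,
hemorrhage) are point-counted on a centered $\sqrt{n} \times \sqrt{n}$
regular lattice with half-pitch margin (default 100 points); a
random-offset mode exists for unbiased designs, but the centered grid
mirrors a fixed software overlay and is deterministic. Alveolar tissue
percentage subtracts non-acinar points from overall tissue; hemorrhage
is counted as its own class and excluded from "tissue" by default
(toggleable), since the class list that includes hemorrhage postdates
the tissue/airspace definition. Wet-to-dry and lung/body weight ratios
are simple guarded quotients.

## What the generators emulate — and what they do not

- **CT phantoms**: two ellipsoidal lungs in a thorax-like background
  (-1000 HU air, +40 HU soft-tissue rim, so masked analysis is honest
  about exclusion), a linear ventro-dorsal density gradient (dorsal =
  dependent, the second array axis by convention, reconfigurable), a
  uniform edema shift, and Gaussian HU noise. Defaults target the
  baseline regime near -549 HU; a shift of ~225 HU reproduces the
  post-CPR -324 HU regime. Truth (volume, gas, weight, band means,
  fractions) is computed from the noiseless field before noise is
  added. Not emulated: real parenchymal texture, vessels and airways,
  reconstruction kernels, beam hardening, segmentation error — passing
  recovery tests therefore demonstrates correctness of the arithmetic
  and conventions, not robustness to clinical segmentation quality.
- **Waveforms**: volume-controlled ventilation (500 mL, 10/min, I:E
  1:1, ZEEP) with linear inflation/deflation, unsynchronized with a
  raised-cosine compression pulse train (102/min, 50% duty cycle,
  amplitude in cmH2O of Pes — no published transfer maps the device's
  53 mm depth to pressure, so amplitude is a free parameter). Pes is
  baseline + volume/chest-wall-compliance + pulses; Paw adds resistive
  and lung-elastic terms and settles exponentially (τ = 0.25 s) into
  occlusion plateaus. The model is linear single-compartment: no
  intrinsic PEEP, airway closure, or flow limitation.
- **Blood gases**: exact Berggren forward model as above, optional
  Gaussian noise on emitted saturations/tensions.
- **Histology**: a smooth Gaussian random field (coarse iid noise,
  bilinear upsampling, correlation length = texture scale) thresholded
  at the empirical quantiles of the requested fractions, giving
  contiguous class blobs; the realized pixel fractions, not the
  requested ones, are the recorded truth.
- **Cohort**: a latent severity score per animal (evenly spread) jointly
  drives the post-CPR edema shift and gradient, compression amplitude
  (mechanical epochs stronger than manual), lung-compliance fall, shunt,
  wet-to-dry ratio, and histology airspace loss — so cross-modality
  associations are positive by construction, which the tests then
  verify the pipeline recovers. Mild per-animal anatomical variability
  (body mass 33 ± 4 kg, baseline density ± 8 HU, lung size ± ~1%) is
  kept deliberately small relative to the severity-driven contrasts.

## Numerical choices and problem sizes

Generators draw from one seeded RNG per call and restore the session
RNG state; all seeds are recorded in outputs, and identical
(parameters, seed) give bit-identical outputs. The cohort drivers under
`analysis/` use five animals, 48×44×36-voxel phantoms at 3 mm (≈600 mL
lungs), 100 Hz traces with five 5-min compression epochs, and 256²
histology images; the test suite uses smaller grids and shorter epochs
of the same shapes, with the headline recovery check run once at
256×128×64. These sizes were chosen so the full suite and the
acceptance script each complete in about a minute while leaving every
statistical check comfortably powered.

Known limitations: no DICOM writing, no automatic segmentation, no
hemodynamic ODE model behind the vascular channels (they are phase-locked
pulse templates for CPP logic only), no oxyhemoglobin dissociation curve
(saturations are inputs), and routine cohort statistics beyond Pearson
correlation and paired comparisons are intentionally left to external
tools via the tidy per-epoch tables the report emits.
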