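---
title: "Distinguishing prostaglandin isomers from silver-adduct MS3 product-ion ratios"
author: "pgms3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing prostaglandin isomers from silver-adduct MS3 product-ion ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgms3)
```

## The problem

PGE2, PGD2 and delta12-PGD2 are prostaglandin isomers that share the
elemental composition C20H32O5, so a single mass channel — m/z 459.1295 for
the silver-cationized ion [M+107Ag]+ — contains all three. Chromatography
can separate them but is unavailable in mass spectrometry imaging (MSI),
where each pixel yields one spectrum. The method implemented here separates
the isomers *spectroscopically*: after two stages of collision-induced
dissociation (MS3 via the water-loss ion, 459.13 → 441.12), three product
ions carry isomer information:

* **m/z 331.0096** (C12H16O4·Ag+, loss of C8H16O) — essentially specific to
  PGE2 (below 2% of base peak in the other two isomers);
* **m/z 333.2060** (C20H29O4+, loss of H2O + AgH) — produced by all three,
  but at sharply different yields (about 5% of base peak for PGE2 versus
  roughly 80% / 100% for PGD2 / delta12-PGD2);
* **m/z 341.0301** (C14H18O3·Ag+, loss of C6H12O + H2O) — specific to
  delta12-PGD2.

Monoisotopic 107Ag is used for cationization so the signal is not split
across the two natural silver isotopes. In an ion trap (where the
diagnostic scans are fast enough for imaging), 331.0096 is not resolved
from the isobaric 331.1905, but the two are strongly correlated with the
PGE2 channels, so the unresolved 331 channel remains usable.

**Relative abundance** of a channel always means its intensity divided by
the summed intensity of the three channels, so the triplet
(r331, r333, r341) lives on a simplex and is insensitive to the absolute
signal level.

## Mass engine

All mass arithmetic routes through one pinned table of monoisotopic
constants (`pg_atomic_masses()`; 107Ag = 106.905092 Da). For a singly
charged cation the electron mass is subtracted — a 1.2 ppm effect at
m/z 459 that is essential for sub-0.3-ppm agreement with published values:

```{r}
adduct_mz("C20H32O5", "107Ag")
ppm_error(331.0096, adduct_mz("C12H16O4", "107Ag"))
```

`assign_product_ion()` annotates product ions by enumerating neutral losses
as element-bounded subformulas of the precursor ion over C/H/O, plus
AgH-containing losses (the silver can leave as neutral AgH, leaving the
charge on the organic fragment, as for m/z 333.2060). Candidates within the
ppm tolerance are ranked by absolute mass error, with ties broken toward
the loss with fewer heavy atoms — the simplest chemistry wins. A
reproducibility note: recomputing the published product-ion table from
these constants reproduces ten of thirteen printed mass errors to within
0.2 ppm; the remaining three rows (m/z 333.0252, 397.1291, 413.1245) are
internally inconsistent in print — their published m/z, formula and ppm do
not satisfy the ppm definition under any atomic-mass convention, and in two
cases a one-digit change in the printed m/z restores consistency. The
package reports the recomputed values.

## The calibration model

Calibration mixtures spanning the 0–100% simplex (constant total
prostaglandin amount, three technical replicates each, measured by flow
injection) give one channel triplet per sample. Two least-squares fits form
the model (`fit_isomer_model()`):

1. a **second-degree polynomial surface**
   `%delta12-PGD2 = p00 + p10*x + p01*y + p20*x^2 + p11*x*y + p02*y^2`
   with `x = r331`, `y = r341`;
2. a **third-degree calibration curve** `r331 = c0 + c1*p + c2*p^2 + c3*p^3`
   with `p = %PGE2`.

Prediction (`predict()`) proceeds in the fixed order PGE2 →
delta12-PGD2 → PGD2: the cubic is inverted numerically at the measured
r331; the surface is evaluated at (r331, r341); and PGD2 is obtained by
closure, 100 minus the other two, so valid compositions sum to exactly
100.

### Numerical choices

* **Cubic inversion** uses the analytic roots (`polyroot`) restricted to a
  working range of [-10, 110]% — raw predictions outside it are removed
  (the composition is flagged invalid). Roots inside [0, 100] are preferred
  when present. If several admissible roots remain, the one nearest the
  grid-search minimizer of `|g(x) - r331|` (0.01-point grid) is selected,
  with the smaller root breaking exact ties. This makes the selection
  deterministic and testable against a pure grid-search oracle.
* **Unweighted** least squares; replicates enter as independent samples.
* Model coefficients are **never hard-coded or reused across
  acquisitions**: product-ion yields depend on the collision-energy
  settings, so training and prediction must share them. Models carry a
  settings tag that `predict_image()` verifies.
* Degenerate designs (fewer than 10 samples, no spread in r331 or %PGE2,
  collinear compositions) are rejected at fit time.

### Why the fit is not exact, even without noise

The channel intensities mix linearly in the isomer *amounts*, but relative
abundances are ratios, so each r-value is a rational function of the
composition. In particular r331 is not exactly a function of %PGE2 alone:
at fixed %PGE2 it varies with the PGD2/delta12-PGD2 split, because
delta12-PGD2 contributes more total diagnostic-channel signal (its extra
341 yield) than PGD2. The cubic is therefore an approximation even on
noiseless data — fitted R^2 is high (about 0.99) but below 1, and
inversion carries a composition-dependent bias of up to about two
percentage points in the interior of the simplex (under one point at the
pure corners). This mirrors the behaviour of the real calibration, where
the published curve fits with R^2 = 0.988 and hold-out errors of a few
percent at high signal. Exact recovery (R^2 = 1, error at solver
tolerance) is obtained only on model-consistent data, which is what
`make_polynomial_set()` generates for oracle testing.

### Cross-validation

`cross_validate()` repeats a random hold-out split (default 10% of samples,
50 iterations): fit on the remainder, predict the hold-out, compute a
root-mean-squared error per isomer, and average per isomer across
iterations. Splits are at the sample level (replicates may straddle the
split); the split RNG is seeded and the seed recorded. Because PGD2 is
obtained by closure it accumulates the errors of the other two predictions,
so its RMSE is expected to be the largest — a property the test suite
asserts.

## The synthetic-data generator

Real calibration solutions and tissue data cannot ship with a package, so
every stage is exercised against a forward model (`simulate_triplets()`):

* a **signature matrix** of per-isomer channel yields, each isomer
  normalized to its own base peak. The anchored entries follow the
  qualitative spectra described above (PGE2: 331 = 1, 333 = 0.05;
  PGD2/delta12-PGD2: 333 = 1; 331 at 0.02 in the non-PGE2 isomers). The
  yield of 341 from delta12-PGD2 (0.35) and the exact sub-2% placements
  are free parameters — no quantitative values are published — and are
  configurable.
* equal per-isomer ionization/fragmentation efficiency in mixing (no
  published efficiency factors; configurable through the signature).
* **noise**: multiplicative Gaussian (default CV 3%) plus additive
  Gaussian (default 1% of the total channel signal), clipped at zero.
  These defaults were chosen once so that fitted R^2 values land in the
  regime of the published fits (0.994 surface / 0.988 cubic) — they are
  tuned plausibility parameters, not measured instrument noise.
* `add_interference()` emulates a chemically complex matrix by injecting a
  non-negative background into chosen channels. The default reference is
  the channel's own intensity (up to 5%): the published validation of the
  diagnostic channels found them PG-specific in a brain-extract matrix, so
  residual contamination should scale with, and stay small relative to,
  the channel signal. A harsher mode referencing the summed three-channel
  signal is available (`reference = "total"`), under which the minor
  channels can be swamped several-fold and per-isomer errors exceed 5%.

What passing these tests shows — and does not show: the generator captures
the mixing structure, the noise floor and the closure geometry of the
method, so it validates the *algorithms* (fitting, inversion, closure,
filtering, assembly). It does not emulate chromatographic or electrospray
drift, isotope envelopes, detector saturation, or real matrix chemistry,
so quantitative error levels on real tissue are established by the
original measurements, not by these simulations.

## Imaging

Line scans interlace one high-resolution SIM scan (precursor m/z 459.1295
and the PGD2-d9 internal standard) with one ion-trap MS3 scan per duty
cycle. `assemble_grid()` indexes pixels by the MS3 cycle and samples SIM
channels at the nearest-in-time SIM scan (no alignment rule is published;
nearest-in-time is the natural choice for interlaced acquisition).
Oversampling across lines is not modelled: each line is an independent
pixel row.

Pixel width is stage speed × cycle period: 0.02 mm/s × 1.55 s = 31 um,
with the 100 um line step as pixel height. A note on units: a duty cycle
printed as "1.55 Hz" is only consistent with this pixel width if it means
a 1.55 s *period*; `grid_geometry()` therefore stores a period in seconds
and accepts a rate only through the explicit `duty_cycle_hz` argument.

Downstream filters follow the published processing rules:

* **tissue mask**: pixels with the 333.2 channel at or above 30 counts
  (inclusive boundary — the publication states only "threshold = 30"; the
  inclusive choice is documented here and in `tissue_mask()`);
* **S/N filter**: per channel, a pixel is included iff intensity/noise is
  strictly above 5 ("above 5"). No noise-estimation method is published;
  the default is a robust level — median plus MAD — over off-tissue
  pixels (at least 20 required), and the estimator is swappable
  (`noise_fun`);
* **one-point quantitation**: per-pixel analyte/standard ratio times the
  standard concentration (0.5 uM PGD2-d9 in the probe solvent);
* **prediction**: per retained pixel via the calibration model; a pixel
  failing any filter, or with a raw prediction outside [-10, 110]%, is
  invalid in all three fraction images. For rendering, valid values
  outside 0–100% are displayed as 0 (the stored values and validity flags
  are untouched).

ROI statistics (`roi_stats()`) are means and SDs over valid pixels —
per-pixel, not per-line (the publication does not say which; pixels are
the finer and more conventional unit). Pixel-to-pixel SDs in tissue are
dominated by biological heterogeneity and exceed the model's technical
RMSE.

## Problem sizes and reproducibility

The package's tests and the acceptance script run entirely on synthetic
data at modest sizes chosen to exercise every code path while keeping a
full run fast: a 16-composition simplex design × 3 replicates for
calibration (48 samples), 50-iteration hold-out cross-validation, a
20 × 32-pixel phantom with an off-tissue border and three tissue regions
(antimesometrial-pole-like at (35, 15, 50)%, epithelium-like, low-signal
mesometrial-pole-like), and 1000 random cases for the inversion oracle.
All randomness flows through explicit integer seeds; generated artifacts
record their seed.

## Known limitations

* The published polynomial coefficients are available only as figure
  images, so they cannot be compared directly; the package always refits
  from calibration data (which is also the scientifically correct use —
  coefficients are instrument- and CID-setting-specific).
* Only the three modelled isomers are predicted; minor isomers that share
  the product ions (e.g. 8-iso-PGE2) are outside scope, as are negative
  mode and sodiated adducts, isotope-pattern simulation and multiply
  charged ions.
* Profile-mode data must be centroided upstream; no peak picking is done.
* Uncertainty is summarized by hold-out RMSE only; no per-pixel error
  propagation is attempted.
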