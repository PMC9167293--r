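---
title: "Geometric-PCA optical stains and the azimuth-shift biomarker for deep-UV microscopy"
author: "duvstain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric-PCA optical stains and the azimuth-shift biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duvstain)
```

## The measurement and the model

Thin tissue sections imaged in transmission at deep-ultraviolet wavelengths
show strong label-free molecular contrast: nucleic acids absorb most
strongly near 255 nm, proteins near 280 nm, a 220 nm band carries mixed
absorption from many species, and a 300 nm band — off every endogenous
absorption peak — responds mainly to elastic scattering, a proxy for
nanoscale tissue architecture. A four-band transmittance cube therefore
gives every pixel a short spectrum whose *shape* encodes molecular
composition and whose *depth* encodes concentration.

duvstain works with these cubes as follows.

1. **Normalization.** Raw counts become transmittance by flat-field
   correction, T = (raw − dark)/(bright − dark), clipped to [0, 1.5]. The
   ceiling above unity tolerates shot noise on bright pixels without letting
   outliers dominate later statistics. Pixels where bright ≤ dark are marked
   invalid and carried in a validity mask that excludes them from every
   downstream pooling step, histogram and biomarker.
2. **Channel registration.** Chromatic shifts in a fixed transmission
   optical train are predominantly translational, so each band is aligned to
   a reference band by the phase-correlation peak (integer shift, with
   optional parabolic sub-pixel refinement applied via the Fourier shift
   theorem). Border pixels that fall off the frame are invalidated. A
   constant band, or one whose normalized correlation peak falls below 0.1,
   is left unshifted with a warning rather than moved to a random maximum.
3. **One pooled PC basis.** Pixel spectra from representative regions are
   pooled (with an optional seeded uniform subsample to cap memory) and
   decomposed by mean-centered PCA. A single basis serves the whole cohort:
   refitting per patient would rotate the angular coordinate system under
   the biomarker and destroy comparability.
4. **Spherical geometry.** Scores on a PC triplet — (1,2,3) or (2,3,4) —
   become azimuth θ = atan2(y, x), elevation φ = atan2(z, √(x²+y²)) and
   radius R. The two angles capture spectral shape, hence composition; the
   radius is a relative concentration measure. Azimuth is defined as 0 at
   the poles and at the origin so the conversion is total and deterministic.
5. **Optical stains.** Images are colorized in HSV space: hue from an angle,
   value from the percentile-clipped radius, saturation fixed at 1. The
   `elevation_123` stain gives the strongest nuclear contrast (nuclei sit at
   negative elevation, where the inverted 255 nm component dominates), the
   `azimuth_234` stain contrasts protein against nucleic acid without the
   scattering component, and the `malignancy_123` stain — azimuth over PCs
   1–3 — maps scattering contributions relative to the two absorbers.
6. **The biomarker.** For each patient and gland class, all labeled pixels
   are pooled across regions into one cumulative 2D angle histogram, the
   histogram is integrated over elevation, and the center of mass (CoM) of
   the azimuth marginal is recorded. Shifts are reported relative to the
   same patient's benign glands; the benign shift is identically 0. A
   patient whose cancerous classes all shift negative is called the
   aggressive phenotype, all positive the non-aggressive phenotype, mixed
   signs indeterminate.

## Why the sign conventions matter

Eigenvector signs are arbitrary, but every azimuth downstream depends on
them, so `fixSigns()` applies a fixed convention anchored in the components'
characteristic shapes on 4-band deep-UV spectra: PC1 is kept unipolar
non-negative (overall attenuation), PC2 positive at 280 nm (protein peak),
PC3 negative at 255 nm (inverted nucleic-acid peak), PC4 positive at
280 nm. Band lookup is by nearest wavelength, so the rules survive small
changes in band centers. The convention is idempotent and recorded in the
serialized basis.

## Centering, PCA domain, and other open choices

Three genuinely open design points are resolved as follows, with the
alternative kept available:

* **Centered scores** (default): projections subtract the pooled mean
  spectrum, so the radius measures deviation from the cohort-average
  composition. Uncentered projection is available via
  `projectCube(..., center = FALSE)`.
* **Transmittance domain** (default): the PCA operates on transmittance,
  where the components' shapes read directly as (inverted) absorption
  peaks; `mode = "optical_density"` transforms spectra to
  −log10(max(T, 1e-4)) first, which linearizes Beer–Lambert mixing. The
  fitted domain is stored in the basis and applied automatically at
  projection time.
* **Linear center of mass** (default): the azimuth CoM is the plain
  weighted mean over bin centers, matching a plain center-of-mass reading;
  angular distributions of well-registered tissue sit well inside (−π, π].
  If more than 1% of a marginal's mass falls within 5° of the ±π seam the
  function warns, and a circular mean (`method = "circular"`) is available.
  The azimuth mode (peak location) is reported alongside the CoM as a
  secondary summary.

Histograms default to 360 × 180 bins (1° resolution) and count weighting;
radius weighting is a switch. Hue ranges default to the [1st, 99th]
percentile of the rendered image's own angle distribution, which maximizes
contrast per image; a fixed range must be passed when stains from different
images are to be compared side by side. Value scaling clips the radius at
its [1st, 99th] percentiles before mapping to [0, 1].

## What the phantom emulates — and what it does not

`generatePhantom()` renders non-overlapping circular glands (an annular,
nucleic-acid-rich epithelium around an empty lumen) on a dark, protein-rich
stromal background, using Beer–Lambert mixing of three endmembers: a
nucleic-acid-like absorber peaking at 255 nm, a protein-like absorber
peaking at 280 nm (both near zero at 300 nm), and a power-law scattering
attenuation (λ/220)^(−b) with b = 2, within the range typical of tissue.
Defaults: benign epithelium concentrations (c_NA, c_prot, s) =
(0.55, 0.45, 0.50), stroma (0.40, 1.30, 0.90), 4% per-pixel concentration
jitter for cellular heterogeneity, and 0.5% additive Gaussian transmittance
noise. The dark stroma places the pooled mean well below the epithelial
brightness, so gland pixels sit at interior azimuths (near 0 rather than
the ±π seam), as real angular distributions do.

The two phenotype presets act on the cancerous classes only, with benign
identical in both. Grade multipliers k = 1.12, 1.20, 1.30 for G3, G4, G5:

* `non_aggressive`: absorbers scale by k, scattering unchanged — cancer
  glands gain nucleic-acid and protein content, rotating their azimuth
  positive relative to benign;
* `aggressive`: scattering scales by k and absorbers by 1/k — the
  composition shifts toward scattering at a similar total attenuation,
  rotating azimuth negative. The fraction reading matters: raising
  scattering alone darkens pixels much as raising absorbers does, moving
  both presets the same way around the pooled mean; it is the compositional
  exchange that produces the opposite-signed shift the aggressive phenotype
  is defined by.

The phantom validates sign and ordering of the biomarker, not magnitude:
it has no nuclear texture, no diffraction or PSF blur, no mosaic seams, no
annotation error, and its class compositions are homogeneous per gland. A
perfect sign-recovery rate on phantoms therefore demonstrates that the
pipeline's geometry and bookkeeping are correct, not that real tissue
separates this cleanly.

## Numerical choices and degenerate inputs

* Transmittance is clipped to [0, 1.5] after flat-fielding and after noise.
* The optical-density transform floors T at 1e-4 before the logarithm.
* Rank-deficient spectra pools are legal: trailing explained-variance
  ratios are zero (never NaN), and missing rotation columns are completed
  to an orthonormal basis.
* Histogram bins are uniform over (−π, π] × [−π/2, π/2]; the elevation
  minimum −π/2 folds into the first bin so mass conservation is exact.
* Zero-radius pixels render black; equal angles always produce equal hue
  (the HSV→RGB conversion is done in double precision precisely so this
  identity is exact).
* Phantom gland placement uses rejection sampling and fails with an
  explicit error when the requested geometry cannot fit.
* Generators and subsamplers set the RNG locally and restore the caller's
  stream.

## Problem sizes

The shipped tests exercise the full chain at sizes a laptop handles in
seconds: PCA oracle checks on matrices up to 1000 × 4, geometry round trips
on 10⁶ points, variance-concentration checks on a 512 × 512 phantom
(~2.6 × 10⁵ spectra), and phenotype sign recovery over 20 seeded 128 × 128
phantoms per preset. The same code paths scale to full-size cubes; the 4 × 4
covariance makes the basis fit cheap at any pixel count, and pooling is the
only memory-bound step (capped by `maxPixels`).

## Known limitations

Gland segmentation is assumed given (manual annotation masks); no automated
segmentation is provided. Mosaic stitching of tiled acquisitions and
whole-slide formats are out of scope, as are virtual-H&E rendering and any
cross-patient statistical testing. The linear CoM is the primary summary
and is only meaningful while the azimuth distribution stays away from the
±π seam; the seam warning and the circular option exist for data that do
not.
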