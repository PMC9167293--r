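# duvstain

Label-free phenotyping of tissue sections from multispectral deep-UV
transmission microscopy.

## The problem

Thin prostate-tissue sections imaged in transmission at four deep-UV bands —
220, 255, 280 and 300 nm — carry endogenous molecular contrast without any
chemical stain: nucleic acids absorb near 255 nm, proteins near 280 nm, and
the 300 nm band responds mainly to elastic scattering, a surrogate for
nanoscale tissue architecture. duvstain turns such four-band transmittance
cubes into

* **optical stains** — false-color HSV renderings built from a geometric
  representation of principal component analysis, which highlight nuclei,
  stroma and a glandular malignancy continuum; and
* a **quantitative biomarker** — the benign-referenced azimuth
  center-of-mass shift of each gland class, whose sign separates an
  aggressive from a non-aggressive glandular phenotype.

It is aimed at researchers in label-free digital histopathology who have
multichannel TIFF cubes, region annotations, and a need for a reproducible,
testable implementation of this pipeline.

## The method in brief

Pooled pixel spectra **x** ∈ R⁴ are decomposed by mean-centered PCA with a
deterministic sign convention (PC1 unipolar, PC2 positive at 280 nm, PC3
negative at 255 nm, PC4 positive at 280 nm). Scores on a PC triplet are
converted to spherical coordinates

θ = atan2(Proj₂, Proj₁), φ = atan2(Proj₃, √(Proj₁² + Proj₂²)), R = ‖Proj‖,

so the angles encode spectral shape (composition) and the radius relative
concentration. Images are colorized with hue = angle, value = radius,
saturation = 1. For the biomarker, pixels of each gland class are pooled per
patient into a cumulative 2D angle histogram over PCs 1–3, integrated over
elevation, and summarized by the azimuth center of mass

CoM = Σⱼ θⱼ wⱼ / Σⱼ wⱼ ,

reported relative to the same patient's benign glands. Negative shifts in
all cancerous classes call the aggressive phenotype; positive shifts the
non-aggressive one.

A seeded Beer–Lambert phantom generator — gland/lumen/stroma geometry,
nucleic-acid-like and protein-like absorbers plus power-law scattering —
makes every stage testable without real data.

## Worked example

```r
library(duvstain)

ph    <- generatePhantom(phantomSpec(preset = "aggressive", seed = 7))
basis <- fitPCA(poolSpectra(ph$cube), wavelengths = wavelengths(ph$cube))
basis
#> PCBasis: 4 bands (220, 255, 280, 300 nm), mode = transmittance, fit on 36864 spectra
#>   explained variance ratio: 0.9940 0.0047 0.0011 0.0002

fld    <- toSpherical(projectCube(ph$cube, basis, c(1L, 2L, 3L)))
shifts <- relativeShifts(perClassCoM(fld, ph$annotation))
print(shifts, digits = 3)
#>   patient_id gland_class com_azimuth mode_azimuth n_pixels relative_shift
#> 1 phantom-01      benign       0.332        0.323     2031          0.000
#> 2 phantom-01          G3       0.256        0.253     1325         -0.076
#> 3 phantom-01          G4       0.215        0.218     1315         -0.117
#> 4 phantom-01          G5       0.172        0.166     2030         -0.160
classifyPhenotype(shifts)
#> [1] "aggressive_phenotype"
```

The first three principal components carry 99.98% of the pooled variance,
so the 3-PC spherical representation loses almost nothing. Every cancerous
class of this aggressive-preset phantom shifts its azimuth CoM negative
relative to benign (−0.076, −0.117, −0.160 rad for G3/G4/G5, increasing in
magnitude with grade), and the sign rule calls the aggressive phenotype.
Rendering `renderStain(fld, stainScheme("malignancy_123"))` writes the
corresponding malignancy map; `runPipeline(pipelineConfig(...))` chains
simulation, basis fitting, all three stains, the biomarker table and a hash
manifest, and `inst/scripts/duvstain` exposes the same stages as shell
subcommands (`simulate`, `fit-pca`, `stain`, `biomarker`, `run`).

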