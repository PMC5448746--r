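# riceCanopy

Measurement, 3D reconstruction and virtual clipping of rice canopy
architecture.

Rice grows in dense transplanted stands whose stems and leaves shelter one
another, which makes whole-canopy 3D digitising slow or impossible. This
package implements the low-cost alternative used in functional–structural
plant modelling: locate each subunit in situ (hill position on the planting
grid, stem surface points and leaf azimuths from a cylindrical
coordinatograph), detach it, photograph it on a calibrated bench, and
reassemble everything into a 3D *digital plant architecture* from which
canopy traits are extracted *in silico*. It is aimed at crop physiologists
and phenotyping groups who need leaf area, leaf angle and light profiles of
real canopies without laser scanners.

The pipeline:

* **Calibration** — pixel `(i, j)` maps to real cm through one binary
  quadratic per axis, `x = a₁i² + b₁ij + c₁j² + d₁i + e₁j + f₁` (and
  likewise `y`), twelve least-squares coefficients per bench
  (`fit_calibration()`).
* **Image analysis** — excess-green graying `G − R/3 − B/3`, Otsu
  binarization (block-adaptive for the large tiller frames), organ
  separation along a robust vertical stem corridor, then stem length/radius
  profiles, leaf nodes, midrib quadratics `x(l), y(l)` and 6th-degree blade
  half-width polynomials (`analyze_leaf_image()`, `analyze_tiller_image()`).
* **Reconstruction** — stem axes from radius-corrected surface points
  (`|top − bottom| = S_l` exactly), leaf nodes interpolated along the axis,
  midribs lifted by azimuth and stem tilt, blade edges offset along the
  venation-plane normal; renderable OBJ/PLY scenes
  (`reconstruct_architecture()`, `build_scene()`, `export_mesh()`).
* **Virtual blade (virtual clipping)** — leaves divide into `fnum` fragments
  along the midrib; parallel blade surfaces (horizontal planes, concentric
  cylinders round the hill axis, or a voxel grid) collect fragment areas by
  midpoint. Vertical/radial/voxel area densities, azimuth and inclination
  distributions, and Beer-law light interception profiles
  (`area_profile_z()`, `area_profile_radial()`, `area_voxel()`,
  `azimuth_distribution()`, `inclination_profile_z()`, `light_profile_z()`),
  with `LIC(n) = 1 − PSAREA(n)/G` and
  `LID(n) = PAR₀ · Π LIC(i)` over the layers above `n`.
* **Synthetic module** — a parametric canopy generator with full ground
  truth plus leaf/tiller photograph renderers, so the entire pipeline is
  testable end to end without field data (`generate_architecture()`,
  `render_leaf_image()`, `render_tiller_image()`,
  `sample_canopy_surface()`).

## Worked example

```r
library(riceCanopy)

arch <- generate_architecture(plant_template(seed = 42))
arch
#> <digital_architecture> 8 hills, 80 tillers, 320 leaves
#>   block 2 x 4 hills, rs = 20 cm, ps = 20 cm

prof <- area_profile_z(arch, fnum = 100, Dns = 5)
round(as.data.frame(prof)[6:12, ], 4)
#>    interval z_lo z_hi      area area_density area_pdensity
#> 6         6   25   30   99.5965       0.0062             0
#> 7         7   30   35  494.6834       0.0309             0
#> 8         8   35   40  989.7868       0.0619             0
#> 9         9   40   45 1164.5949       0.0728             0
#> 10       10   45   50 1151.8929       0.0720             0
#> 11       11   50   55 1196.6498       0.0748             0
#> 12       12   55   60 1043.5806       0.0652             0
```

The canopy holds about 10 090 cm² of leaf over the 8-hill block
(leaf area index 3.15), concentrated between 35 and 75 cm height;
`area_density` is cm² of leaf per cm³ of canopy slab under the printed
`Area(n)/(Dns·pm·rs·ps)` normalization, and `area_pdensity` rescales it to
integrate to one.

Light interception under a sun at 60° altitude:

```r
lz <- light_profile_z(arch, fnum = 100, Dns = 5,
                      sun = sun_config(60 * pi / 180, pi, PAR0 = 1))
round(as.data.frame(lz)[c(3, 8, 13, 18), ], 3)
#>    interval z_lo z_hi     area  psarea   lic   lid
#> 3         3   10   15    0.000   0.000 1.000 0.215
#> 8         8   35   40  989.787 436.107 0.864 0.269
#> 13       13   60   65 1111.625 505.720 0.842 0.643
#> 18       18   85   90  135.555  65.973 0.979 0.996
```

`psarea` is the sun-projected leaf area of the layer, `lic` the fraction of
light it transmits, and `lid` the relative light reaching it: essentially
full daylight at 85–90 cm, 64 % at 60 cm, and 22 % in the lowest layers.

A command-line interface wrapping the same functions ships as
`inst/exec/ricecanopy` (`simulate`, `calibrate`, `analyze-leaf`,
`analyze-tiller`, `reconstruct`, `traits`); run it with `--help` for the
config schema.

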