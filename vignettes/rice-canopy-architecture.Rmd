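---
title: "Measuring, reconstructing and virtually clipping rice canopy architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring, reconstructing and virtually clipping rice canopy architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceCanopy)
```

## The measurement problem

Rice grows in dense transplanted stands in which stems and leaves shelter one
another, so whole-canopy 3D digitising (laser scanning, magnetic digitisers)
is slow, expensive, or simply blocked by occlusion. The alternative this
package implements is a *location--separation--measurement* workflow: each
subunit of the canopy is first located in situ with cheap bench tools, then
detached and measured flat.

* A hill (one transplanted clump) is located by its row/column position on
  the planting grid, with row spacing `rs` and plant spacing `ps` (cm).
* A tiller's stem is located by a cylindrical coordinatograph, which records
  a few points on the outward stem surface as (polar radius, azimuth,
  height) around the hill axis, plus the azimuth of each leaf's midrib.
* The tiller and its detached leaves are photographed on calibrated benches;
  image analysis yields the stem length and radius profile, each leaf's node
  position and 2D midrib curve, and each blade's width profile.

From those records a 3D *digital plant architecture* is assembled, and
canopy traits are extracted by *virtual clipping*: partitioning space with
mathematical blade surfaces instead of physically cutting layers.

## Image analysis

**Calibration.** Each bench camera is calibrated with a printed grid. Pixel
`(i, j)` (column, row) maps to real cm coordinates through one binary
quadratic per axis,

$$x = a_1 i^2 + b_1 ij + c_1 j^2 + d_1 i + e_1 j + f_1,$$

and likewise for $y$, twelve coefficients fitted by least squares
(`fit_calibration()`). The design is centred and scaled internally so pixel
indices in the thousands cause no conditioning trouble; a Jacobian sign check
warns if the fitted map folds inside the calibrated region. The *pixel
pitch* (local scale of the map) serves as the natural resolution bound
$\varepsilon$ for every binning operator below.

**Segmentation.** Plant tissue is separated from the background by the
excess-green gray value $G - R/3 - B/3$ (clamped at zero: the formula can go
negative on non-green pixels, and suppressing those is its evident purpose),
followed by Otsu's threshold. Leaf photographs use one global threshold and
a $3\times3$ average filter re-thresholded at 0.5. Tiller photographs span a
much larger field, so illumination varies: the frame is split into a
$4\times4$ grid of blocks (edge-padded when the dimensions do not divide),
each thresholded on its own, then smoothed with a $2\times2$ average filter.
A block's own Otsu split is only trusted when it looks genuinely bimodal —
a high between-class variance ratio, or a moderate one with a small
foreground fraction. The caveat matters: a block containing *no* plant under
an illumination ramp still shows a decent between-class ratio, but its split
covers half the block, whereas plant organs are thin. Untrusted blocks
inherit the mean trusted threshold of their block-row (the same illumination
level).

**Leaf shape.** The leaf mask is rotated so the vein runs along the abscissa
(principal axis of the second-moment matrix; the designated base edge breaks
the sign ambiguity), shifted so the base centre is the origin, and the width
$L_w(L_l) = \max(y) - \min(y)$ is read per abscissa bin of one pixel pitch,
plus one pitch because a pixel covers its pitch rather than only its centre.
Half-widths are fitted by a 6th-degree polynomial in the arc distance $l$
from the node (fitted on the scaled abscissa $l/L$ for conditioning, then
mapped back); the constant term absorbs the fit residual.

**Tiller geometry.** The stem corridor is a robust vertical line through the
per-row median columns of the mask (an M-estimator line restricted to a
window around the occupancy peak, so leaves cannot drag it), with corridor
width twice the median stem half-width so the tapered stem base stays
inside. Mask pixels in the corridor form the stem — reduced to its largest
connected body, so leaves crossing the corridor above the stem tip are not
absorbed; everything else splits into leaf components ordered by node
height. Stem length is the height extent; the radius at height $z$ is half
the horizontal extent of the one-pitch bin (again plus a pitch: a
single-pixel column reads half a pitch). Each leaf's node is its point
nearest the stem axis; the midrib is the mean height per one-pitch radial
bin, shifted to the node, parameterised by cumulative arc length and fitted
by two quadratics $x(l), y(l)$.

Two numerical caveats are worth recording. First, for strongly drooping
blades the radial coordinate stops being monotone along the blade and the
binned midrib becomes multivalued; the fit then covers the binned means only
and the result is flagged (`multivalued` attribute). Second, base and
dropping angles are *not* read off the global quadratic: a least-squares
quadratic over the whole blade biases its endpoint derivatives on strongly
bent leaves. `leaf_angles()` instead fits local quadratics over a short
gauge window at each end (default `min(6, 0.3 L)` cm), skipping the few
millimetres next to the corridor cut where blade-tube pixels from a range of
arc positions mix, and evaluates the base derivative at the node.

## Lifting to 3D

* **Stem axis.** Each coordinatograph surface point is corrected to an axis
  point by subtracting the stem radius at its height before the polar to
  Cartesian conversion; a 3D line is fitted (total least squares for more
  than two points), the bottom endpoint is the ground intersection, and the
  top endpoint lies exactly one stem length along the upward unit direction,
  so $\lvert \mathrm{top} - \mathrm{bottom}\rvert = S_l$ identically.
* **Leaf node.** The node sits on the axis at fraction $y/S_l$ — for a
  vertical stem this is simply height $y$ — plus the radial offset
  $x(\cos\theta, \sin\theta, 0)$ at the leaf azimuth $\theta$. The
  image-frame radial offset is treated as non-negative; the azimuth carries
  the direction.
* **Midrib.** $X = x(l)\cos\theta + x_{ln}$, $Y = x(l)\sin\theta + y_{ln}$,
  $Z = z_{ln} + y(l)\, z_t/S_l$: the radial run rotates to the azimuth and
  the height run scales by the stem tilt factor, starting at the node (the
  $z_{ln}$ start is required for leaves to attach to their stems in any
  rendered scene).
* **Blade edges.** The venation-plane normal is the cross product of the two
  midrib chords (first-to-middle, middle-to-last); each midrib sample is
  offset by $\pm$ the local half-width along it, so the total blade width
  equals the fitted width. A perfectly straight midrib has a zero cross
  product; the fallback normal is horizontal and perpendicular to the chord.

Scenes (`build_scene()`) represent each stem as a closed 12-segment cylinder
at the mean radius and each blade as a two-strip triangle ribbon between the
edge curves, exportable as ASCII OBJ or PLY.

## Virtual clipping

Solving for the exact intersection of every blade surface with every leaf
surface is what the method deliberately avoids. Instead each leaf is divided
into `fnum` fragments on an equal-$l$ grid; fragment $i$ carries the
trapezoid area $(l_{i+1}-l_i)(W(l_{i+1})+W(l_i))/2$ with $W = 2\times$
half-width, the midpoint of its midrib segment, the segment's four-quadrant
azimuth, and its inclination $\arcsin(|\Delta z| / |\Delta|)$. A fragment
belongs *wholly* to the interval containing its midpoint — the fragment
approximation that replaces surface-intersection clipping. Interval indices
are 1-based with boundaries falling upward, guarded against floating-point
noise by rounding the index ratio to nine decimals.

* **Vertical profile** (`area_profile_z()`): interval
  $\lfloor \bar z / D_{ns}\rfloor + 1$; density
  $\mathrm{Area}(n) / (D_{ns}\, pm\, rs\, ps)$; probability density further
  divided by the total area, so it integrates to one.
* **Radial profile** (`area_profile_radial()`): concentric cylinders around
  the hill axis; density divides by the ground-plane annulus area
  $\pi((nD_{ns})^2 - ((n-1)D_{ns})^2)$ and the hill count. The interval
  index uses the *horizontal* distance of the fragment midpoint from the
  hill axis: cylindrical sections around a vertical axis are at constant
  horizontal distance, and the annulus normalization only makes sense for
  that convention.
* **Voxels** (`area_voxel()`): each fragment splits width-wise into four
  strips of a quarter of its area, with centres interpolating between the
  two edge midpoints at cross-width weights 1/8, 3/8, 5/8, 7/8; x/y indices
  come from the strip centre in canopy coordinates and the z index from the
  midrib midpoint.
* **Orientation** (`azimuth_distribution()`, `inclination_profile_*()`):
  area-weighted histograms and means. Empty intervals report `NA` for ratio
  quantities, never a fake zero.
* **Light** (`light_profile_z()`): each fragment projects
  $f_{area}\,\lvert A \rvert$ with
  $A = \cos\theta_{sun}\cos\theta_{leaf} +
  \sin\theta_{sun}\sin\theta_{leaf}\cos(\varphi_{sun}-\varphi_{leaf})$ — the
  absolute value because a projected area is unsigned even when the element
  is lit from behind. The layer interception coefficient is
  $1 - \mathrm{PSAREA}(n)/G$ with $G$ the ground area of the sampled block,
  $(rows \cdot rs)(cols \cdot ps)$; a raw plant-count normalization is kept
  behind `normalization = "count"` for comparison, but an interception
  coefficient must compare projected leaf area to ground area to be
  dimensionless. Relative light density attenuates top-down,
  $\mathrm{LID}(n) = \mathrm{PAR}_0 \prod_{i \text{ above } n}
  \mathrm{LIC}(i)$, the Beer-law layer product. A layer whose projected area
  exceeds the ground area would give a negative coefficient; it is clamped
  at zero with a warning.

Defaults are `fnum = 100` and `Dns = 5` cm — the setting at which the
vertical profile is stable: with coarse fragments (`fnum = 10`) and fine
sections (`Dns = 1` cm) the profile becomes visibly ragged, which
`profile_sensitivity()` reproduces as an overlay figure. 36 azimuth sectors.

## The synthetic generator

`generate_architecture()` produces canopies with full ground truth so every
operator can be tested end-to-end. The defaults describe a transplanted
stand around heading: a 2 x 4 hill block at 20 cm x 20 cm spacing, 10
tillers per hill, 4 expanded blades per tiller, stem lengths
$\mathcal N(65, 6^2)$ cm with mild tilt (sd 5 degrees), blade lengths
$\mathcal N(32, 6^2)$ cm, maximum half-widths $\mathcal N(0.75, 0.1^2)$ cm,
base angles 25--45 degrees from vertical, and uniformly random azimuths;
the resulting leaf area index of about 3 is typical for that stage. The
half-width template is $h(s) \propto s(1-s)(2-s)$, $s = l/L$: widest about
42% from the base and ending in a *simple* zero — a pointed blade with a
finite apex angle. (A double root at the tip would keep the blade sub-pixel
wide for its last centimetre, which no finite-resolution measurement could
resolve — a degenerate geometry rather than a hard test case.) The template
is exactly representable in the 6th-degree family the shape fit uses, so
refits have an attainable truth. Stems carry coordinatograph surface points
constructed consistently with the known axis and radius profile, with
optional measurement noise.

Renderers close the imaging loop: leaf photographs are rasterised through
the true calibration (anti-aliased by 3 x 3 supersampling, optionally
through a quadratic distortion map), tiller photographs paint each blade as
a tube of discs around its midrib on alternating sides of the stem, with an
optional top-to-bottom illumination ramp strong enough that no global
threshold separates plant from background. Tiller rendering uses a
scale-only calibration: rasterising through a distorted map would require
inverting the quadratic per pixel, and distortion handling is exercised
where it matters, on the leaf bench and the calibration grids. Renderers
also report the *certain* foreground (pixel centres at least half a pixel
inside an organ); the half-pixel boundary band is genuinely ambiguous at
raster scale and is excluded from recall checks.

What the generator deliberately does not emulate: occlusion between organs
beyond a warning threshold (real tillers are arranged to be separable before
photographing, and an occlusion stress mode exists but extraction is not
guaranteed there), background clutter and non-studio lighting, leaf sheaths
and panicles, and blade twist (the venation plane is a single plane per
leaf). Passing tests therefore demonstrate the correctness of the operators
and the internal consistency of the pipeline, not robustness to field
photography.

One representational caveat: generated midribs are quadratics in their
*parameter*, while extraction refits quadratics in measured *arc length*.
The two families coincide only approximately (a quadratic cannot have unit
speed), which is why angle validation reads tangents locally rather than
comparing raw coefficients, and why the midrib-coefficient recovery test
uses a gently curved blade where parameter and arc length nearly agree.

## Numerical choices and degenerate inputs

* $\varepsilon$ for all binning operators = one pixel pitch, the resolution
  bound of the data; widths and heights measured from pixel spans add one
  pitch (a pixel covers its pitch).
* Interval boundaries fall upward (`floor` convention), with a nine-decimal
  rounding guard so exact boundary values are stable under floating point.
* Empty canopies give all-zero area profiles, `NA` inclinations, and a light
  profile equal to PAR0 everywhere.
* Constant images binarize to empty masks with a warning; masks with
  multiple components are rejected by the single-leaf extractor with advice
  to label first; fewer than three midrib bins is a fit error.
* Archives serialize with 17 significant digits; derived 3D curves are not
  stored and are recreated deterministically by `reconstruct_architecture()`.

Test problem sizes: the default study canopy (8 hills, 80 tillers, 320
leaves, 32 000 fragments at `fnum = 100`); a 100 000-point Monte-Carlo
surface sample for the profile oracle; 40 rendered leaves at 0.015 cm/px
and 8 rendered tillers at 0.05 cm/px for the imaging round trips; 100
random coefficient sets for calibration recovery.

## Known limitations

* The fragment approximation misassigns the parts of a fragment that truly
  straddle a section boundary; the error shrinks with `fnum` and is
  invisible next to Monte-Carlo noise at the default settings, but coarse
  fragments with fine sections are unreliable by construction.
* The light model is a single-direction Beer-law product: no scattering, no
  diffuse sky integration, no within-layer mutual shading geometry.
* Organ separation assumes an approximately vertical stem and separable
  leaves; heavily occluded tillers are flagged, not solved.
* The radial profile treats each hill's axis as vertical at its origin;
  strongly leaning hills would need a tilted-axis extension.
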