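---
title: "The anchoring model: placing 2D brain sections in 3D atlas space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The anchoring model: placing 2D brain sections in 3D atlas space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasanchor)
```

## The problem

Serial microscopic sections of rodent brains are routinely cut at
orientations that deviate from the standard coronal, sagittal or
horizontal planes of a 3D reference atlas. Assigning anatomical location
to features in those images by comparison with 2D atlas plates is then
inaccurate. The approach implemented here registers each section image to
an *arbitrary oblique plane* of the atlas by an affine placement, without
deforming the section image itself: instead, a matching atlas plate is
resampled from the volume and stretched over the image.

## The anchoring model

A section image of `w x h` pixels is placed in the atlas by three vectors
in atlas *voxel* coordinates:

* `o` — from the atlas origin to the image's top-left corner,
* `u` — from `o` to the top-right corner (the horizontal edge),
* `v` — from `o` to the bottom-left corner (the vertical edge).

Any pixel maps to a continuous voxel coordinate by the weighted sum

$$ \mathbf{p}(x, y) = \mathbf{o} + \frac{x}{w}\,\mathbf{u} + \frac{y}{h}\,\mathbf{v}, $$

so the four image corners land exactly on `o`, `o+u`, `o+v`, `o+u+v`.
The weights are `x/w`, not `x/(w-1)`: pixel `w-1` therefore maps slightly
short of `o+u`, a deliberate property of the interchange convention that
this package reproduces literally rather than "correcting". Whether the
original tools sample pixel centres (`(x+0.5)/w`) is not documented
anywhere we know of; we follow the printed `x/w` form.

The voxel frame is RAS: origin at the bottom-left corner of the most
anterior coronal plane, x left→right, y posterior→anterior, z
inferior→superior. Physical stereotaxic coordinates come from published
4×4 affines stored verbatim (row-vector convention): Allen CCFv3 output
is in µm with PIR axis order, Waxholm Space rat output in mm with RAS
order. The matrices are *not* re-derived from resolution constants — the
Allen one encodes an axis reordering that a scale-and-offset derivation
would get wrong — and results carry their axis labels so PIR/RAS mix-ups
are visible. The Waxholm matrix implies 0.0390625 mm voxels; the commonly
quoted "40 µm" resolution is a rounded figure, and the matrix is treated
as authoritative.

### Poses and tilt angles

Anchoring vectors are the canonical representation; for human
interaction the same plane is more naturally described by a centre, a
dorsoventral (DV) and a mediolateral (ML) tilt angle, and two scale
factors. No published definition of the angle math exists, so this
package *declares* one: the plane normal is proportional to
`(-tan ml, 1, -tan dv)`, which makes the normal's sagittal-projection
angle exactly `dv` and its horizontal-projection angle exactly `ml`;
`u` stays horizontal (no z component). Positive DV tilts the image top
toward anterior, positive ML tilts the image-right edge toward anterior;
negate the angles to match the opposite convention. With both angles
zero, scales one and the centre on the mid-coronal axis, the plane is
the default coronal plane `o = (0, y0, Nz)`, `u = (Nx, 0, 0)`,
`v = (0, 0, -Nz)` — image left is the subject's left, image top
superior. `pose_to_anchoring()` and `anchoring_to_pose()` are exact
mutual inverses for planes expressible in this convention; planes tilted
90° or more from coronal have no pose and raise an error.

## Atlas plates

`render_slice()` resamples a volume along a plane at the native atlas
resolution: plate dimensions are `round(|u|) x round(|v|)` (one plate
pixel per voxel along each edge, clamped to at least 1), and plate pixel
`(i, j)` samples the volume at `o + (i/c_w) u + (j/c_h) v` — the same
weight convention as the pixel mapping, kept deliberately consistent so
that the axis-aligned case reduces to direct array extraction (our
strongest oracle; note the convention places row `j = 0` of a
full-extent default plane one voxel outside the grid, which renders as
background). Position mapping between the original image and its plate
is a separable scaling `c_x = x·c_w/w`, `c_y = y·c_h/h`.

Sampling is nearest-neighbour by default, rounding half up per axis
(`floor(c + 0.5)`) — the common raster convention, declared here because
no published choice exists. Trilinear interpolation is available for
template volumes but refused for segmentations: region labels must never
be blended. Any sample outside `[0, N-1]` on any axis returns the
background value 0, for templates and labels alike. All geometry is in
double precision.

## Interchange formats

Series descriptors travel as XML or JSON. Both dialects are parsed
liberally (whitespace around `=` inside the anchoring string, URL
percent-encoding) and emitted conservatively (no spaces, standard
quotes, UTF-8). Anchoring numbers are serialized with shortest
round-trip precision — the shortest decimal string that re-parses to the
identical double — so XML↔JSON conversion is lossless digit-for-digit.
Stored descriptors contain anchorings only for slices a user has
verified; this package additionally supports an optional
`status="estimated"` extension (off by default) so propagated estimates
can travel between headless runs.

The `.flat` label raster is fully specified: one byte of `Bpp` (1 when
the largest label fits a byte, else 2), two big-endian 32-bit
dimensions, then `Bpp·w·h` bytes of big-endian pixels. The pixel order —
row-major, top image row first — is declared here to match PNG raster
order, so a plate's `.flat` and PNG artifacts align index-for-index.
Segmentation PNGs carry palette colours (ids live in the `.flat` file);
template PNGs are 24-bit truecolor with the grayscale intensity
replicated across channels, scaled by the volume's global range. The
palette JSON is an array of `(index, red, green, blue, name)` tuples
whose redundant index must equal the array position — enforced, not
assumed. Export folder timestamps are injectable for reproducible tests.

## Propagation

Anchoring every section by hand is wasteful; users anchor a few sections
with clear landmarks and the rest are estimated:

* **Fresh series.** `initial_distribution()` spaces the `N` sections
  evenly along the sectioning axis, rank `k` at `(N - k + 0.5)/N` of the
  extent — the first section most anterior for a coronal series.
* **One verified anchor.** Its `u`, `v` are copied and `o` translated
  along the plane unit normal by `(nr difference) x default_spacing`;
  the spacing defaults to `extent/(N+1)`, mirroring the even
  distribution.
* **Two or more.** The nine components `(o, u, v)` are interpolated
  linearly in the *serial number* (gaps such as every-4th-section series
  are thereby respected), and extrapolated from the two nearest verified
  anchors beyond the ends; when the atlas dimensions are known an
  extrapolated plane is translated back so its centre stays inside the
  atlas bounding box, since planes outside it would only render
  background.

The exact redistribution scheme used by the original interactive tool is
not published; componentwise linear interpolation was chosen because it
reproduces verified endpoints bit-for-bit (the compatibility contract),
is idempotent, and approximates interpolation of position, scale and
tilt when angular differences between anchors are small. For large angle
gaps between consecutive verified sections it is a documented
approximation — interpolating poses instead would preserve edge lengths
better but cannot reproduce arbitrary anchorings exactly.

## The synthetic atlas

Real reference volumes are hundreds of megabytes and not shipped;
`make_synthetic_atlas()` generates a small stand-in emulating exactly
the features the machinery relies on: a segmentation of nested
axis-aligned boxes (labels `1..K` on background 0, voxel counts in
closed form via `synthetic_label_counts()`, centre always the innermost
label), a smooth separable-gradient template sharing that structure, and
a palette of distinct colours. It is deterministic in its seed. It does
*not* emulate anatomy: no curved region boundaries, no left-right
asymmetry, no intensity noise or staining artifacts. Tests passing on it
demonstrate the correctness of the geometry, resampling, propagation and
format code — not registration quality on real histology, which in this
workflow is supplied by the human anchoring decisions.

Default test problem sizes are a `64 x 80 x 56` voxel atlas with 3
regions and series of 2-10 sections — small enough for the whole suite
to run in seconds while still exercising unequal extents on every axis.

## Numerical and degenerate-input choices

* Nearest-neighbour rounding is `floor(c + 0.5)` per axis (half always
  rounds up, unlike banker's rounding).
* `voxel_to_pixel()` signs its out-of-plane distance by
  `n = (u x v)/|u x v|`.
* Degenerate anchorings (`u`, `v` collinear) are rejected wherever a
  plane is required (`voxel_to_pixel()`, `native_slice_dims()`,
  `render_slice()`); `pixel_to_voxel()` tolerates them, being a plain
  weighted sum.
* NIfTI files are reindexed to RAS using the file's affine for axis
  order and flips only; an oblique affine is an error rather than being
  silently resampled. Files with no spatial transform recorded are taken
  to be RAS already.
* Label values above 65535 cannot be written to `.flat` and are an
  error.

## Known limitations

Non-linear (elastic) refinement and per-region local anchoring are out
of scope, as is any image-content-based automatic registration: the
package redistributes user-supplied anchorings, it does not compute them
from pixels. Cross-species physical-to-physical mapping is not provided.
Only PNG image headers are read when scanning folders; for other formats
pass explicit `(filename, width, height)` listings.
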