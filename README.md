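# atlasanchor

Headless registration of serial 2D microscopic brain-section images to
3D reference atlases (Allen Mouse CCFv3, Waxholm Space rat), for
neuroscientists who need to assign atlas coordinates and region labels
to features in section images — electrode tracts, tracer injections,
segmented cells — without deforming the images themselves.

## The model

A section image of $w \times h$ pixels is *anchored* to the atlas by
three vectors in atlas voxel coordinates: $\mathbf{o}$ (origin, the
image's top-left corner), $\mathbf{u}$ (horizontal edge) and
$\mathbf{v}$ (vertical edge). Every pixel then has a continuous voxel
coordinate

$$\mathbf{p}(x,y) = \mathbf{o} + \tfrac{x}{w}\,\mathbf{u} + \tfrac{y}{h}\,\mathbf{v},$$

and published $4\times4$ affines take voxels to physical stereotaxic
space (µm, PIR order for Allen CCFv3; mm, RAS order for Waxholm). Around
this mapping the package provides:

* plane geometry: pixel↔voxel↔physical transforms, the
  pose (centre + dorsoventral/mediolateral tilt angles + scales)
  parameterization of a cutting plane;
* atlas plates: resampling template and segmentation volumes along any
  anchoring plane at native atlas resolution, with nearest/trilinear
  sampling (labels are never blended);
* interchange formats: XML and JSON series descriptors (digit-for-digit
  lossless), big-endian `.flat` label rasters, palette JSON, 24-bit PNG
  plates, NIfTI volume loading with RAS reindexing;
* propagation: estimating anchorings for unanchored sections from the
  user-verified ones (linear in serial number, endpoint-exact), and the
  even initial distribution of a fresh series;
* a synthetic atlas generator, so everything is testable without
  downloading reference volumes, and a CLI covering the whole workflow.

## Worked example

```r
library(atlasanchor)

# the shipped example descriptor: two sections anchored to oblique planes
xml <- system.file("extdata", "example_series.xml", package = "atlasanchor")
series <- read_series_xml(xml)
series
#> # Section series 'Test series': 2 slice(s), 2 anchored (2 verified)
#> # A tibble: 2 × 14
#>   filename       nr width height    ox    oy    oz    ux    uy    uz    vx    vy
#> 1 sampleID_s…     2 24723  18561  312.  534.  218. -186. -35.5   6.6  -4.6 -7.5
#> 2 sampleID_s…     8 24722  17507  335.  486.  252. -229. -13.3 -12.0  11.0 -7.15

# where does the centre pixel of section nr 2 sit in the atlas?
a <- slice_anchoring(series, 2)
pixel_to_voxel(a, x = 12000, y = 9000, width = 24723, height = 18561)
#>        x        y        z
#> 219.8348 512.9324 138.4937          # continuous atlas voxel coordinate

pixel_to_physical("allen_ccfv3", a, 12000, 9000, 24723, 18561)
#>         P         I         R
#>  351.6894 4512.6563 5495.8706      # micrometres, PIR axis order

# a synthetic atlas stands in for the real volumes
atlas <- make_synthetic_atlas(dims = c(64, 80, 56), n_regions = 3, seed = 7)
plate <- render_slice(atlas$segmentation,
                      default_plane("coronal", 40, c(64, 80, 56)))
plate
#> <custom_slice> 64 x 56 px from 'segmentation' (segmentation)

# region under an image pixel
lookup_region(atlas$segmentation, atlas$palette,
              default_plane("coronal", 40, c(64, 80, 56)),
              x = 500, y = 400, width = 1000, height = 800)
#> # A tibble: 1 × 4
#>       x     y    id name
#> 1   500   400     3 region_3
```

The voxel coordinate is the anchoring formula at work; the physical
readout applies the published Allen affine, so `P = 13175 - 25 y_v`
etc.; and the lookup reports the innermost synthetic region because the
image centre maps to the atlas centre for this plane.

The same workflow is scriptable from a shell via the bundled CLI
(`system.file("exec", "atlasanchor", package = "atlasanchor")`):
`make-fixture`, `build-descriptor`, `propagate`, `export-slices`,
`transform`, `lookup`, `convert`; see `?cli_run`.

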