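# musicalr

Label-free super-resolution density mapping of fibrous matrix proteins
from fluorescence fluctuation image stacks.

Collagen and keratin autofluoresce, and in fixed tissue sections that
autofluorescence fluctuates from frame to frame. A stack of a few hundred
short exposures from an ordinary wide-field microscope therefore contains
sub-resolution information: pixels fed by a common emitter fluctuate
together, pixels fed only by noise do not. `musicalr` reconstructs a
super-resolved *indicator map* from such stacks by multiple-signal-
classification (MUSIC-style) subspace decomposition, and quantifies
matrix-protein density on the result the way histopathology workflows do —
ROI mean densities, tissue-layer intensity ratios, multi-scale variance,
fibril widths, SSIM. A fibril-phantom simulator with a full camera noise
model generates ground-truthed test data.

## The core algorithm

For each `N × N` sliding window of the stack (vectorized to an `N² × K`
matrix `M`), a thin SVD `M = U Σ Vᵀ` splits the pixel space into a signal
subspace (top `r` left singular vectors, `r` chosen at the knee of the
log singular-value spectrum) and a noise subspace. A candidate emitter
position `p` on a 10× sub-pixel grid is scored against the microscope's
PSF: with `g(p)` the unit-norm PSF pattern integrated over the window's
pixels,

    i(p) = ( ||P_S g(p)|| / ||P_N g(p)|| )^alpha ,   alpha = 4 by default.

The indicator is large exactly where the PSF pattern is explained by
temporally coherent structure. Window results are averaged into a seam-free
map; borders that cannot host a full window are masked.

The optics module supplies the supporting quantities: depth of field
`DOF = lambda*mu/NA^2 + mu*e/(M*NA)`, field of view `pixels * e / M`,
Rayleigh limit `0.61*lambda/NA`, and Gaussian or Airy PSF kernels.

## Worked example

```r
library(musicalr)

# study conditions in one call: dense/sparse fibril field, blinking
# emitters, out-of-focus background, camera noise, 500 frames at 20x/0.80 NA
sim <- simulate_fibril_stack(seed = 1100)
sim$stack
#> Image stack: 64 x 64 pixels, 500 frames, 0.3225 um/pixel

map <- reconstruct(sim$stack, musical_params(), sim$optics)
map
#> Indicator map: 640 x 640 sub-pixels (0.03225 um each), window N = 7, alpha = 4
#>   valid: 82.1%; degenerate windows: 0

# the sharp map localizes the fibril network better than the blurred
# mean frame does (pixelwise correlation with the emitter-count raster):
ok <- map$valid_mask
gt <- sim$phantom$density_raster           # ground-truth emitter counts
dl <- mean_frame(sim$stack)
cor(map$values[ok], gt[ok])                               #> 0.184
cor(dl[rep(1:64, each = 10), rep(1:64, each = 10)][ok], gt[ok])  #> 0.108

# density quantification on the map
roi_mean_density(map, roi_spec(c(101, 101), c(100, 100)))
#> 0.576
multiscale_variance(map, window_sizes = c(5, 2.5))
#> Multi-scale variance report
#>       5 um ( 155 px):  16 windows, mean within-var 7.228e+10, between-var 2.747e+08
#>     2.5 um (  78 px):  63 windows, mean within-var 7.393e+10, between-var 9.865e+08
```

A two-layer phantom with a programmed 2:1 fibril density recovers a layer
ratio near 2 (geometric mean 1.69 over ten seeded images), and a simulated
fibrosis series with progressively homogenized fibril density is ordered
monotonically by the between-window variance at the 90/45/25 µm scales —
the readouts used to stage fibrotic progression.

A thin command-line front end is included at `inst/cli/musical.R`
(`simulate | run | analyze | optics` over a YAML config); `run_pipeline()`
is the same entry point from R and writes a manifest (config snapshot,
output checksums, timings) alongside every run.

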