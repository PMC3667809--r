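# iftseg

Seeded image-foresting-transform segmentation and cell-spreading
quantification for TIRF time-lapse stacks.

## The problem

Total internal reflection fluorescence (TIRF) microscopy illuminates only
the ~100 nm above the coverslip, so the fluorescent footprint of a
dye-labeled cell reports its substrate contact area. Recording a field of
cells every few seconds while they attach and spread yields a 2D+t volume
from which one wants, per cell and per frame, the contact area — the
*spreading kinetics*. Thresholding is unreliable because labeled cells vary
widely in brightness; drawing each cell by hand does not scale.

`iftseg` segments such stacks with the **image foresting transform (IFT)**:
the volume is a graph whose nodes are pixels, adjacent pixels are joined by
arcs weighted by their intensity dissimilarity `w(p,q) = |I(p) − I(q)|`, and
a handful of user-marked *seeds* — each cell with a unique positive label,
the background with label 0 — compete for every pixel. Pixel `q` receives
the label of the seed reaching it by the minimum-cost path, where the path
cost is either

- `max`-arc (default): `cost(π) = max over arcs of w` — the watershed-like
  rule, robust to gradual intensity ramps inside a footprint, or
- `additive`: `cost(π) = Σ w`.

The forest (label, cost, predecessor and root per pixel) is computed exactly
by a priority-queue propagation over the whole 2D+t graph, so seeds clicked
in one or a few frames classify the entire recording; cost ties are resolved
deterministically and results are bit-reproducible. From the label volume
the package counts per-cell areas per frame, exports fixed-dialect CSV,
aggregates cohorts into mean ± s.e.m. spreading curves, fits the logistic
spreading law `A(t) = A_max / (1 + exp(−k (t − t₀)))`, and compares groups
with the pooled two-tailed Student's t-test. Auxiliary numerics for western
blot loading normalization and baseline-normalized ratio traces (R/R₀) are
included.

A phantom simulator generates spreading stacks with exact ground truth
(logistic growth, irregular footprints, per-cell intensity variation,
Poisson + Gaussian noise), so the whole pipeline is testable without any
microscope data, and segmentation accuracy is measurable as a Dice
coefficient against truth.

## Worked example

```r
library(iftseg)

# a synthetic 128x128, 20-frame stack with 2 spreading cells and realistic noise
ph    <- defaultPhantom(seed = 7, frames = 20, dim = c(128, 128), nCells = 2)
seeds <- defaultSeedAnnotation(ph, seed = 8)   # stands in for manual clicks
seg   <- segmentVolume(phantomGrid(ph), seeds)

at <- computeAreas(seg, pixelArea = pixelArea(phantomGrid(ph)),
                   frameInterval = frameInterval(phantomGrid(ph)))
at
#> AreaTable: 2 cell(s) x 20 frame(s), pixel area 0.25 um^2, interval 5 s
#>   cell_label frame time_s area_px area_um2
#> 1          1     0      0     170    42.50
#> 2          1     1      5     178    44.50
#> 3          1     2     10     182    45.50
#> 4          1     3     15     191    47.75

head(curveData(aggregateCurves(at, group = "phantom")))
#>   frame time_s n mean_um2 sem_um2
#> 1     0      0 2   31.125  11.375
#> 2     1      5 2   32.500  12.000
#> 3     2     10 2   33.250  12.250
#> 4     3     15 2   34.750  13.000
#> 5     4     20 2   36.625  13.625
#> 6     5     25 2   37.750  13.500
```

Each `AreaTable` row is one cell in one frame: pixel count and calibrated
area (`area_um2 = area_px × pixel area`); `frame` is 0-based so
`time_s = frame × interval`. The curve pools cells per frame: `n` cells
contributing, mean area, and s.e.m. (sample sd / √n, `NA` when n < 2). On
this phantom the segmentation matches the ground truth with Dice 1.0 in
every frame (`diceCoefficient()` against `truthLabels(ph)`).

Real recordings enter through `readStack()` (multi-page single-channel
TIFF; calibration always comes from arguments, never from TIFF tags) and
`readSeedFile()` (CSV `t,row,col,label` or JSON, 0-based coordinates).
`exportAreasCSV()` / `exportCurveCSV()` write the fixed CSV dialects.

A command line covers the same pipeline (`segment`, `quantify`, `curves`,
`simulate`, `validate`):

```sh
Rscript inst/scripts/iftseg simulate --output-dir sim --seed 1
Rscript inst/scripts/iftseg segment  --stack sim/phantom.tif --seeds sim/seeds.csv \
        --output-dir seg --pixel-size-um 0.5 --frame-interval-s 5
Rscript inst/scripts/iftseg quantify --labels seg/labels.tif --output-dir out \
        --pixel-size-um 0.5 --frame-interval-s 5
Rscript inst/scripts/iftseg curves   --areas out/areas.csv --output-dir out
```

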