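---
title: "Methods: seeded forest segmentation and spreading-kinetics quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seeded forest segmentation and spreading-kinetics quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iftseg)
```

# The segmentation model

A TIRF time-lapse is treated as a graph: every pixel of the
(rows × cols × frames) volume is a node, and nodes are adjacent when they
are 4-connected (optionally 8-connected) within a frame, or when they are
the same pixel in consecutive frames. The arc weight is the intensity
dissimilarity

$$ w(p, q) = |I(p) - I(q)| \cdot s_{pq}, $$

where $s_{pq}$ is 1 for in-plane arcs and the `temporalScale` multiplier for
cross-frame arcs. Seeds — pixels marked as a specific cell (unique positive
label) or as background (label 0) — compete for all other pixels: each pixel
receives the label of the seed that reaches it with the minimum-cost path,
where the cost of a path is either the maximum arc weight along it
(`"max"`, default) or the sum of arc weights (`"additive"`). Both rules are
monotone non-decreasing under path extension, which is what makes the greedy
priority-queue computation exact.

The `max` rule is the default because a TIRF footprint is rarely uniform:
intensity ramps gradually from the adhesion core to the rim, and under the
`max` rule a path that stays inside a cell only pays its single worst step,
while any path crossing the cell boundary pays the full cell–background
contrast. This is the classic watershed-style behaviour and it degrades
gracefully as noise grows. The additive rule is available for images where
boundaries are soft but long paths should be penalized.

## Assumptions

* One channel; brighter-than-background cells (the method only uses
  *differences*, so absolute brightness and per-cell brightness variation do
  not matter — only local contrast does).
* Cells do not touch each other; where two cells meet, the arc weights
  between them come from their (usually different) plateau intensities, but
  no shape prior separates merging cells.
* The background is statistically uniform enough that background seeds can
  reach the whole background at lower cost than any cell-crossing path.

## Determinism and tie resolution

Costs have a unique optimum, but at exact cost ties several seeds may claim
a pixel. The package resolves ties deterministically: seed pixels always
keep their own label (they are never relaxed), and a tied pixel takes the
**earliest-listed seed** among those that reach it along an optimal path all
of whose prefixes are themselves optimal ("tight" paths — arcs $p \to q$
with $\mathrm{extend}(\mathrm{cost}(p), w) = \mathrm{cost}(q)$). This rule
has a unique fixed point, is independent of traversal order, and is computed
by two entirely different routes that must agree:

* `runIFT()` — the production path: a Dijkstra-style priority queue ordered
  by the lexicographic pair (cost, seed entry order), FIFO on insertion;
* `bruteForceIFT()` — the reference oracle: Bellman–Ford cost relaxation to
  the unique fixed point, then minimal-seed-order propagation over tight
  arcs only.

A subtlety worth recording: the "obvious" one-pass lexicographic relaxation
(carrying (cost, seed order) as a single tuple) is *not* equivalent to the
queue algorithm under the `max` rule, because the secondary criterion has no
optimal substructure — an optimal path may pass through a pixel whose own
optimum comes from another seed. The tight-arc formulation above removes
that ambiguity; the test suite asserts exact agreement of label, cost and
root maps on hundreds of random instances, plus the full forest contract
(complete labeling, seed fidelity, Bellman optimality at every arc, acyclic
predecessor chains).

Because the tie rule uses seed *entry order* and never the label value,
relabeling seeds by any bijection permutes the output labels identically
(asserted as a property test). `defaultSeedAnnotation()` and
`propagateSeeds()` list cell seeds before background seeds, so at exact ties
cells win over background — the conservative choice for area measurement at
noise-dominated boundaries.

# Segmentation modes

`segmentVolume()` supports two strategies:

* **`volume3d`** (default): one forest over the whole 2D+t graph. Seeds
  placed in any frame(s) classify every frame through the temporal arcs.
  Chosen as default because it matches the workflow of seeding "one or
  several slices" once per recording, and because temporal arcs stabilize
  frames where a cell is locally faint.
* **`per_frame_propagate`**: frame 1 is segmented from its seeds; each next
  frame is seeded by eroding the previous frame's labeled regions
  (`propagateSeeds()`). Intended for long acquisitions with drift, where a
  frame-1 seed may no longer lie inside its cell by frame 200. The erosion
  radius (default 2 px, square structuring element) keeps propagated seeds
  clear of the moving boundary; if erosion empties a shrinking region, its
  deepest interior pixel (by distance transform) is kept so the label
  survives. A label that disappears entirely is dropped with a warning.

Both modes are deterministic; the provenance list of the returned volume
records the configuration, an MD5 digest of the seeds, and the package
version, so re-running identical inputs is bit-identical.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `CostModel` rule | `"max"` | — | object delineation robust to intensity ramps |
| `smoothSigma` | 0 | px | optional Gaussian pre-smoothing of each frame before weights; off because the default phantom and typical TIRF contrast do not need it |
| `seedHandicap` | 0 | cost | no per-seed bias |
| `AdjacencySpec` in-plane | 4 | — | thinnest connectivity; 8 available |
| `temporalScale` | 1 | — | cross-frame arcs weighted like in-plane arcs |
| `erosionRadius` | 2 | px | seed-propagation margin (per-frame mode) |
| pixel size | user | µm | always from configuration, never TIFF tags |
| frame interval | 5 | s | the standard acquisition rate of the assay |

# The phantom generator

`simulateSpreadingStack()` emulates the features of the assay that make
segmentation non-trivial, with exact ground truth recorded before noise:

* **Logistic area growth** $A(t) = A_{max} / (1 + e^{-k (t - t_0)})$ — the
  sigmoid-to-plateau shape of spreading curves. Default draw ranges
  ($A_{max} \sim U[250, 450]$ µm², $k \sim U[0.010, 0.020]$ s⁻¹,
  $t_0 \sim U[30, 80]$ s at 0.5 µm pixels) describe a cell landing with a
  few tens of µm² of contact and plateauing within a 5-minute recording.
* **Irregular outlines**: the disc radius is modulated by a ≤ 5-harmonic
  Fourier perturbation (amplitude 0.1), rescaled so the enclosed area still
  equals $A(t)$; footprints are therefore star-shaped, not circular.
* **Brightness variability**: each cell's plateau intensity is drawn from
  U[300, 800] over a background of 100 — segmentation cannot rely on one
  global threshold.
* **Noise**: Poisson resampling of the clean image (shot noise) followed by
  additive Gaussian noise (σ = 30), clamped at 0.

The default phantom (256 × 256 px, 5 cells, 60 frames at 5 s) is the
condition under which the acceptance properties are measured: default
segmentation succeeds (per-cell per-frame Dice ≥ 0.9, per-frame area error
≤ 10%) but the input is genuinely noisy. Identical seeds give bit-identical
phantoms. `defaultPhantom()` scales the plateau-area range down with the
field of view so small test phantoms keep disjoint cells; at the default
geometry the range is unchanged.

What the phantom does **not** emulate — and hence what passing tests do not
show about real data: optical blur (no PSF or evanescent-field depth
model — truth boundaries are pixel-sharp, which real TIRF images are not),
photobleaching, cell migration, touching or colliding cells, and uneven
illumination. Accuracy numbers on phantoms are an upper bound for real
recordings.

# Quantification and statistics

* Areas are pixel counts per (label, frame), converted exactly by
  `area_um2 = area_px × pixel area`; a label absent from a frame yields an
  explicit zero row. With background included, per-frame areas sum to the
  frame's pixel count (conservation, asserted in tests).
* Spreading curves report, per frame, `n`, mean area and s.e.m. using the
  $n-1$ sample standard deviation; the s.e.m. is flagged `NA` when $n < 2$.
  Cells are aligned on the first acquisition frame by default (recordings
  start as cells land); per-cell frame offsets are supported for cells
  landing mid-recording, and `n` per frame makes partial contribution
  visible.
* Group comparison is the pooled-variance two-tailed Student's t
  ($df = n_a + n_b - 2$), on per-cell areas at a frame or per-cell means
  over a window. Zero pooled variance is handled explicitly: equal means
  give $t = 0, p = 1$; unequal means give $p = 0$ flagged `degenerate`.
* `fitSpreadingCurve()` fits the logistic law by Levenberg–Marquardt with
  data-derived starting values (plateau from the maximum, midpoint from the
  half-maximum crossing, rate from the 10–90% rise time).
* Blot loading normalization divides each lane's antibody signal by its
  actin signal relative to the reference lane (reference actin ≡ 1);
  invariant under rescaling the whole actin channel.
* Ratio traces are normalized by the mean over a baseline window
  ($R/R_0$; baseline mean of the output is exactly 1). An optional *linear*
  baseline detrend (fit on the baseline window, subtracted everywhere,
  baseline mean restored to 1) is provided but **off by default** — the
  appropriate drift model depends on the acquisition and no particular one
  is assumed.

# Numerical and format choices

* Intensities are held in double precision whatever the source bit depth.
* CSV dialects are fixed (headers, comma separator, '.' decimal, LF,
  UTF-8, sorted rows); doubles are written as `%.17g`, so write → read
  reproduces values exactly and a second write is byte-identical.
* In-memory coordinates are 1-based `(t, row, col)` as is natural in R;
  all on-disk formats (seed CSV/JSON, the `frame` column of area CSVs) are
  0-based, so `time_s = frame × interval`.
* Label TIFFs are 16-bit with label values verbatim; calibration metadata
  is never read from TIFF tags.
* Exact floating-point equality is used for cost ties (both routes compute
  identical arithmetic); invariant tests compare with a 1e-12 slack where
  two different summation orders meet.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on generated data:
random grids up to 6 × 6 for the oracle equivalence and forest-contract
properties (100 instances × 2 cost rules each), the full default phantom
(256 × 256 × 60, 5 cells) for segmentation accuracy, the same phantom
without noise for the exactness check, and a 256 × 320 × 60 stack of 20
identical logistic cells ($A_{max} = 350$ µm², $k = 0.015$ s⁻¹,
$t_0 = 50$ s) for end-to-end kinetics recovery — sizes chosen to exercise
the full pipeline at the assay's native scale while keeping a complete run
in well under a minute each.

# Known limitations

* No automatic seeding: seeds come from files (the interactive clicking of
  the original workflow is out of scope).
* Touching cells are separated only by their intensity difference; a true
  boundary prior (e.g. gradient ridges) is not implemented.
* The brute-force oracle is deliberately capped at 10,000 pixels.
* Differential (incremental) seed editing and GPU execution are out of
  scope; a full 2D+t forest on a 4-million-pixel volume takes on the order
  of ten seconds on one CPU core.
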