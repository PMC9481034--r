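---
title: "Quantifying the structure of actin aster networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the structure of actin aster networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Actin filaments in a crowded solution (for instance with methyl cellulose as
a depletion agent) self-assemble into large, flat networks of star-shaped
*asters*: bright junctions from which multiple filament bundles radiate,
with neighbouring junctions connected by one or several parallel strands.
Because the network's vertical extension (one or two aster layers, about
10–25 µm) is small compared with its lateral extent (up to square
millimetres), the analysis treats the fluorescence micrograph as a
two-dimensional point-and-bundle pattern.

`asternet` answers three questions about such an image:

1. **Where are the aster centres?** (oriented-line correlation detection)
2. **How are they spaced and connected?** (Delaunay statistics: mean
   inter-vertex distance, neighbour degree, vertices per mm²)
3. **How regular and homogeneous is the arrangement?** (comparison with an
   equilateral-hexagon packing model; tile bootstrap of per-region spacing)

## Vertex detection

Aster centres are junctions at which bundles meet from many directions. The
detector exploits exactly this property:

* The image is high-pass filtered by subtracting a local box mean (window
  three line-lengths wide) to remove the slow background gradient of the
  diffusion setup.
* It is then cross-correlated with a bank of thin line kernels at
  `n_angles = 15` orientations spaced evenly from 0 to π. Each kernel is
  normalised to zero mean and unit norm, so flat regions respond with
  exactly zero and responses are comparable across angles.
* The per-angle responses are overlaid by **pixelwise summation**. A point
  on a straight bundle responds at essentially one orientation; a junction
  responds at many, so the sum amplifies junctions specifically. (A
  pixelwise maximum would score straight bundles as highly as junctions,
  which is why the sum is used.)
* A second correlation pass repeats the per-angle correlation with lines
  elongated by `elongation_factor = 2`. Along a bundle only one orientation
  stays coherent over the longer support, at a junction several do, which
  further pronounces the vertices. Because every stage is a linear
  convolution, the production path composes the whole chain (including the
  final Gaussian blur) into a single effective kernel and applies one
  FFT correlation; this is algebraically identical to running the stages
  one by one, up to a narrow boundary band where the staged path re-applies
  its reflective padding.
* The combined response is blurred (`blur_sigma_um = 1`), binarised at the
  `threshold_quantile = 0.70` quantile of its positive values, eroded with
  a disc of radius 1 px, and reduced to connected components of at least
  4 px. Each component becomes one vertex at its response-weighted
  centroid (sub-pixel accuracy matters: the default calibration is
  0.366 µm/px while spacing statistics are reported to 0.1 µm).
* Centres closer than `min_separation_um = 3` are not regarded as
  individual vertices: single-linkage clusters under the *strict* 3 µm
  proximity relation are replaced by their score-weighted centroids,
  repeatedly until all pairwise distances are at least 3 µm. Two vertices
  at exactly 3.0 µm are kept apart.

### Choice of the segmentation defaults

The blur/threshold/erosion stage admits a wide parameter range, and the
defaults were fixed by parameter recovery on synthetic ground truth rather
than by eye. Two regimes matter:

* **Dense fields** (asters tiling the whole image, the intended
  application): junction responses exceed bundle responses several-fold,
  but junction brightness itself varies about three-fold with the number
  of strands per bundle. A *moderate* quantile (0.70) keeps the dim
  junctions; the strong blur and erosion one might first reach for
  (e.g. 2 µm / radius 2) smear the compact junction peaks into the bundle
  ridges and collapse recall to a fraction of the planted vertices.
* **Sparse scenes** (isolated asters, useful for validation): most of the
  image carries no signal, so a fixed quantile of positive responses lands
  inside the star itself and satellite blobs appear on the limbs. Sparse
  validation fixtures therefore use `threshold_quantile = 0.99`. The
  quantile is deliberately a parameter: it must reflect aster coverage.

A purely relative threshold would also fire on a completely signal-free
image. The detector therefore applies an absolute significance floor,
`noise_floor_k = 5` times the noise standard deviation expected in the
filtered response. That expectation is exact, not heuristic: white noise of
standard deviation σ passed through a linear kernel K has response noise
σ·‖K‖₂, with σ estimated robustly from the median absolute difference of
adjacent pixels and ‖K‖₂ taken from the composed detection kernel. A
background-plus-noise image then yields an empty (flagged) vertex set at
any quantile.

## Network statistics

Detected centres are connected by a Delaunay triangulation (via `deldir`),
the field's standard connectivity proxy for such point patterns; its
deterministic handling of cocircular quadruples makes repeated runs
byte-identical. Statistics follow three filtering rules:

* **Edge lengths** outside the closed interval [3, 20] µm are discarded:
  sub-3 µm distances are handled at detection time by merging, and
  distances above 20 µm arise at the image edge or over aster-free
  patches. The interval is closed at both ends — the strict inequality of
  the merge rule concerns vertex identity, not edge retention, and one
  convention is applied consistently.
* **Degrees** are counted over retained edges only, and only vertices
  farther than `boundary_margin_um` (default: the 20 µm upper length
  cut-off) from the image border enter the degree statistics. Degrees
  below five occur essentially only where the field of view truncates a
  neighbourhood; a geometric margin is reproducible, whereas discarding
  low-degree vertices after the fact would be circular. The median is
  reported (it is an integer for any realistic degree distribution), with
  the interquartile range from linear-interpolation quantiles (type 7).
* **Density** is the raw vertex count divided by the image area, scaled to
  1 mm², with no edge correction — asters straddling the border are
  counted wherever their centroid is detected.

### The hexagon packing model

An ideally regular network places vertices on a triangular lattice —
equivalently, packs equilateral hexagons — with lattice constant *a* equal
to the mean inter-vertex distance. Rows of such a lattice are √3/2·a
apart, so one square millimetre holds

N(a) = (1000/a) · (1000/(√3/2 · a)) = 2·10⁶/(√3·a²)

vertices. The **hexagon correlation** is the ratio of the observed density
to N(a) evaluated at the observed mean spacing; values near 1 say the
network packs like the ideal lattice. For the printed worked example
(a = 11.8 µm, 7,697 vertices/mm²) the ratio is 0.928.

### Homogeneity

The field is split into 16 or 64 equal tiles (the coarser grid for smaller
or lower-magnification fields), each tile is triangulated and filtered
independently, and tiles with fewer than four vertices, a degenerate
triangulation or no retained edge are marked invalid — they are too small
to carry a spacing estimate. The mean of the valid per-tile means is
bootstrapped (B resamples with replacement, seeded) and the bootstrap
distribution is summarised by a Gaussian kernel density estimate with
Silverman's rule-of-thumb bandwidth. If all tile means coincide the
bandwidth degenerates; a spike of width 10⁻⁶ of the common mean is used so
the density still integrates to one.

## The synthetic-data generator

Real micrographs of the deposited samples are not required for testing:
the generator emulates the statistical structure the analysis assumes.

* **Geometry** — vertices on a triangular lattice with constant `a`
  (default 11 µm, inside the 9–13 µm range the analysis targets), each
  displaced by a uniform draw from a disc of radius `jitter_fraction · a`
  (isotropic and bounded; the default 0.1 keeps the degree-6 topology) and
  deleted independently with `missing_vertex_prob` (default 0). Ground
  truth connectivity is the Delaunay triangulation of the jittered
  positions — the same proxy the analysis uses.
* **Rendering** — each edge is drawn as 1–3 anti-aliased strands of width
  0.8 µm, offset perpendicular to the edge by up to 0.6 µm (neighbouring
  asters often connect via multiple strands), scaled by the signal
  amplitude over a uniform background and convolved with an isotropic
  Gaussian point-spread function (σ = 0.5 µm).
* **Noise** — per-pixel Poisson resampling (shot noise) plus additive
  zero-mean Gaussian read noise (σ = 5 counts), clipped at zero.
* **Frame** — 2048 × 2048 px at 0.366 µm/px ≈ 750 × 750 µm. The
  calibration is an inference from the displayed field size at that pixel
  count and is deliberately configurable; the analysis never guesses it
  from file metadata.

Every stage is a pure function of the specification and a seed (layout:
`seed`, rendering: `seed + 1`, noise: `seed + 2`), so fixtures regenerate
bit-for-bit from their JSON sidecar.

**What the generator does not emulate:** pre-aster forms from anisotropic
flow, uneven illumination beyond a smooth background, bundle curvature,
out-of-focus light from a second network layer, photobleaching, and asters
outside the frame whose limbs enter it. Passing the recovery tests
therefore demonstrates correctness of the pipeline on networks with the
assumed statistical structure, not robustness to every imaging artefact of
real samples.

## Numerical choices and degenerate inputs

* Correlations use reflective (mirror) boundary padding, extended to the
  next 7-smooth size so the FFT stays fast at any input dimension.
* Fewer than 3 vertices, or an all-collinear configuration, is an explicit
  degenerate-input error for triangulation; an empty segmentation is *not*
  an error but a flagged empty result (exit code 3 in the CLI).
* Components with non-positive total response weight fall back to an
  unweighted centroid.
* Raising the threshold quantile can split one component into two before
  both shrink away, so the vertex count is non-increasing in the quantile
  only up to occasional ±1 blips; the test suite asserts monotonicity with
  a 1% slack.
* Multi-strand connections between the same vertex pair count as one
  neighbour relation: the triangulation is over points, not strands.
* Evaluation of detection against ground truth uses greedy nearest-pair
  matching within 2 µm; an optional boundary margin excludes the border
  band, where planted vertices sit on the very frame edge with half their
  limbs outside the field.

## Problem sizes

The bundled validation runs the full pipeline on one 2048 × 2048 px
fixture (~5,400 vertices, a few tens of seconds) plus a central
250 × 250 µm crop, and exercises unit properties on 180–600 µm fields;
brute-force oracles (empty-circumcircle Delaunay, transitive-closure
merging) run on ≤ 12 points where exhaustive checking is feasible.

## Known limitations

* The detector assumes junction-dominated scenes; in sparse fields the
  threshold quantile must be raised by the user (see above).
* Density carries no edge correction, so small fields underestimate the
  hexagon correlation slightly — the same magnification bias the
  statistics are known to show on real images.
* The pipeline is strictly 2D; multi-page TIFFs are rejected rather than
  projected.
* Tile bootstrap partitions globally detected vertices; it does not re-run
  detection per tile.
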