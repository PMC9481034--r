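# asternet

Structural analysis of entropically self-assembled actin **aster networks**
in fluorescence micrographs.

Actin filaments bundled by a crowding agent (e.g. methyl cellulose)
organise into large, effectively two-dimensional networks of star-shaped
asters: bright junctions connected to their neighbours by one or several
filament bundles, with typical inter-junction spacings of 9–13 µm. For
people quantifying such networks — or any junction-dominated filament
network imaged in 2D — `asternet` provides a reproducible pipeline that:

1. **detects aster centres** by correlating the image with a bank of thin
   line kernels at 15 orientations from 0 to π, overlaying (summing) the
   per-angle responses, sharpening junctions with a second, elongated
   correlation pass, then blurring, quantile-thresholding and eroding the
   response into one sub-pixel centroid per junction; centres closer than
   3 µm are merged (strictly-less-than rule);
2. **measures the network** through a Delaunay triangulation of the
   centres: mean ± sd inter-vertex distance over edges in the closed
   [3, 20] µm band, median neighbour degree (interior vertices only) with
   interquartile range, and vertex density scaled to 1 mm²;
3. **scores regularity** against an equilateral-hexagon (triangular
   lattice) packing model with lattice constant *a* set to the measured
   mean spacing,

   N(a) = (1000/a) · (1000/(√3/2·a)) = 2·10⁶/(√3·a²)  vertices per mm²,

   reporting the hexagon correlation = observed density / N(a);
4. **assesses homogeneity** by splitting the field into 16 or 64 tiles,
   bootstrapping the per-tile mean spacings and summarising them with a
   kernel density estimate;
5. **generates ground-truthed synthetic fields** (jittered triangular
   lattice, multi-strand bundles, Gaussian PSF, Poisson + read noise) so
   every stage is validated by parameter recovery without any microscopy
   data.

## Worked example

```r
library(asternet)

# a 220 x 220 um synthetic field: lattice constant 11 um, jitter 0.1 a
spec   <- aster_field_spec(field_width_um = 220, field_height_um = 220,
                           seed = 7)
sim    <- simulate_aster_field(spec)
report <- aster_analysis(sim$image, bootstrap_seed = 1, log_level = "quiet")
report
#> Network summary
#>   vertices / retained edges    449 / 1281
#>   Av Dist (um)                 11.22 +/- 1.49
#>   Neighb (median)              6 (IQR 0)
#>   Vert. Dens (per mm^2)        9280
#>   Corr. Hex                    1.012
#> homogeneity_report: 16 tiles (16 valid), B = 1000
#>   tile means: 10.95 - 11.77 um; bootstrap mean 11.420 um (sd 0.052)
```

Reading the numbers: the 449 detected centres sit 11.22 µm apart on
average (the planted lattice constant was 11 µm), interior vertices have a
median of 6 Delaunay neighbours, and the observed density of
9,280 vertices/mm² is within 1.2% of the hexagon-model prediction at that
spacing (`Corr. Hex` ≈ 1 means the network packs like a regular
triangular lattice). The narrow bootstrap distribution of per-tile means
(sd 0.05 µm) says the field is spatially homogeneous.

`plot(report)` overlays the retained triangulation on the detected
centres; `write_report(report, "out/")` persists summary JSON, vertex and
edge CSVs, a plain-text table (Av Dist / Neighb / Vert. Dens / Corr. Hex)
and the run log.

Real micrographs enter through `read_image(path, pixel_size_um)` (8/16-bit
single-channel TIFF or PNG; the µm-per-pixel calibration is always
explicit, never guessed from metadata). A thin command line lives at
`inst/cli/asternet.R` with `simulate`, `detect`, `analyze` and `run`
subcommands.

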