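# mmsla

Print planning and fidelity morphometrics for multi-material projection
stereolithography (MMSLA) bioprinting.

Projection stereolithography builds hydrogel objects layer by layer by
projecting 2-D grayscale photomasks into a photocrosslinkable bioink. A
multi-material variant adds a laterally translating sled carrying up to
four bioink droplets and a rinse station, so that successive layers — or
co-planar regions of one layer — can be printed from different materials,
with a saline rinse and wick step between material switches to keep the
inks pure. `mmsla` implements the computational side of that workflow for
people who build or benchmark such printers:

- **Design & masks** — parametric layered multi-material designs
  (`makeCheckerboardDesign()`, `makePresetDesign()`, shape constructors)
  rasterized to 8-bit grayscale photomask stacks at projector resolution
  by supersampled coverage sampling (`buildMaskStack()`,
  `writeMaskStack()`).
- **Scheduling** — a compiler from design + masks to an ordered, validated
  machine-event sequence (LOWER / EXPOSE / RAISE / SLED_MOVE / RINSE /
  WICK) with a constant-dose exposure-time model
  (`compileSchedule()`, `validateSchedule()`, `estimateDuration()`,
  `exposureTime()`).
- **Synthetic imaging** — a renderer producing microscope-like
  multi-channel fluorescence images of a printed feature layer, with
  configurable placement jitter, diameter error, edge roughness, blur and
  noise, plus exact per-feature ground truth
  (`renderFeatureLayer()`, `writeGroundTruth()`).
- **Morphometry** — blob-style print-fidelity analysis: segmentation
  (`segmentFeatures()`), per-feature area, Crofton perimeter, equivalent
  diameter and circularity (`measureFeatures()`, `circularity()`),
  nearest-neighbor centroid distances (`nearestNeighborDistances()`),
  mutual-nearest-neighbor post/hole pairing (`pairPostsHoles()`), and a
  summary report against a resolution threshold
  (`summarizeMorphometry()`, `analyzeCheckerboard()`).
- **Pipeline & CLI** — `runPipeline()` ties design → masks → schedule →
  render → morphometry into one reproducible, fully seeded run;
  `inst/scripts/mmsla` exposes `plan`, `render`, `measure`, `fidelity`
  and `validate` subcommands.

## The core metrics

For each segmented feature (a cylindrical **post** of one material, or the
matching **hole** in the open lattice of a second material):

- equivalent diameter `d = 2 * sqrt(A / pi)` from the pixel-count area `A`;
- circularity `C = 4 * pi * A / P^2`, with the perimeter `P` estimated by a
  four-direction Cauchy–Crofton transition count (raw pixel-edge counting
  cannot reach `C = 1` on digital disks);
- nearest-neighbor distance: minimum centroid-to-centroid distance within
  a feature class;
- alignment error: Euclidean distance between a post centroid and the
  centroid of the hole it nests in, found by mutual-nearest-neighbor
  matching gated at half the array pitch. The headline fidelity figure is
  the fraction of alignment errors strictly below the projector's pixel
  size (50 um) — the instrument's theoretical resolution limit.

## Worked example

```r
library(mmsla)

# The fidelity test article: Ø 500 um posts, hexagonally packed at
# 1000 um pitch, nested in the complementary open lattice, on a 300 um
# dye-free base layer.
design <- makeCheckerboardDesign(postDiameter = 500, pitch = 1000,
                                 rows = 8, cols = 8,
                                 baseThickness = 300, featureThickness = 100)

# Noise-free render at 5 um/px and full morphometric analysis
render <- renderFeatureLayer(design,
                             imagingConfig(pixelSize = 5, blurSigma = 0,
                                           noiseSd = 0, background = 0,
                                           foreground = 1, seed = 1))
analysis <- analyzeCheckerboard(render, pitch = 1000, threshold = 50,
                                segmentation = "half-max")
analysis$report
#> MorphometryReport
#>   post  equivalentDiameter       mean   498.774  sd    0.090  n 64
#>   post  circularity              mean     0.997  sd    0.001  n 64
#>   post  nearestNeighborDistance  mean   999.892  sd    0.055  n 64
#>   hole  equivalentDiameter       mean   501.209  sd    0.166  n 64
#>   hole  circularity              mean     1.003  sd    0.005  n 64
#>   hole  nearestNeighborDistance  mean   999.840  sd    0.125  n 64
#>   alignment: 64 pair(s), 100.0% of errors < 50 um (projector pixel size)
```

The measured post diameters (498.8 um), circularities (0.997) and
nearest-neighbor distances (999.9 um) recover the designed 500 um /
1.00 / 1000 um values to within half an imaging pixel, and with no
injected placement error every post centroid coincides with its hole
centroid. Adding realistic per-axis placement jitter
(`fidelityModel(placementJitterSd = 15)`) produces Rayleigh-distributed
alignment errors whose sub-50 um fraction the same analysis chain
recovers.

The dose model reproduces the instrument calibration:

```r
exposureTime(200, 10)   # 60  s for a 200 um layer at 10 mW/cm^2
exposureTime(300, 10)   # 120 s for a 300 um layer
exposureTime(200, 20)   # 30  s: constant dose, double the irradiance
```

A full reproducible run from a config file:

```r
runPipeline(system.file("extdata", "fidelity-run.yaml", package = "mmsla"),
            outdir = "out")
```

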