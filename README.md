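# contourGraph

Semi-automatic breast-contour detection in frontal torso photographs,
for the image-based assessment of aesthetic outcomes of breast cancer
conservative treatment (BCCT).

Most objective BCCT scoring systems need the breast contour — the curve
between an inner endpoint near the midline and an outer endpoint near the
arm — before any symmetry or shape feature can be computed. Given the two
endpoints, `contourGraph` extracts the contour as a shortest path on a
weighted pixel graph:

1. **Edge detection** — Sobel, Prewitt, Canny, a weighted channel
   combination, or a learned *Sobel-skip U-Net* produce a
   gradient-magnitude map `g` on the 0–255 scale.
2. **Weighted graph** — 8-adjacent pixels `i, j` are connected with arc
   weight `f(g) = alpha * exp(beta * (255 - g)) + gamma`, where `g` is the
   mean magnitude of the two pixels; diagonal arcs are scaled by `sqrt(2)`.
   An optional endpoint-conditioned shape-prior mask multiplies arc
   weights away from plausible contours.
3. **Shortest path** — Dijkstra's algorithm (exact, deterministic
   tie-breaking) returns the minimum-cost 8-connected pixel chain between
   the endpoints: the predicted contour.

The learned operator is a four-block U-Net whose decoder concatenates the
(fixed, non-learned) Sobel response of the input at every resolution, with
a 256-feature bottleneck and ~1.76 M parameters. It is trained with the
structured hinge loss

```
L = ReLU( cost(gt) - cost(pp) )
```

where `gt` is the ground-truth chain expanded from weak annotations
(endpoints + a few keypoints) and `pp` is the current shortest path; the
loss is zero exactly when the annotated contour is itself a shortest
path. Gradients flow through the two path-cost sums only (a structured
hinge subgradient; the path search is detached).

Because patient photographs are available only on request to their
custodians, the package also ships a synthetic torso-scene generator with
exact ground truth (controllable contour contrast, distractor edges,
illumination ramps, noise) and an evaluation harness (normalized contour
error, k-fold splitting, operator benchmarking), so the entire method is
buildable and testable offline.

## Worked example

```r
library(contourGraph)

dir <- file.path(tempdir(), "demo")
generateDataset(4, dir, presetRanges("clean"), seed = 7)

res <- evaluateOperator(file.path(dir, "manifest.json"), "sobel")
res
#> EvalResult [sobel]: n=8 contours, mean 0.109%, sd 0.044%, max 0.204%

round(perImageErrors(res), 3)
#>  scene_001.png:left scene_001.png:right  scene_002.png:left scene_002.png:right
#>               0.054               0.118               0.120               0.110
#>  scene_003.png:left scene_003.png:right  scene_004.png:left scene_004.png:right
#>               0.092               0.079               0.204               0.097

out <- detectContour(file.path(dir, "scene_001.png"),
                     file.path(dir, "scene_001_left.json"),
                     out = file.path(dir, "contour.json"), overlay = TRUE)
out$path
#> PixelPath: 41 nodes, (66,57) -> (66,25), cost 62.021
```

Errors are symmetric mean nearest-neighbour distances between predicted
and true chains, standardized by the image diagonal and reported in
percent — 0.109% on a 128×128 scene is a mean deviation of about 0.2 px.
`detectContour()` writes the contour as a polyline JSON, a provenance
record (configuration, package version, input checksums) and, with
`overlay = TRUE`, a PNG with the contour drawn.

The arc-weight defaults give a ~600:1 cost ratio between non-edge and
strong-edge arcs:

```r
arcWeight(255, 255, "straight", edgeWeightParams())  # 1.005
arcWeight(0, 0, "straight", edgeWeightParams())      # 586.99
```

Training the learned operator on weak-contrast, cluttered scenes:

```r
scenes <- lapply(drawSceneSpecs(40, presetRanges("cluttered"), seed = 101),
                 generateScene)
model <- sobelUNet(baseFeatures = 16, seed = 1)
fit <- trainSobelUNet(model, scenes, trainConfig(epochs = 6, seed = 1))
```

On ten held-out cluttered scenes this drops the mean contour error from
2.25% (Sobel baseline) to 0.59% (seed 1) / 1.20% (seed 2); the untrained
model sits at 3.1–3.3%.

A thin command-line wrapper over these functions is installed at
`inst/scripts/contour-graph-cli.R` with subcommands `detect`, `gt-path`,
`synth`, `train`, `eval` and `bench`.

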