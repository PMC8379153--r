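# nanoruler

Single-molecule localization microscopy (STORM) analysis of DNA-origami
nanorulers, built to answer one question: **how much does hydrogel embedding
distort nanoscale structure?**

Expansion microscopy embeds a sample in a swellable gel and physically
magnifies it, but the embedding chemistry can displace the labels it is
supposed to hold in place. DNA-origami nanorulers — rigid structures with
fluorescent labeling sites at designed spacings (10 sites every 28 nm on a
line, a sparse 84-nm variant, and a rectangle with two rows 30 nm apart and
11-nm within-row spacing) — turn that displacement into a measurable number.
The package is aimed at microscopists and method developers who have
molecule-list localization tables (`x_nm, y_nm, frame`) and want the complete
quantitative pipeline behind such a calibration:

* **Emitter clustering** — DBSCAN (`eps` 10–15 nm, `minPts` 5) for resolvable
  spacings; K-means seeded by local maxima of a Gaussian-blurred image where
  DBSCAN would merge neighboring clouds (11-nm rows).
* **Object selection** — single-linkage grouping, then the published rule:
  ≥ 5 clusters on a straight line, total-least-squares R² > 0.9 (≥ 3 for
  rectangular rows and the 4-site sparse ruler).
* **Nearest-neighbor statistics** — per-emitter nearest-neighbor distances,
  each unordered pair counted once; first-peak Gaussian fit in the window
  0.5–1.5 × the design spacing; optional division by the gel expansion factor.
* **Distortion estimate** — comparing the fitted peak width σ before and
  after origami denaturation:

  σ_emitter = √((σ_post² − σ_pre²) / 2),  FWHM = 2√(2 ln 2) · σ_emitter.

  A 16-nm per-emitter distortion is equivalent to 38 nm FWHM — the scale of
  error a free-radical polyacrylamide gel can introduce, versus < 5 nm
  (< 12 nm FWHM) for click-chemistry tetra-gels.
* **Synthetic fields** — a generator that emulates the origami designs, dye
  blinking clouds, incomplete labeling, per-site gel displacement, isotropic
  expansion (2.2–2.5×) and background, with ground-truth sidecars, so every
  stage is testable without the microscope.

## Worked example

Simulate the no-gel reference field (100 ten-site linear origami in a
90 × 90 µm field), run the full linear pipeline, and read off the first peak:

```r
library(nanoruler)

design <- standardDesign("linear28")
sim <- simulateField(design, simulationConfig(seed = 1), "pre")
sim$localizations
#> LocalizationTable with 26038 localizations
#>   x: [219.3, 89259.9] nm  y: [625.6, 89648.3] nm  frames: 2..15000

res <- analyzeLinearField(sim$localizations, expectedSpacing = 28, designSites = 10)
res$fit
#> PeakFit: mean 27.38 nm, sigma 3.66 nm (window 14.0-42.0 nm)
length(res$objects)   # 99 of 100 objects pass the >=5-collinear-clusters rule
```

The fitted mean sits at the designed 28-nm spacing (the slight deficit is the
nearest-neighbor statistic preferring each chain's smaller gaps); the
distance set also shows secondary mass near 56 nm from origami with a missing
dye. Now the actual measurement — a pre/post denaturation pair on the sparse
84-nm ruler with a 16-nm per-site gel displacement injected:

```r
cfg <- simulationConfig(seed = 1, gelDistortion = 16)
d84 <- standardDesign("linear84")
fitPre  <- analyzeLinearField(simulateField(d84, cfg, "pre")$localizations,
                              84, minClusters = 3)$fit
fitPost <- analyzeLinearField(simulateField(d84, cfg, "post")$localizations,
                              84, minClusters = 3)$fit
estimateDistortion(fitPre, fitPost)
#> DistortionEstimate: sigma 15.1 nm (FWHM 35.6 nm), pre 3.94 / post 21.72 nm
```

The pre-condition peak is narrow (structure intact), the post-condition peak
is broadened by the injected displacement, and the estimator recovers it —
slightly low, because the straightness selection and the nearest-neighbor
dedup both trim the distribution's tails (see the methods vignette,
`vignettes/nanoruler-methods.Rmd`, for the measured size of both effects).

The rectangular branch (`analyzeRectField()`) adds ROI selection by
localization density, a two-parallel-row fit, per-row maxima-seeded K-means,
and the within-row 11-nm peak; `runPipeline()` composes any of these from a
single YAML/`pipelineConfig()` configuration and writes clusters, objects,
distances, a JSON summary and a run log. A thin command-line front end lives
in `inst/scripts/nanoruler.R`.

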