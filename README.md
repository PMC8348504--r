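# ThermoTrace

Active (pulsed) infrared thermography is a cheap, non-destructive way to
look for structure hidden below a surface: heat the surface with a known
flux, film it cooling down, and read the buried structure out of the
spatio-temporal temperature pattern.  `ThermoTrace` implements a complete
in-silico feasibility pipeline for two such problems:

* **Plant root-system architecture (RSA).**  A sugar-beet-like taproot
  (primary branches Ø 1 mm, secondary laterals Ø 0.5 mm) buried 1–8 mm
  deep in soil behind a 2 mm acrylic cover in a 65 × 95 × 12 mm sample.
  The cover is heated at 0.0005 W/mm² for 10 s (30.875 J in total) and the
  surface is recorded for 120 s.
* **Non-visible bubbles in plexiglass.**  A conical air void (base
  diameter 1.98–6.35 mm, apex depth 1.59–6.35 mm) between two
  40 × 40 × 7 mm plexiglass plates under 0.152 mm black electrical tape,
  heated at 0.0012 W/mm² for 30 s and recorded for 150 s.

The package provides, as tested S4-based building blocks:

1. **Sample builders** — parametric voxel models with exact depth
   layering and ground-truth masks (`buildTaprootArchitecture()`,
   `rasterizeRsaSample()`, `buildBubbleSample()`).
2. **A transient conduction solver** — conservative finite-volume update
   with harmonic-mean interface conductances; explicit FTCS stepping, or
   a dimensionally split backward-Euler scheme for stiff grids (thin
   tape, air); flux + convection (+ optional T⁴ radiation) on the imaged
   surface, all other faces insulated (`simulateSample()`).
3. **The line-scan root detector** — per-line time-averaged temperature
   profiles whose local minima (difference/sign/difference rule) mark
   buried roots, plus overlay evaluation and a depth-limit protocol
   (`detectRoots()`, `overlayEvaluation()`, `deepestDetectableDepth()`).
4. **Depth and size predictors** — leave-one-model-out polynomial
   regression, an RBF SVM with grid-searched (cost, γ), and
   single-hidden-layer neural networks whose hidden size is chosen by
   K-fold cross-validated R²; accuracy is scored as
   `100·(1 − mean|ŷ − y|/y)` (`prBattery()`, `fitSvm()`,
   `fitAnnKfold()`, `fitMimo()`, `fitMiso()`).
5. **A noise battery** — seeded Gaussian noise of stated SD injected into
   a stated fraction of training rows, retrain, score on clean
   validation data (`injectNoise()`, `runNoiseBattery()`).

## Worked example

Simulate the 2 mm-depth root model at the study conditions and recover
the root structure:

```r
library(ThermoTrace)

arch   <- buildTaprootArchitecture(seed = 1)
sample <- rasterizeRsaSample(rsaSampleSpec(burialDepth = 2), arch)
sample
#> VoxelSample: 65 x 95 x 12 voxels, pitch 1 mm, depth 12 mm
#>   volumes (mm^3): soil=6.157e+04, root=180, acrylic=1.235e+04
#>   hidden-structure mask: 180 of 6175 surface pixels

totalInputEnergy(rsaSampleSpec(2), rsaSimulationConfig())
#> [1] 30.875

run <- simulateSample(sample, rsaSimulationConfig())   # ~4 s
run
#> SurfaceSequence: 121 frames of 65 x 95 pixels, t = 0..120 s
#>   temperature range 296.150..298.176 K

averageSurfaceTemperature(run)[c(11, 31, 61, 121), ]
#>  time    meanT
#>    10 298.1764
#>    30 297.0363
#>    60 296.6914
#>   120 296.4884

det <- detectRoots(run)
det
#> DetectionResult: 229 pixels flagged on a 65 x 95 frame (window 5)
overlayEvaluation(det, truthMask(sample))[c("precision", "recall")]
#> $precision  0.62...   $recall  0.79...
```

The heating pulse deposits exactly 30.875 J; the surface peaks just
above 298 K at the end of heating and relaxes toward ambient; and the
line scan recovers 79% of the (1-px-dilated) root projection at 2 mm
burial depth, with the residual 38% of flagged pixels being the method's
characteristic scatter of spurious minima.

End-to-end scenarios (nine-depth battery, parameter sweeps, bubble
grids) are driven by `runScenario()` from a YAML config, or from the
shell via `inst/scripts/thermotrace`.

## Documentation

The methods vignette (`vignettes/active-thermography.Rmd`) describes the
heat-conduction model and its assumptions, the solver numerics and time
stepping, the detection-limit protocol, the model-selection protocols,
and what the synthetic data do and do not emulate.
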