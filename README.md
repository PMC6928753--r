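# msplant3d

Nondestructive estimation of canopy nitrogen, phosphorus and potassium
(NPK) from **multispectral 3D point cloud models** of greenhouse plants.

A plant on a motorised turntable is imaged from four angles 90° apart by a
depth camera (RGB-D) and a hyperspectral imager. msplant3d fuses the two
modalities and carries the result through to nutrient prediction:

* **Spectral registration** — the spectral image is registered onto the
  depth camera's pixel frame from Fourier spectra alone: translation from
  the peak of the inverse FFT of the normalised cross-power spectrum,
  rotation θ₀ and scale σ by the Fourier–Mellin method (phase correlation
  on log-polar resampled FFT magnitudes). One shared transform maps every
  band of the reflectance cube.
* **Turntable self-calibration** — two frames of the turntable 180° apart
  locate a yellow and a red sticker; each pair's midpoint lies on the
  rotation axis M(a₀, b₀, c₀) and the chords' cross product gives the unit
  axis direction P(a, b, c).
* **Reconstruction** — depth pixels back-project through the pinhole model,
  x = (i−cₓ)z/fₓ, y = −(j−c_y)z/f_y, z = Depth/1000; each view is
  rough-registered by translating M to the origin, rotating P onto +Y
  (Rx(α), Rz(β)) and undoing the view's turntable angle γ about Y; and
  sequential point-to-point ICP refines the residuals. Every point keeps
  its per-band reflectance.
* **Quality metrics** — grayscale similarity D = 1 − Σ|M−F|/(m·n·255),
  spectral overlap C = 100·|F₂∧M₂|/|F₂|, and the directed Hausdorff
  distance set HD(RP, MP) = {min_b d(p_a, p_b)} with mean / population SD /
  max and segment proportions at 0.1, 0.3, 0.6 and 1.0 cm.
* **Wavelength selection** — Gaussian smoothing, removal of six
  infrared-interference bands (128 → 122), PCA loading peaks, per-band
  nutrient correlations, random-frog selection probabilities with a PLS
  inner model, and a documented combination rule (PCA-CC-RF).
* **Nutrient models** — BPANN (15 tanh hidden units, quasi-Newton), ε-SVR
  (Gaussian kernel), and rational-quadratic GPR, evaluated by Rc², Rp²,
  RMSEC, RMSEP and mean relative error; plus the Kjeldahl /
  molybdenum-antimony / flame-AAS mass-fraction formulas used for the
  reference chemistry.

A fully synthetic turntable-scene generator (`sceneSpec()`,
`makePlantCloud()`, `renderViews()`, `makeNpkDataset()`,
`makePlantedSignalSpectra()`) provides ground-truth clouds, depth frames,
displaced spectral cubes, sticker calibration frames and dose-structured
NPK spectra, so the entire pipeline is testable without hardware.

## Worked example

```r
library(msplant3d)

spec  <- sceneSpec(seed = 42, depthNoiseSd = 2)   # 4 views, 2 mm depth noise
plant <- makePlantCloud(spec)
scene <- renderViews(plant, spec)

calib <- estimateAxis(stickerCentroids(scene$stickerFrames$obs0),
                      stickerCentroids(scene$stickerFrames$obs180))
calib
#> AxisCalibration: center (0.0200, -0.3200, 1.2000) m, direction (0.0200, 0.9994, 0.0300)

views <- lapply(scene$views, function(v)
  list(depth = v$depth, stack = v$stack, gamma = v$gamma))
model <- reconstructViews(views, calib, spec$intrinsics)
model
#> MultispectralPointCloud: 14122 points, RGB, 5 bands (41.2% valid reflectance), 4 views

evaluateReconstruction(model, roughRegister(plant, calib, 0))
#> HDStats: n=14122, HD_avg=0.151 cm, HD_std=0.098 cm, HD_max=0.700 cm
#>   segments (0,0.1] (0.1,0.3] (0.3,0.6] (0.6,1] (1,Inf): 37.08 54.35 8.43 0.14 0.00 %
```

The recovered axis matches the scene's ground truth; with 2 mm depth noise
the reconstructed model sits on average 1.5 mm from the true surface, with
91 % of points within 3 mm. Points on the pot carry no reflectance (the
spectral imager frames only the canopy), hence the 41 % valid-reflectance
fraction. The mean canopy reflectance per characteristic band — the model
input for nutrient prediction — is then:

```r
round(extractCanopyReflectance(model), 4)
#> 451.60 544.10 585.70 696.30 739.00
#> 0.0860 0.1538 0.1370 0.3198 0.4550
```

Wavelength selection and a nutrient model on synthetic spectra:

```r
ds      <- makePlantedSignalSpectra(n = 200, snr = 10, seed = 7)
spectra <- removeInterferenceBands(smoothSpectra(ds$spectra))
rf      <- randomFrog(spectra, ds$y, nIter = 1000, seed = 7)
round(sort(rf, decreasing = TRUE)[1:6], 3)
#> 697.64 741.73 587.40 449.61 543.31 537.80
#>  0.997  0.952  0.945  0.930  0.898  0.509
ds$planted
#> [1] 449.61 543.31 587.40 697.64 741.73
```

The five highest selection probabilities are exactly the five planted
signal wavelengths. Fitting a GPR to nitrogen content on a 42/18
calibration/prediction split of a 60-plant dose-design dataset:

```r
npk <- makeNpkDataset(n = 60, seed = 7)
idx <- match(npk$planted$N, wavelengths(npk$spectra))
X   <- reflectance(npk$spectra)[, idx]
sp  <- calibrationSplit(60, 42, seed = 7)
fit <- fitGPR(X[sp$calib, ], npk$npk$N[sp$calib], seed = 7)
evaluateModel(fit, X[sp$calib, ], npk$npk$N[sp$calib],
              X[sp$pred, ],  npk$npk$N[sp$pred])
#>     Rc2 RMSEC   Rp2 RMSEP    RE
#> 1 0.998 0.300 0.997 0.365 0.722
```

RMSE values are in mg/g and RE in percent over the 18 prediction samples.

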