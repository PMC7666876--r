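# melsci

Multi-exposure laser speckle contrast imaging (MELSCI) pipeline:
simulation, contrast computation, camera-noise calibration, and
machine-learning perfusion estimation.

Laser speckle contrast imaging infers microcirculatory blood flow from
the motion blur of laser speckle: during a camera exposure, moving
scatterers decorrelate the speckle pattern and lower its spatial
contrast. A single exposure time confounds speed, concentration and
static tissue; the multi-exposure approach records how squared contrast
`K²(T)` decays over exposures of 1–64 ms and inverts that whole curve
into a perfusion estimate. This package implements the full processing
chain together with a dynamic-speckle simulator that provides exact
ground truth for every stage.

## The pipeline

1. **Simulate** (or load) a stack of 64 consecutive 1-ms frames
   (`scene_spec()`, `simulate_frame_stack()`, multi-page TIFF I/O).
   The simulator uses a per-pixel AR(1) complex Gaussian field with
   decorrelation time `tau`, dynamic fraction `rho`, and a camera model
   with shot, dark and fixed-pattern noise. Bit-reproducible from a
   seed.
2. **Synthesize exposures** of 2, 4, …, 64 ms by recursive pairwise
   frame summation — 7 exposure times, 127 images from one stack
   (`synthesize_exposures()`).
3. **Contrast**: variance in non-overlapping 4×4 pixel blocks (16×
   spatial reduction), averaged per exposure, divided by the squared
   scaled mean intensity: `K²(T) = σ²(T) / (T⟨I⟩)²`
   (`compute_contrast_cube()`). At 1000 fps input this is one cube per
   64 ms — 15.625 cubes/s.
4. **Calibrate the camera** on speckle-free illumination: the joint
   model `σ²(T, I) = T·I·N_shot + T·N_dark + T²·E_const` is fitted over
   a 24-level intensity sweep (`simulate_intensity_sweep()`,
   `fit_noise_model()`), subtracted in contrast space
   (`correct_contrast()`), and the result is normalized by the maximum
   contrast of a static target (`measure_kmax()`,
   `normalize_contrast()`).
5. **Estimate perfusion** per pixel: single-exposure indices
   `1/K²(T)` and `1/K(T) − 1`, or a small neural network (7–64–64–1,
   tanh) trained on the closed-form forward model with
   simulator-calibrated feature noise (`generate_training_set()`,
   `train_perfusion_net()`, `predict_perfusion()`); 2-s moving average
   and ROI traces via `temporal_smooth()` / `roi_trace()`.

A closed-form oracle, `theoretical_contrast(tau, T, rho, beta)`, gives
the exact expectation of `K²(T)` for the simulated scene model and
anchors the test suite.

## Worked example

```r
library(melsci)

# a homogeneous perfused patch: tau = 5 ms, fully dynamic, noisy sensor
sensor <- noise_spec(n_shot = 5, n_dark = 20, pattern_amplitude = 2, seed = 4)
scene  <- scene_spec(64, 64, tau = 5, rho = 1, mean_intensity = 1000,
                     noise = sensor, seed = 1)
stack  <- simulate_frame_stack(scene)
cube   <- compute_contrast_cube(stack)
print(cube)
#> MELSCI contrast cube [raw]: 16 x 16 px, T = 1,2,4,8,16,32,64 ms
#> mean K2(T) decaying from ~0.88 at 1 ms to ~0.08 at 64 ms

theoretical_contrast(5, c(1, 8, 64))
#> [1] 0.87900058 0.43764913 0.07507258

# calibrate the sensor once: noise fit + static-target contrast scale
cal <- calibrate_sensor(sensor, seed = 11)
coef(cal$fit)      # ~ (5, 20, 4): n_shot, n_dark, e_const = pattern sd^2
cal$scale$k2_max   # ~ 0.957

# correct, normalize, and estimate perfusion with the network
norm <- normalize_contrast(correct_contrast(cube, cal$fit), cal$scale)
net  <- train_perfusion_net(generate_training_set(10000, noise_sd = TRUE,
                                                  seed = 12), seed = 12)
net$metrics        # held-out R2 ~ 0.98, slope ~ 1.0
map  <- predict_perfusion(net, norm)
mean(map)          # perfusion units; 250 PU == (tau = 10 ms, rho = 0.5)
```

A command-line interface covers the same steps
(`melsci_cli("help")`): `simulate`, `contrast`, `fit-noise`,
`calibrate-kmax`, `train`, `perfuse`, `report`.

## Validation highlights

* Pooled Monte Carlo `K²(T)` of 200 noise-free 256×256 stacks
  (τ = 5 ms, ρ = 1) matches the closed form within 3 standard errors at
  all seven exposures (observed max |z| = 1.6, SE ≈ 1e-4).
* The default calibration sweep recovers `N_shot` to ~0.1 %, `N_dark`
  to ~3 %, `E_const` to ~3 %; weighted least squares and a Nelder–Mead
  cross-check agree to better than 4 significant figures.
* Corrected noise-only contrast is zero-mean within sampling error at
  every exposure; corrected noisy dynamic scenes match the noise-free
  closed form within 3 SE.
* The perfusion network reaches held-out R² ≈ 0.999 (slope ≈ 1.01) on
  noise-free samples and R² ≈ 0.98 with feature noise calibrated for
  the 2-s smoothing window; trained instead with the single-cube noise
  profile (`default_feature_noise(1)`), it orders flow states on an
  end-to-end simulated 20-point sweep at least as well as every
  single-exposure index (probe R² ≈ 0.98, margin +0.010 to +0.023
  across scenes).

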