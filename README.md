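# kubonet

Neural-network classification of simulated two-dimensional infrared (2D IR)
spectra.

2D IR resolves the frequency-fluctuation dynamics of a vibrational probe,
but conventional analyses (center-line slope, model fitting) need many
pump-time and waiting-time points, which makes data collection slow. When
the scientific question is binary — *is this sample the same as a reference
or not?* — most of that data may be unnecessary. kubonet provides the full
toolchain to study that question in simulation:

- a **Kubo line-shape simulator** of linear and third-order 2D-IR signals
  with anharmonicity and lifetime decay (`ffcf()`, `lineshape_g()`,
  `detect()`, `absorptive_spectrum()`, `center_line_slope()`);
- a **dataset generator** that defines classes by the percent-different
  magnitude (PDM) of Kubo parameters relative to a reference,

  PDM = sqrt( ((Δs − Δref)/Δref)² + ((τs − τref)/τref)² ),

  labels a sample *inside* when PDM ≤ b (default b = 0.10), concentrates
  draws at the boundary with a one-sided Cauchy radial law, and adds
  SNR-controlled Gaussian noise (`pdm()`, `sample_params()`,
  `generate_dataset()`);
- a **compact residual convolutional classifier** (1-D/2-D/3-D
  convolutions, batch norm, softmax pseudoprobabilities, cross-entropy,
  0.5-threshold accuracy, k-fold CV, Brier-score early stopping) written on
  fast compiled kernels (`build_classifier()`, `train_classifier()`);
- an **evaluation layer** computing Brier scores and Brier Skill Scores
  (BSS; 0 = chance, 1 = perfect) and scanning classification skill across
  every single (pump-time, waiting-time) spectral slice (`slice_scan()`,
  `error_map()`, `snr_bss_curve()`, `loss_rank_scores()`);
- **normalization and augmentation** utilities for experimental-style
  frequency–frequency spectra, plus a synthetic five-solvent panel
  generator (`normalize_spectrum()`, `balance_by_augmentation()`,
  `synth_solvent_panel()`).

## Worked example

Classify single spectral slices around the reference (Δ = 20/3 cm⁻¹,
τ = 5 ps) with a 10% PDM boundary at SNR 100:

```r
library(kubonet)

ref  <- kubo_component(20/3, 5)
grid <- time_grid(t3_axis = seq(0, 4, length.out = 64), n_pad = 64L)
spec <- dataset_spec(pdm_boundary_spec(ref, boundary = 0.10, cauchy_scale = 0.05),
                     n_samples = 2000L, snr = 100,
                     slice_selection = c(2, 3),   # t1 = 2 ps, t2 = 3 ps
                     grid = grid)
ds  <- generate_dataset(spec, seed = 1)
ds
#> kubonet dataset: 2000 samples (1000 inside / 1000 outside), payload
#> 64x1x1x2, 1600 train / 400 validation

fit <- train_classifier(ds, model_config(width = 8),
                        train_config(max_epochs = 100, batch_size = 100,
                                     learning_rate = 2e-3, lr_decay_epoch = 70,
                                     patience_epochs = 30,
                                     smoothing_window = 11, seed = 1))
summary(fit)
#> Residual classifier training summary
#>   epochs run:        60 (stopped at 60, best 20)
#>   best val Brier:    0.0689
#>   best val accuracy: 0.912 (final 0.892)
```

A validation accuracy of 91% means the network separates samples whose Kubo
parameters differ by ~10% — line-shape differences invisible by eye — from a
*single* complex detection-axis slice. Samples it still gets wrong sit
within ~0.005 PDM of the boundary (`error_map(fit, ds)`). Scanning all
slices shows which (pump-time, waiting-time) combinations are informative:

```r
map <- slice_scan(spec, t1_values = c(0, 1, 2), t2_values = c(0.75, 3, 6),
                  model_cfg = model_config(width = 8),
                  train_cfg = train_config(max_epochs = 100, batch_size = 100,
                                           learning_rate = 2e-3,
                                           lr_decay_epoch = 70,
                                           patience_epochs = 30,
                                           smoothing_window = 11, seed = 1),
                  seed = 1)
subset(as.data.frame(map), best_acc == max(best_acc))
#>   t1 t2  best_bss final_bss best_acc seed   ok
#> 6  2  3 0.7215933 0.6484791   0.9125    1 TRUE
```

Slices at later pump-times score best for this reference — the accumulated
phase evolution there encodes the fluctuation amplitude and correlation
time most distinctly — while the full 21 × 21 grid (441 networks per
reference, `slice_grid(time_grid())`) maps the whole landscape.

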