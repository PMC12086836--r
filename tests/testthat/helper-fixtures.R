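# Shared fixtures: small grids and datasets sized for fast unit tests.

test_sys <- function(delta = 6.7, tau = 5, ...) {
  system_params(kubo = kubo_component(delta, tau), ...)
}

# 64-point detection axis without padding: same detection-time extent (hence
# the same underlying resolution) as the default grid, minimal bin count.
tiny_grid <- function(t1_axis = seq(0, 4, by = 0.5), t2_axis = seq(0, 15, by = 3)) {
  time_grid(t1_axis = t1_axis, t2_axis = t2_axis,
            t3_axis = seq(0, 4, length.out = 64), n_pad = 64L)
}

tiny_dataset <- function(n = 200L, snr = 100, slice = c(1, 3), seed = 1L,
                         ref = kubo_component(20 / 3, 5)) {
  spec <- dataset_spec(pdm_boundary_spec(ref), n_samples = n, snr = snr,
                       slice_selection = slice, grid = tiny_grid())
  generate_dataset(spec, seed = seed)
}

fast_train_cfg <- function(epochs = 10L, seed = 1L, ...) {
  train_config(max_epochs = epochs, batch_size = 50L, learning_rate = 2e-3,
               early_stop = FALSE, seed = seed, ...)
}

# synthetic gaussian-noise dataset (no signal) for chance-level checks
noise_dataset <- function(n = 500L, len = 32L, seed = 1L) {
  set.seed(seed)
  x <- array(rnorm(len * 2 * n), dim = c(len, 1L, 1L, 2L, n))
  y <- rep(c(0L, 1L), length.out = n)
  n_train <- round(0.8 * n)
  idx <- sample.int(n, n_train)
  list(x = x, y = y, train_idx = sort(idx), val_idx = setdiff(seq_len(n), idx))
}
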