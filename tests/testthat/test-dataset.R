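test_that("PDM reproduces the worked boundary-straddling values", {
  ref <- c(20 / 3, 5)
  expect_equal(pdm(ref, ref), 0)
  expect_equal(pdm(ref, c(6.257, 5.386)), 0.0987, tolerance = 0.0005 / 0.0987)
  expect_equal(pdm(ref, c(6.244, 5.388)), 0.1002, tolerance = 0.0005 / 0.1002)
  # symmetric under which coordinate differs
  expect_equal(pdm(c(4, 4), c(5, 4)), pdm(c(4, 4), c(4, 5)))
  expect_error(pdm(c(-1, 5), c(6, 5)), "positive")
})

pdm_vec_check <- function(ref, delta, tau)
  sqrt(((delta - ref$delta) / ref$delta)^2 + ((tau - ref$tau) / ref$tau)^2)

test_that("boundary-focused sampling lands on the requested side", {
  spec <- pdm_boundary_spec(kubo_component(20 / 3, 5))
  set.seed(3)
  inside <- sample_params(spec, "inside", 500L)
  outside <- sample_params(spec, "outside", 500L)
  expect_true(all(inside$pdm <= spec$boundary))
  expect_true(all(outside$pdm > spec$boundary))
  # stored radial pdm agrees with the recomputed one
  expect_equal(inside$pdm,
               pdm_vec_check(spec$ref, inside$delta, inside$tau), tolerance = 1e-9)
  # all draws respect the parameter box
  pb <- spec$param_bounds
  expect_true(all(outside$delta >= pb$delta[1] & outside$delta <= pb$delta[2]))
  expect_true(all(outside$tau >= pb$tau[1] & outside$tau <= pb$tau[2]))
})

test_that("outside radial excess follows the box-truncated half-Cauchy law", {
  spec <- pdm_boundary_spec(kubo_component(20 / 3, 5), cauchy_scale = 0.05)
  set.seed(17)
  draws <- sample_params(spec, "outside", 1e5L)
  # independent Monte-Carlo replay of the radial rule: p = b + |Cauchy(0, g)|,
  # uniform angle, rejection outside the parameter box
  set.seed(99)
  r <- abs(rcauchy(4e5, 0, spec$cauchy_scale))
  th <- runif(4e5, 0, 2 * pi)
  p <- spec$boundary + r
  d <- spec$ref$delta * (1 + p * cos(th)); tt <- spec$ref$tau * (1 + p * sin(th))
  pb <- spec$param_bounds
  keep <- d >= pb$delta[1] & d <= pb$delta[2] & tt >= pb$tau[1] & tt <= pb$tau[2]
  expect_equal(median(draws$pdm - spec$boundary), median(p[keep] - spec$boundary),
               tolerance = 0.02)
  # the box trims only the far tail: the median stays near gamma itself
  expect_equal(median(draws$pdm - spec$boundary), 0.05, tolerance = 0.1)
  # heavy-tail sanity: most mass within 2 gamma of the boundary
  ins <- sample_params(spec, "inside", 1e4L)
  all_pdm <- c(draws$pdm[1:1e4], ins$pdm)
  expect_gte(mean(abs(all_pdm - 0.10) <= 0.1), 0.6)
})

test_that("add_noise calibrates sigma to peak/snr and normalizes", {
  set.seed(5)
  # spike signal: off-peak output elements are pure rescaled noise, so the
  # noise sd is measurable to the small rescaling uncertainty of the peak
  v <- complex(real = c(3, numeric(2e4 - 1)), imaginary = numeric(2e4))
  snr <- 50
  out <- add_noise(v, snr)
  expect_equal(max(abs(out)), 1)
  scale_back <- 3   # peak survives normalization to within O(1/snr)
  sigma_hat <- sd(c(Re(out[-1]), Im(out[-1]))) * scale_back
  expect_equal(sigma_hat, max(abs(v)) / snr, tolerance = 0.05)
  # snr = Inf only normalizes
  expect_equal(add_noise(v, Inf), v / max(abs(v)))
  expect_error(add_noise(0 * v, 10), "all-zero")
  expect_error(add_noise(v, -1), "positive")
})

test_that("slice extraction is pure indexing with full metadata", {
  p <- test_sys()
  g <- tiny_grid()
  sig <- detect(p, g)
  s <- extract_slice(sig, 0.5, 3)
  expect_s3_class(s, "ir_slice")
  expect_length(s$values, g$n_pad)
  expect_identical(s$values, sig$values[which(g$t1_axis == 0.5), which(g$t2_axis == 3), ])
  expect_error(extract_slice(sig, 0.123, 3), "not on the signal grid")
  # the (0, 0) slice carries the largest peak amplitude over the grid
  peaks <- apply(abs(sig$values), c(1, 2), max)
  expect_equal(unname(which(peaks == max(peaks), arr.ind = TRUE)[1, ]), c(1L, 1L))
})

test_that("channel encoding splits complex payloads losslessly", {
  set.seed(2)
  z <- complex(real = rnorm(64), imaginary = rnorm(64))
  enc <- encode_channels(z)
  expect_equal(dim(enc), c(64L, 1L, 1L, 2L))
  expect_equal(decode_channels(enc), z)
  r <- matrix(rnorm(25), 5, 5)
  enc2 <- encode_channels(r)
  expect_equal(dim(enc2), c(5L, 5L, 1L, 1L))   # real payload: single channel
  expect_equal(decode_channels(enc2), r)
  # after noise normalization channel maxima are bounded by 1
  zn <- add_noise(z, 10)
  expect_lte(max(abs(encode_channels(zn))), 1)
})

test_that("generate_dataset honors balance, split, and determinism", {
  ds <- tiny_dataset(n = 200L, seed = 9L)
  expect_equal(sum(ds$y == 1L), 100L)
  expect_equal(sum(ds$y == 0L), 100L)
  expect_length(ds$train_idx, 160L)
  expect_length(ds$val_idx, 40L)
  expect_length(intersect(ds$train_idx, ds$val_idx), 0L)
  # label consistency with the PDM rule, exhaustively
  b <- ds$spec$boundary$boundary
  expect_identical(ds$y, as.integer(ds$params$pdm <= b))
  # same seed -> byte-identical
  ds2 <- tiny_dataset(n = 200L, seed = 9L)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$params, ds2$params)
  # different seed differs
  ds3 <- tiny_dataset(n = 200L, seed = 10L)
  expect_false(identical(ds$x, ds3$x))
})

test_that("uniform test set matches the boundary-disk geometry", {
  bspec <- pdm_boundary_spec(kubo_component(20 / 3, 5), boundary = 0.10)
  bounds <- list(delta = (20 / 3) * c(0.7, 1.3), tau = 5 * c(0.7, 1.3))
  ts <- generate_uniform_testset(bounds, 1e5L, bspec, seed = 4L)
  expect_true(all(ts$params$delta >= bounds$delta[1] & ts$params$delta <= bounds$delta[2]))
  expect_identical(ts$y, as.integer(ts$params$pdm <= 0.10))
  # inside fraction = area(PDM disk) / area(box); the disk radius b in
  # fractional coordinates maps to an ellipse of area pi b^2 delta_ref tau_ref
  p_expect <- (pi * 0.10^2 * (20 / 3) * 5) / (diff(bounds$delta) * diff(bounds$tau))
  expect_equal(mean(ts$y), p_expect, tolerance = 0.02 / p_expect)
})

test_that("dataset serialization round-trips through the text container", {
  ds <- tiny_dataset(n = 20L, seed = 2L)
  dir <- file.path(tempdir(), "ds_roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$x, ds$x, tolerance = 1e-12)
  expect_identical(back$y, ds$y)
  expect_equal(back$params$pdm, ds$params$pdm)
  expect_identical(back$train_idx, ds$train_idx)
  unlink(dir, recursive = TRUE)
})
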