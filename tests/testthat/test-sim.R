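C_CMPS <- 2.99792458e-2

test_that("FFCF matches the Kubo closed form", {
  k <- kubo_component(6.67, 5)
  dw <- 2 * pi * C_CMPS * 6.67
  expect_equal(ffcf(k, 0), dw^2)
  expect_equal(ffcf(k, 5), dw^2 / exp(1))
  # direct high-precision arithmetic oracle at t = 2.5 ps
  expect_equal(ffcf(k, 2.5), dw^2 * exp(-0.5), tolerance = 1e-12)
  # two components add
  k2 <- list(kubo_component(3, 1), kubo_component(4, 2))
  expect_equal(ffcf(k2, 1.3),
               (2 * pi * C_CMPS * 3)^2 * exp(-1.3) + (2 * pi * C_CMPS * 4)^2 * exp(-0.65))
  expect_error(ffcf(k, -1), "nonnegative")
})

test_that("line-broadening function equals the double integral of the FFCF", {
  g_numeric <- function(k, t) {
    stats::integrate(function(u) {
      vapply(u, function(uu)
        stats::integrate(function(s) ffcf(k, s), 0, uu, rel.tol = 1e-10)$value,
        numeric(1L))
    }, 0, t, rel.tol = 1e-10)$value
  }
  k <- kubo_component(6.67, 5)
  dw <- 2 * pi * C_CMPS * 6.67
  expect_equal(lineshape_g(k, 0), 0)
  expect_equal(lineshape_g(k, 5), dw^2 * 25 / exp(1))
  for (t in c(0.1, 1, 10))
    expect_equal(lineshape_g(k, t), g_numeric(k, t), tolerance = 1e-6)
  # grid of (t, delta, tau) combinations against the numerical oracle
  for (delta in c(2, 6.67, 12)) for (tau in c(0.5, 2, 8)) {
    kk <- kubo_component(delta, tau)
    for (t in c(0.3, 3)) {
      expect_equal(lineshape_g(kk, t) / g_numeric(kk, t), 1, tolerance = 1e-6)
    }
  }
  # monotone nondecreasing
  tg <- seq(0, 20, by = 0.25)
  expect_true(all(diff(lineshape_g(k, tg)) >= 0))
})

test_that("response functions obey the three-level cancellation identities", {
  p <- test_sys()
  # t3 = 0: GSB+SE and ESA oscillators cancel under harmonic dipole scaling
  expect_equal(response_rephasing(p, 0.7, 2, 0), 0 + 0i)
  expect_equal(response_nonrephasing(p, 1.3, 0.4, 0), 0 + 0i)
  # anharm = 0: two-level cancellation at all times
  p0 <- system_params(anharm = 0, kubo = kubo_component(6.7, 5))
  expect_equal(response_rephasing(p0, 0.5, 1, 0.7), 0 + 0i)
  expect_equal(response_nonrephasing(p0, 0.5, 1, 0.7), 0 + 0i)
  # t1 = 0: both pathways coincide (identical phase and g-combination)
  for (t2 in c(0, 2)) for (t3 in c(0.3, 1.1)) {
    expect_equal(response_rephasing(p, 0, t2, t3),
                 response_nonrephasing(p, 0, t2, t3), tolerance = 1e-12)
  }
  expect_error(response_rephasing(p, -0.1, 0, 0), "nonnegative")
})

test_that("response g-sign patterns match an independent term-by-term expansion", {
  p <- test_sys(delta = 5.1, tau = 2.3)
  g <- function(t) lineshape_g(p$kubo, t)
  w01 <- 2 * pi * C_CMPS * (p$omega01 - p$rotating_frame)
  dan <- 2 * pi * C_CMPS * p$anharm
  set.seed(11)
  for (i in 1:5) {
    t1 <- runif(1, 0, 3); t2 <- runif(1, 0, 10); t3 <- runif(1, 0, 3)
    osc <- 2 * exp(-1i * w01 * t3) - 2 * exp(-1i * (w01 - dan) * t3)
    life <- exp(-(t1 + t3) / (2 * p$t1_lifetime) - t2 / p$t1_lifetime)
    er <- exp(-g(t1) + g(t2) - g(t3) - g(t1 + t2) - g(t2 + t3) + g(t1 + t2 + t3))
    en <- exp(-g(t1) - g(t2) - g(t3) + g(t1 + t2) + g(t2 + t3) - g(t1 + t2 + t3))
    expect_equal(response_rephasing(p, t1, t2, t3),
                 osc * exp(1i * w01 * t1) * er * life, tolerance = 1e-12)
    expect_equal(response_nonrephasing(p, t1, t2, t3),
                 osc * exp(-1i * w01 * t1) * en * life, tolerance = 1e-12)
  }
})

test_that("response envelope decays with pump and detection time at long waiting time", {
  p <- test_sys()
  t2 <- 15   # decorrelated regime: broadening + lifetime give a monotone envelope
  a_t1 <- abs(response_rephasing(p, seq(0, 4, by = 0.25), t2, 0.5))
  expect_true(all(diff(a_t1) < 0))
  # along t3 the anharmonic beat modulates |R|; sample at a fixed beat phase
  # (multiples of the 1/(c * anharm) period) to expose the decaying envelope
  beat <- 1 / (C_CMPS * p$anharm)
  a_t3 <- abs(response_rephasing(p, 0.5, t2, 0.25 + beat * (0:2)))
  expect_true(all(diff(a_t3) < 0))
})

test_that("detection transform reproduces the Lorentzian Fourier pair", {
  t2dephase <- 0.3
  tg <- time_grid(t3_axis = seq(0, 4, length.out = 128), n_pad = 512L)
  dt <- tg$t3_axis[2]
  decay <- matrix(exp(-tg$t3_axis / t2dephase) + 0i, ncol = 1)
  s <- Re(kubonet:::detect_transform(decay, 128L, 512L))
  axis <- kubonet:::fft_freq_axis(512L, dt)
  hwhm <- spectral_fwhm(as.vector(s), axis) / 2
  expect_equal(hwhm, 1 / (2 * pi * C_CMPS * t2dephase),
               tolerance = (axis[2] - axis[1]) / (1 / (2 * pi * C_CMPS * t2dephase)))
})

test_that("detect satisfies the discrete Parseval relation and pads stably", {
  p <- test_sys()
  g <- tiny_grid()
  sig <- detect(p, g)
  # Parseval at a few cells against the halved, padded time series
  for (cell in list(c(1L, 1L), c(3L, 2L), c(5L, 4L))) {
    t1 <- g$t1_axis[cell[1]]; t2 <- g$t2_axis[cell[2]]
    r <- response_rephasing(p, t1, t2, g$t3_axis) +
      response_nonrephasing(p, t1, t2, g$t3_axis)
    r[1] <- r[1] / 2
    lhs <- sum(abs(sig$values[cell[1], cell[2], ])^2)
    rhs <- g$n_pad * sum(abs(r)^2)
    expect_equal(lhs / rhs, 1, tolerance = 1e-8)
  }
  # doubling n_pad interpolates: argmax moves less than one original bin
  g2 <- time_grid(t1_axis = g$t1_axis, t2_axis = g$t2_axis,
                  t3_axis = g$t3_axis, n_pad = 128L)
  sig2 <- detect(p, g2)
  # track the positive-going fundamental (real channel), which is unimodal
  w1 <- sig$omega3_axis[which.max(Re(sig$values[1, 1, ]))]
  w2 <- sig2$omega3_axis[which.max(Re(sig2$values[1, 1, ]))]
  bin <- diff(sig$omega3_axis[1:2])
  expect_lte(abs(w1 - w2), bin + 1e-9)
  expect_error(time_grid(t3_axis = seq(0, 4, length.out = 64), n_pad = 32L), "n_pad")
})

test_that("absorptive spectrum places the fundamental and ESA features correctly", {
  p <- test_sys()
  g <- time_grid()
  sp <- absorptive_spectrum(p, 0, g)
  i <- which(abs(sp$values) == max(abs(sp$values)), arr.ind = TRUE)
  b1 <- diff(sp$omega1_axis[1:2]); b3 <- diff(sp$omega3_axis[1:2])
  expect_lt(abs(sp$omega1_axis[i[1]] - p$omega01), b1 + 1e-9)
  expect_lt(abs(sp$omega3_axis[i[2]] - p$omega01), b3 + 1e-9)
  expect_gt(sp$values[i], 0)  # fundamental positive-going
  # ESA: most negative value along omega3 at the pump resonance
  row <- which.min(abs(sp$omega1_axis - p$omega01))
  j <- which.min(sp$values[row, ])
  expect_lt(abs(sp$omega3_axis[j] - (p$omega01 - p$anharm)), 2 * b3)
  expect_lt(sp$values[row, j], 0)
  # off-grid waiting time refused
  expect_error(absorptive_spectrum(p, 0.123, g), "not on the waiting-time grid")
})

test_that("inhomogeneous-limit spectrum elongates along the diagonal at t2 = 0", {
  p <- test_sys(delta = 12, tau = 40)   # Dw * tau ~ 90
  g <- time_grid(t1_axis = seq(0, 3, by = 0.15), t2_axis = c(0, 1),
                 t3_axis = seq(0, 3, length.out = 64), n_pad = 256L)
  sp <- absorptive_spectrum(p, 0, g, n_pad1 = 256L)
  # sample the positive feature along diagonal and antidiagonal cuts
  i <- which(abs(sp$values) == max(abs(sp$values)), arr.ind = TRUE)
  offs <- seq(-40, 40, by = 0.5)
  interp <- function(d1, d3) {
    pracma::interp2(x = sp$omega3_axis, y = sp$omega1_axis, Z = sp$values,
                    xp = sp$omega3_axis[i[2]] + d3, yp = sp$omega1_axis[i[1]] + d1)
  }
  diag_cut <- interp(offs, offs)
  anti_cut <- interp(offs, -offs)
  w_diag <- spectral_fwhm(diag_cut, offs * sqrt(2))
  w_anti <- spectral_fwhm(anti_cut, offs * sqrt(2))
  expect_gt(w_diag, w_anti)
})

test_that("linear absorption interpolates between Lorentzian and Gaussian limits", {
  # motional narrowing, Dw * tau = 0.1: FWHM -> 2 * Dw^2 * tau (rad/ps)
  tau <- 2; delta <- 0.1 / (2 * pi * C_CMPS * tau)
  dw <- 2 * pi * C_CMPS * delta
  p1 <- system_params(t1_lifetime = 1e6, kubo = kubo_component(delta, tau))
  gl <- time_grid(t3_axis = seq(0, 2000, length.out = 4096), n_pad = 8192L)
  la1 <- linear_absorption(p1, gl)
  expect_equal(spectral_fwhm(la1$values, la1$omega_axis),
               2 * dw^2 * tau / (2 * pi * C_CMPS), tolerance = 0.1)
  # inhomogeneous limit, Dw * tau = 50: FWHM -> 2 sqrt(2 ln 2) Dw
  delta2 <- 6.67; dw2 <- 2 * pi * C_CMPS * delta2; tau2 <- 50 / dw2
  p2 <- system_params(t1_lifetime = 1e6, kubo = kubo_component(delta2, tau2))
  gg <- time_grid(t3_axis = seq(0, 4, length.out = 256), n_pad = 2048L)
  la2 <- linear_absorption(p2, gg)
  expect_equal(spectral_fwhm(la2$values, la2$omega_axis),
               2 * sqrt(2 * log(2)) * dw2 / (2 * pi * C_CMPS), tolerance = 0.1)
  # peak at omega01 within a bin
  expect_lt(abs(la2$omega_axis[which.max(la2$values)] - p2$omega01),
            diff(la2$omega_axis[1:2]) + 1e-9)
  # FWHM grows monotonically with Dw * tau between the limits
  widths <- vapply(c(0.5, 2, 8, 32), function(dwt) {
    d <- 6.67; tt <- dwt / (2 * pi * C_CMPS * d)
    pp <- system_params(t1_lifetime = 1e6, kubo = kubo_component(d, tt))
    gw <- time_grid(t3_axis = seq(0, 30, length.out = 512), n_pad = 4096L)
    la <- linear_absorption(pp, gw)
    spectral_fwhm(la$values, la$omega_axis)
  }, numeric(1L))
  expect_true(all(diff(widths) > 0))
})

test_that("center-line slope tracks the normalized FFCF", {
  p <- test_sys()   # Dw * tau = 6.3
  g <- time_grid()
  t2s <- c(0, 1.5, 3, 4.5, 6, 9)
  specs <- lapply(t2s, function(t2) absorptive_spectrum(p, t2, g))
  cls <- center_line_slope(specs)
  expect_true(all(cls > 0 & cls <= 1))
  expect_true(all(diff(cls) < 0))   # spectral diffusion decorrelates
  # CLS(t2)/CLS(0) ~ exp(-t2/tau) within 15%
  ratio <- cls / cls[1]
  expect_equal(as.vector(ratio), exp(-t2s / 5), tolerance = 0.15)
  # single-exponential fit recovers tau within 20%
  tau_fit <- -1 / coef(lm(log(as.vector(cls)) ~ t2s))[2]
  expect_equal(unname(tau_fit), 5, tolerance = 0.2)
})

test_that("CLS approaches one in the inhomogeneous limit", {
  p <- test_sys(delta = 12, tau = 40)
  g <- time_grid(t1_axis = seq(0, 3, by = 0.15), t2_axis = c(0, 1),
                 t3_axis = seq(0, 3, length.out = 64), n_pad = 256L)
  specs <- lapply(c(0, 1), function(t2) absorptive_spectrum(p, t2, g, n_pad1 = 256L))
  cls <- center_line_slope(specs)
  expect_gte(cls[1], 0.8)
  expect_lte(cls[1], 1.0)
})
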