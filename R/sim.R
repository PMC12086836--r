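#' Frequency-fluctuation correlation function (FFCF)
#'
#' Evaluates the multi-component Kubo FFCF
#' `C(t) = sum_i Dw_i^2 * exp(-t / tau_i)` with `Dw_i = 2*pi*c*delta_i`
#' converting each fluctuation amplitude from cm^-1 to angular frequency
#' (rad/ps).
#'
#' @param kubo a `kubo_component` or list of them
#' @param t time(s) in ps (>= 0)
#' @return correlation value(s) in rad^2/ps^2
#' @examples
#' ffcf(kubo_component(6.67, 5), c(0, 5))
#' @export
ffcf <- function(kubo, t) {
  kubo <- as_kubo_list(kubo)
  if (any(t < 0)) stop_domain("`t` must be nonnegative")
  out <- numeric(length(t))
  for (k in kubo) {
    dw <- wn2ang(k$delta)
    out <- out + dw^2 * exp(-t / k$tau)
  }
  out
}

#' Line-broadening function g(t)
#'
#' The double time-integral of the FFCF, entering the exponents of the
#' third-order response functions. For a sum of Kubo components the closed
#' form is `g(t) = sum_i Dw_i^2 tau_i^2 (exp(-t/tau_i) + t/tau_i - 1)`;
#' dimensionless, nonnegative, and monotone nondecreasing in `t`.
#'
#' @inheritParams ffcf
#' @return broadening value(s), dimensionless
#' @examples
#' lineshape_g(kubo_component(6.67, 5), c(0, 1, 10))
#' @export
lineshape_g <- function(kubo, t) {
  kubo <- as_kubo_list(kubo)
  if (any(t < 0)) stop_domain("`t` must be nonnegative")
  out <- numeric(length(t))
  for (k in kubo) {
    dw <- wn2ang(k$delta)
    x <- t / k$tau
    out <- out + dw^2 * k$tau^2 * (exp(-x) + x - 1)
  }
  out
}

resp_core <- function(p, t1, t2, t3, pathway) {
  if (any(t1 < 0) || any(t2 < 0) || any(t3 < 0))
    stop_domain("response times must be nonnegative")
  g <- function(t) lineshape_g(p$kubo, t)
  w01 <- wn2ang(p$omega01 - p$rotating_frame)
  dan <- wn2ang(p$anharm)
  osc3 <- 2 * exp(-1i * w01 * t3) - 2 * exp(-1i * (w01 - dan) * t3)
  life <- exp(-(t1 + t3) / (2 * p$t1_lifetime) - t2 / p$t1_lifetime)
  if (pathway == "rephasing") {
    ex <- -g(t1) + g(t2) - g(t3) - g(t1 + t2) - g(t2 + t3) + g(t1 + t2 + t3)
    pump <- exp(+1i * w01 * t1)
  } else {
    ex <- -g(t1) - g(t2) - g(t3) + g(t1 + t2) + g(t2 + t3) - g(t1 + t2 + t3)
    pump <- exp(-1i * w01 * t1)
  }
  osc3 * pump * exp(ex) * life
}

#' Third-order rephasing response function
#'
#' Kubo/cumulant response for a three-level vibrational ladder with harmonic
#' dipole scaling: ground-state bleach plus stimulated emission (weight 2 at
#' the fundamental) minus excited-state absorption (weight 2, shifted by the
#' anharmonicity), a line-broadening exponent
#' `exp(-g(t1)+g(t2)-g(t3)-g(t1+t2)-g(t2+t3)+g(t1+t2+t3))`, and population
#' relaxation `exp(-(t1+t3)/(2*T1) - t2/T1)`. Phases are expressed in the
#' rotating frame of `p$rotating_frame`. Arguments are recycled elementwise.
#'
#' @param p a [system_params()] object
#' @param t1,t2,t3 pump, waiting, and detection times in ps (>= 0)
#' @return complex amplitude(s)
#' @export
response_rephasing <- function(p, t1, t2, t3) resp_core(p, t1, t2, t3, "rephasing")

#' Third-order non-rephasing response function
#'
#' As [response_rephasing()] but with broadening exponent
#' `exp(-g(t1)-g(t2)-g(t3)+g(t1+t2)+g(t2+t3)-g(t1+t2+t3))` and pump phase
#' `exp(-i*w01*t1)`.
#'
#' @inheritParams response_rephasing
#' @return complex amplitude(s)
#' @export
response_nonrephasing <- function(p, t1, t2, t3) resp_core(p, t1, t2, t3, "nonrephasing")

# Detection-axis transform: one-sided discrete FT with the first time point
# weighted 1/2 (trapezoid-consistent), zero-padded to n_pad, kernel
# exp(+i*omega*t). Input: matrix (n_t3 x m). Output: matrix (n_pad x m),
# fftshifted so the frequency axis is increasing.
detect_transform <- function(rmat, n_t3, n_pad) {
  rmat[1L, ] <- rmat[1L, ] * 0.5
  padded <- matrix(0 + 0i, n_pad, ncol(rmat))
  padded[seq_len(n_t3), ] <- rmat
  s <- stats::mvfft(padded, inverse = TRUE)
  s[fftshift_index(n_pad), , drop = FALSE]
}

fftshift_index <- function(n) c((n %/% 2 + 1L):n, 1L:(n %/% 2))

fft_freq_axis <- function(n, dt) {
  k <- seq.int(-(n %/% 2), n - n %/% 2 - 1L)
  k / (n * dt * C_CMPS)
}

# Vectorized response over a t1 vector and t3 vector at fixed t2, for one
# sample; returns complex (n_t1 x n_t3) including pump phase and lifetime.
response_block <- function(p, t1_vec, t2, t3_vec, pathway) {
  g <- function(t) lineshape_g(p$kubo, t)
  w01 <- wn2ang(p$omega01 - p$rotating_frame)
  dan <- wn2ang(p$anharm)
  n1 <- length(t1_vec); n3 <- length(t3_vec)
  g1 <- g(t1_vec); g3 <- g(t3_vec); g2 <- g(t2)
  g12 <- g(t1_vec + t2); g23 <- g(t2 + t3_vec)
  g123 <- matrix(g(outer(t1_vec + t2, t3_vec, `+`)), n1, n3)
  if (pathway == "rephasing") {
    ex <- -g1 + g2 - g12 + g123 - matrix(g3 + g23, n1, n3, byrow = TRUE)
    pump <- exp(+1i * w01 * t1_vec)
  } else {
    ex <- -g1 - g2 + g12 - g123 + matrix(-g3 + g23, n1, n3, byrow = TRUE)
    pump <- exp(-1i * w01 * t1_vec)
  }
  osc3 <- 2 * exp(-1i * w01 * t3_vec) - 2 * exp(-1i * (w01 - dan) * t3_vec)
  life <- exp(-t2 / p$t1_lifetime) *
    outer(exp(-t1_vec / (2 * p$t1_lifetime)), exp(-t3_vec / (2 * p$t1_lifetime)))
  (pump * exp(ex)) * matrix(osc3, n1, n3, byrow = TRUE) * life
}

#' Simulate the mixed-domain third-order signal
#'
#' Evaluates the summed rephasing + non-rephasing response on the full
#' (t1, t2, t3) grid and applies the detection transform over t3 (first point
#' halved, zero-padded to `grid$n_pad`), yielding the complex signal
#' `S(t1, t2, omega3)`. The detection frequency axis is shifted back out of
#' the rotating frame to absolute cm^-1.
#'
#' @param p a [system_params()] object
#' @param grid a [time_grid()] object
#' @return a `mixed_domain_signal`
#' @examples
#' sig <- detect(system_params(kubo = kubo_component(6.7, 5)), screen_grid())
#' @export
detect <- function(p, grid) {
  stopifnot(inherits(p, "system_params"), inherits(grid, "time_grid"))
  n1 <- length(grid$t1_axis); n2 <- length(grid$t2_axis)
  n3 <- length(grid$t3_axis); np <- grid$n_pad
  dt3 <- grid$t3_axis[2L] - grid$t3_axis[1L]
  vals <- array(0 + 0i, dim = c(n1, n2, np))
  for (j in seq_len(n2)) {
    r <- response_block(p, grid$t1_axis, grid$t2_axis[j], grid$t3_axis, "rephasing") +
      response_block(p, grid$t1_axis, grid$t2_axis[j], grid$t3_axis, "nonrephasing")
    s <- detect_transform(t(r), n3, np)   # (np x n1)
    vals[, j, ] <- t(s)
  }
  omega3 <- p$rotating_frame + fft_freq_axis(np, dt3)
  new_mixed_domain_signal(vals, grid$t1_axis, grid$t2_axis, omega3, p)
}

# Vectorized single-slice simulator: for fixed (t1, t2), computes the complex
# detection-axis slice for many samples that differ only in the (delta, tau)
# of a single varied Kubo component. Returns list(values = (n_pad x n)
# complex matrix, omega3_axis).
simulate_slices <- function(delta, tau, sys, t1, t2, grid) {
  stopifnot(length(delta) == length(tau))
  n <- length(delta); t3 <- grid$t3_axis
  n3 <- length(t3); np <- grid$n_pad
  dt3 <- t3[2L] - t3[1L]
  dw <- wn2ang(delta)
  gfun <- function(t) {
    # (n x length(t)) matrix of per-sample g values
    x <- outer(1 / tau, t)             # t/tau
    (dw^2 * tau^2) * (exp(-x) + x - 1)
  }
  g3 <- gfun(t3); g23 <- gfun(t2 + t3); g123 <- gfun(t1 + t2 + t3)
  g1 <- as.vector(gfun(t1)); g2 <- as.vector(gfun(t2)); g12 <- as.vector(gfun(t1 + t2))
  ex_r <- (-g1 + g2 - g12) + (-g3 - g23 + g123)
  ex_nr <- (-g1 - g2 + g12) + (-g3 + g23 - g123)
  w01 <- wn2ang(sys$omega01 - sys$rotating_frame)
  dan <- wn2ang(sys$anharm)
  osc3 <- 2 * exp(-1i * w01 * t3) - 2 * exp(-1i * (w01 - dan) * t3)
  life <- exp(-(t1 + t3) / (2 * sys$t1_lifetime) - t2 / sys$t1_lifetime)
  pump_r <- exp(+1i * w01 * t1); pump_nr <- exp(-1i * w01 * t1)
  resp <- (pump_r * exp(ex_r) + pump_nr * exp(ex_nr)) *
    matrix(osc3 * life, n, n3, byrow = TRUE)    # (n x n3)
  s <- detect_transform(t(resp), n3, np)        # (np x n)
  list(values = s, omega3_axis = sys$rotating_frame + fft_freq_axis(np, dt3))
}

#' Purely absorptive frequency-frequency spectrum
#'
#' Double Fourier transform of the summed pathways at one waiting time: the
#' rephasing signal is transformed over t1 with the conjugated pump-phase
#' kernel and the non-rephasing signal with the direct kernel, so both place
#' the fundamental at (+omega01, +omega01); the real part of the sum is the
#' purely absorptive spectrum. The 0->1 feature is positive-going and the
#' excited-state absorption negative-going, displaced by the anharmonicity
#' along the probe axis.
#'
#' @param p a [system_params()] object
#' @param t2 waiting time in ps; must be a point of `grid$t2_axis`
#' @param grid a [time_grid()] object
#' @param n_pad1 zero-padding length for the pump transform (default 256)
#' @return a `spectrum2d`
#' @export
absorptive_spectrum <- function(p, t2, grid, n_pad1 = 256L) {
  stopifnot(inherits(p, "system_params"), inherits(grid, "time_grid"))
  if (min(abs(grid$t2_axis - t2)) > 1e-9)
    stop_domain("`t2` is not on the waiting-time grid; interpolation is refused")
  t1 <- grid$t1_axis; t3 <- grid$t3_axis
  n1 <- length(t1); n3 <- length(t3); np3 <- grid$n_pad
  n_pad1 <- as.integer(n_pad1)
  if (n_pad1 < n1) stop_domain("`n_pad1` must be at least the length of `t1_axis`")
  dt1 <- t1[2L] - t1[1L]; dt3 <- t3[2L] - t3[1L]

  sr <- detect_transform(t(response_block(p, t1, t2, t3, "rephasing")), n3, np3)
  snr <- detect_transform(t(response_block(p, t1, t2, t3, "nonrephasing")), n3, np3)
  # sr, snr: (np3 x n1) == (omega3 x t1); now pump-axis transform
  pump_transform <- function(s, inverse) {
    m <- t(s)                      # (t1 x omega3)
    m[1L, ] <- m[1L, ] * 0.5
    padded <- matrix(0 + 0i, n_pad1, ncol(m))
    padded[seq_len(n1), ] <- m
    out <- stats::mvfft(padded, inverse = inverse)
    out[fftshift_index(n_pad1), , drop = FALSE]   # (omega1 x omega3)
  }
  a <- Re(pump_transform(sr, inverse = FALSE) + pump_transform(snr, inverse = TRUE))
  omega1 <- p$rotating_frame + fft_freq_axis(n_pad1, dt1)
  omega3 <- p$rotating_frame + fft_freq_axis(np3, dt3)
  new_spectrum2d(a, omega1, omega3, t2, p)
}

#' Linear absorption spectrum
#'
#' One-sided Fourier transform of `exp(-g(t) - t/(2*T1)) * exp(-i*w01*t)`
#' evaluated on the detection-time axis of `grid`. Used as a simulator
#' validity check via its motional-narrowing (Lorentzian) and inhomogeneous
#' (Gaussian) limits.
#'
#' @inheritParams absorptive_spectrum
#' @return a list with `values` (real spectrum) and `omega_axis` (cm^-1)
#' @export
linear_absorption <- function(p, grid) {
  stopifnot(inherits(p, "system_params"), inherits(grid, "time_grid"))
  t3 <- grid$t3_axis; np <- grid$n_pad
  dt <- t3[2L] - t3[1L]
  w01 <- wn2ang(p$omega01 - p$rotating_frame)
  s <- exp(-lineshape_g(p$kubo, t3) - t3 / (2 * p$t1_lifetime)) * exp(-1i * w01 * t3)
  v <- Re(detect_transform(matrix(s, ncol = 1L), length(t3), np))
  list(values = as.vector(v), omega_axis = p$rotating_frame + fft_freq_axis(np, dt))
}

#' Full width at half maximum of a sampled peak
#'
#' Linear interpolation of the half-maximum crossings around the global
#' maximum of a single-peaked real spectrum.
#'
#' @param values real spectrum values
#' @param axis matching axis values (uniform, increasing)
#' @return FWHM in axis units
#' @export
spectral_fwhm <- function(values, axis) {
  i <- which.max(values)
  half <- values[i] / 2
  lo <- which(values[seq_len(i)] < half)
  hi <- which(values[i:length(values)] < half)
  if (!length(lo) || !length(hi)) stop_domain("peak not resolved within the axis window")
  l <- max(lo)   # last below-half index left of peak
  r <- i - 1L + min(hi)
  xl <- axis[l] + (half - values[l]) / (values[l + 1L] - values[l]) * (axis[l + 1L] - axis[l])
  xr <- axis[r - 1L] + (half - values[r - 1L]) / (values[r] - values[r - 1L]) * (axis[r] - axis[r - 1L])
  xr - xl
}

#' Center-line slope (CLS) of the 0->1 feature
#'
#' For each spectrum, locates the probe-frequency maximum of the fundamental
#' feature (with three-point parabolic interpolation) for pump frequencies
#' within `window` of `omega01`, and returns the slope of the fitted center
#' line. The CLS as a function of waiting time approximates the normalized
#' FFCF and is used as a simulator validity check.
#'
#' @param spectra list of `spectrum2d` at increasing waiting times, sharing axes
#' @param omega01 fundamental frequency (cm^-1); default taken from the
#'   spectra's attached simulation parameters
#' @param window pump-frequency half-window in cm^-1 (default: the fluctuation
#'   amplitude of the first Kubo component)
#' @return numeric CLS values, one per spectrum, with waiting times as names;
#'   `NA` where the center line is degenerate (flagged by a warning)
#' @export
center_line_slope <- function(spectra, omega01 = NULL, window = NULL) {
  if (length(spectra) < 2L) stop_domain("need spectra at >= 2 waiting times")
  ax1 <- spectra[[1L]]$omega1_axis; ax3 <- spectra[[1L]]$omega3_axis
  for (s in spectra)
    if (!isTRUE(all.equal(s$omega1_axis, ax1)) || !isTRUE(all.equal(s$omega3_axis, ax3)))
      stop_domain("all spectra must share frequency axes")
  p <- spectra[[1L]]$params
  omega01 <- omega01 %||% p$omega01
  window <- window %||% p$kubo[[1L]]$delta
  anharm <- if (!is.null(p)) p$anharm else Inf
  t2s <- vapply(spectra, function(s) s$t2, numeric(1L))
  if (any(diff(t2s) <= 0)) stop_domain("spectra must be ordered by increasing t2")

  rows <- which(abs(ax1 - omega01) <= window)
  keep3 <- ax3 >= omega01 - min(anharm, 2 * window) / 2   # exclude the ESA feature
  cls <- vapply(spectra, function(s) {
    centers <- rep(NA_real_, length(rows))
    for (ii in seq_along(rows)) {
      v <- s$values[rows[ii], ]
      v[!keep3] <- -Inf
      m <- which.max(v)
      if (m <= 1L || m >= length(v) || !is.finite(v[m - 1L]) || !is.finite(v[m + 1L])) next
      denom <- v[m - 1L] - 2 * v[m] + v[m + 1L]
      if (denom >= 0) next                       # flat or non-concave: degenerate
      frac <- 0.5 * (v[m - 1L] - v[m + 1L]) / denom
      centers[ii] <- ax3[m] + frac * (ax3[2L] - ax3[1L])
    }
    ok <- is.finite(centers)
    if (sum(ok) < 3L) return(NA_real_)
    unname(coef(lm(centers[ok] ~ ax1[rows][ok]))[2L])
  }, numeric(1L))
  if (anyNA(cls)) warning("degenerate center line for some waiting times (flagged as NA)")
  names(cls) <- format(t2s)
  attr(cls, "t2") <- t2s
  cls
}
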