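#' Kubo component of the frequency-fluctuation correlation function
#'
#' A single stochastic frequency-modulation process with fluctuation
#' amplitude `delta` (cm^-1) and correlation time `tau` (ps). The FFCF
#' contribution is `Dw^2 * exp(-t/tau)` with `Dw = 2*pi*c*delta` in rad/ps.
#'
#' @param delta fluctuation amplitude in cm^-1 (> 0)
#' @param tau correlation time in ps (> 0)
#' @return an object of class `kubo_component`
#' @examples
#' kubo_component(20 / 3, 5)
#' @export
kubo_component <- function(delta, tau) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop_domain("`delta` must be a single positive number (cm^-1)")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop_domain("`tau` must be a single positive number (ps)")
  structure(list(delta = delta, tau = tau), class = "kubo_component")
}

#' @export
print.kubo_component <- function(x, ...) {
  cat(sprintf("Kubo component: delta = %.4g cm^-1, tau = %.4g ps\n", x$delta, x$tau))
  invisible(x)
}

as_kubo <- function(x) {
  if (inherits(x, "kubo_component")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(kubo_component(x[[1L]], x[[2L]]))
  stop_domain("expected a `kubo_component` or a numeric (delta, tau) pair")
}

as_kubo_list <- function(x) {
  if (inherits(x, "kubo_component")) return(list(x))
  if (is.list(x)) return(lapply(x, as_kubo))
  list(as_kubo(x))
}

#' Physical parameters of a simulated chromophore
#'
#' Collects the constants of the three-level vibrational system used by the
#' response-function simulator: the 0->1 transition frequency, the anharmonic
#' shift separating the excited-state absorption (1->2 at `omega01 - anharm`),
#' the vibrational lifetime, and one or more Kubo components describing
#' frequency fluctuations. Numerical detection sampling is carried out in a
#' rotating frame at `rotating_frame` (default: `omega01`), which permits
#' coarse detection-time steps without aliasing; absolute frequency axes are
#' restored on output.
#'
#' @param omega01 0->1 transition frequency in cm^-1 (> 0)
#' @param anharm anharmonic shift in cm^-1 (>= 0); `omega12 = omega01 - anharm`
#' @param t1_lifetime vibrational lifetime T1 in ps (> 0)
#' @param kubo a `kubo_component` or list of them (length >= 1)
#' @param rotating_frame carrier frequency subtracted for numerical sampling
#'   (cm^-1); defaults to `omega01`
#' @return an object of class `system_params`
#' @examples
#' system_params(kubo = kubo_component(6.7, 5))
#' @export
system_params <- function(omega01 = 2155, anharm = 25, t1_lifetime = 10,
                          kubo = list(kubo_component(20 / 3, 5)),
                          rotating_frame = omega01) {
  if (omega01 <= 0) stop_domain("`omega01` must be positive")
  if (anharm < 0) stop_domain("`anharm` must be nonnegative")
  if (t1_lifetime <= 0) stop_domain("`t1_lifetime` must be positive")
  kubo <- as_kubo_list(kubo)
  if (length(kubo) < 1L) stop_domain("at least one Kubo component is required")
  structure(list(omega01 = omega01, anharm = anharm, t1_lifetime = t1_lifetime,
                 kubo = kubo, rotating_frame = rotating_frame),
            class = "system_params")
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf("System: omega01 = %.4g cm^-1, anharm = %.4g cm^-1, T1 = %.4g ps\n",
              x$omega01, x$anharm, x$t1_lifetime))
  for (k in x$kubo)
    cat(sprintf("  Kubo component: delta = %.4g cm^-1, tau = %.4g ps\n", k$delta, k$tau))
  invisible(x)
}

check_uniform <- function(x, name) {
  if (length(x) < 2L) return(invisible(x))
  d <- diff(x)
  if (any(d <= 0)) stop_domain("`", name, "` must be strictly increasing")
  if (max(abs(d - d[1L])) > 1e-9 * max(abs(d)))
    stop_domain("`", name, "` must be uniformly spaced")
  invisible(x)
}

#' Time grid for third-order signal simulation
#'
#' Defines the pump-time (t1), waiting-time (t2) and detection-time (t3) axes
#' together with the zero-padding length used by the detection transform.
#' Default: t1 spanning 0-4 ps in 0.2 ps steps (21 points), t2 spanning
#' 0-15 ps in 0.75 ps steps (21 points), t3 spanning 0-4 ps with 128 points
#' zero-padded to 512.
#'
#' @param t1_axis pump-time points in ps (uniform, starting at 0)
#' @param t2_axis waiting-time points in ps (increasing)
#' @param t3_axis detection-time points in ps (uniform, starting at 0)
#' @param n_pad zero-padding length for the detection transform
#'   (>= `length(t3_axis)`)
#' @return an object of class `time_grid`
#' @export
time_grid <- function(t1_axis = seq(0, 4, by = 0.2),
                      t2_axis = seq(0, 15, by = 0.75),
                      t3_axis = seq(0, 4, length.out = 128),
                      n_pad = 512L) {
  if (t1_axis[1L] != 0) stop_domain("`t1_axis` must start at 0")
  if (t3_axis[1L] != 0) stop_domain("`t3_axis` must start at 0")
  check_uniform(t1_axis, "t1_axis")
  check_uniform(t3_axis, "t3_axis")
  if (any(diff(t2_axis) <= 0)) stop_domain("`t2_axis` must be strictly increasing")
  n_pad <- as.integer(n_pad)
  if (n_pad < length(t3_axis))
    stop_domain("`n_pad` must be at least the length of `t3_axis`")
  structure(list(t1_axis = t1_axis, t2_axis = t2_axis, t3_axis = t3_axis,
                 n_pad = n_pad), class = "time_grid")
}

#' A reduced time grid for high-throughput slice screening: 64 detection-time
#' points over 0-4 ps padded to 128, same pump/waiting axes as [time_grid()].
#' Detection-time extent (hence underlying resolution) is unchanged; only the
#' unaliased bandwidth and interpolation density are reduced.
#' @rdname time_grid
#' @export
screen_grid <- function(t1_axis = seq(0, 4, by = 0.2),
                        t2_axis = seq(0, 15, by = 0.75)) {
  time_grid(t1_axis = t1_axis, t2_axis = t2_axis,
            t3_axis = seq(0, 4, length.out = 64), n_pad = 128L)
}

new_mixed_domain_signal <- function(values, t1_axis, t2_axis, omega3_axis, params) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1L] == length(t1_axis),
            dim(values)[2L] == length(t2_axis),
            dim(values)[3L] == length(omega3_axis))
  structure(list(values = values, t1_axis = t1_axis, t2_axis = t2_axis,
                 omega3_axis = omega3_axis, params = params),
            class = "mixed_domain_signal")
}

#' @export
print.mixed_domain_signal <- function(x, ...) {
  cat(sprintf("Mixed-domain 2D-IR signal: %d pump-times x %d waiting-times x %d detection bins\n",
              length(x$t1_axis), length(x$t2_axis), length(x$omega3_axis)))
  cat(sprintf("  t1: %.3g-%.3g ps, t2: %.3g-%.3g ps, omega3: %.6g-%.6g cm^-1\n",
              min(x$t1_axis), max(x$t1_axis), min(x$t2_axis), max(x$t2_axis),
              min(x$omega3_axis), max(x$omega3_axis)))
  invisible(x)
}

new_spectrum2d <- function(values, omega1_axis, omega3_axis, t2, params = NULL) {
  stopifnot(nrow(values) == length(omega1_axis),
            ncol(values) == length(omega3_axis),
            all(is.finite(values)))
  structure(list(values = values, omega1_axis = omega1_axis,
                 omega3_axis = omega3_axis, t2 = t2, params = params),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("2D-IR frequency-frequency spectrum (%d x %d) at t2 = %.3g ps\n",
              nrow(x$values), ncol(x$values), x$t2))
  invisible(x)
}

#' @export
plot.spectrum2d <- function(x, n_levels = 21, ...) {
  graphics::filled.contour(x$omega1_axis, x$omega3_axis, x$values,
                           color.palette = grDevices::hcl.colors,
                           nlevels = n_levels,
                           xlab = "pump frequency (cm^-1)",
                           ylab = "probe frequency (cm^-1)", ...)
  invisible(x)
}
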