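#' Percent-different magnitude (PDM) of Kubo parameters
#'
#' Euclidean norm of the fractional differences of the Kubo parameters of a
#' comparison sample relative to a reference sample:
#' `sqrt(((delta_s - delta_ref)/delta_ref)^2 + ((tau_s - tau_ref)/tau_ref)^2)`.
#' Dimensionless; zero iff the parameters coincide. A PDM threshold (e.g.
#' 0.10) defines the binary classification boundary around the reference.
#'
#' @param ref reference `kubo_component` (or numeric `(delta, tau)` pair)
#' @param s comparison `kubo_component` (or numeric pair)
#' @return nonnegative dimensionless magnitude
#' @examples
#' pdm(c(20 / 3, 5), c(6.257, 5.386))   # 0.0987
#' pdm(c(20 / 3, 5), c(6.244, 5.388))   # 0.1002
#' @export
pdm <- function(ref, s) {
  ref <- as_kubo(ref)
  if (is.numeric(s) && length(s) == 2L) s <- kubo_component(s[[1L]], s[[2L]])
  s <- as_kubo(s)
  sqrt(((s$delta - ref$delta) / ref$delta)^2 + ((s$tau - ref$tau) / ref$tau)^2)
}

pdm_vec <- function(ref, delta, tau) {
  sqrt(((delta - ref$delta) / ref$delta)^2 + ((tau - ref$tau) / ref$tau)^2)
}

#' Specification of a PDM classification boundary
#'
#' @param ref reference `kubo_component`
#' @param boundary PDM threshold b in (0, 1); default 0.10
#' @param cauchy_scale scale gamma of the one-sided Cauchy distribution used
#'   for boundary-focused radial sampling; default 0.05
#' @param param_bounds list with elements `delta` and `tau`, each a (lo, hi)
#'   admissible range; defaults to +/- 90 percent of the reference
#' @return an object of class `pdm_boundary_spec`
#' @export
pdm_boundary_spec <- function(ref, boundary = 0.10, cauchy_scale = 0.05,
                              param_bounds = NULL) {
  ref <- as_kubo(ref)
  if (boundary <= 0 || boundary >= 1) stop_domain("`boundary` must be in (0, 1)")
  if (cauchy_scale <= 0) stop_domain("`cauchy_scale` must be positive")
  param_bounds <- param_bounds %||% list(delta = ref$delta * c(0.1, 1.9),
                                         tau = ref$tau * c(0.1, 1.9))
  if (ref$delta < param_bounds$delta[1L] || ref$delta > param_bounds$delta[2L] ||
      ref$tau < param_bounds$tau[1L] || ref$tau > param_bounds$tau[2L])
    stop_domain("`param_bounds` must contain the reference parameters")
  structure(list(ref = ref, boundary = boundary, cauchy_scale = cauchy_scale,
                 param_bounds = param_bounds), class = "pdm_boundary_spec")
}

#' Boundary-focused Kubo parameter sampling
#'
#' Draws `(delta, tau)` pairs concentrated at the PDM classification boundary:
#' the radial PDM is `b -/+ |Cauchy(0, gamma)|` (minus for `side = "inside"`,
#' plus for `"outside"`), rejecting negative radii (inside) and draws whose
#' mapped parameters leave the admissible box; the angular direction is
#' uniform on `[0, 2*pi)`. The heavy Cauchy tail supplies a sparse spray of
#' easy samples away from the boundary while concentrating mass at the
#' boundary itself.
#'
#' @param spec a [pdm_boundary_spec()]
#' @param side `"inside"` or `"outside"` the boundary
#' @param n number of draws
#' @return data.frame with columns `delta`, `tau`, `pdm`
#' @export
sample_params <- function(spec, side = c("inside", "outside"), n = 1L) {
  stopifnot(inherits(spec, "pdm_boundary_spec"))
  side <- match.arg(side)
  b <- spec$boundary; g <- spec$cauchy_scale
  ref <- spec$ref; pb <- spec$param_bounds
  out_d <- numeric(n); out_t <- numeric(n); out_p <- numeric(n)
  got <- 0L; tries <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    tries <- tries + m
    r <- abs(stats::rcauchy(m, 0, g))
    p <- if (side == "inside") b - r else b + r
    theta <- stats::runif(m, 0, 2 * pi)
    d <- ref$delta * (1 + p * cos(theta))
    tt <- ref$tau * (1 + p * sin(theta))
    ok <- p >= 0 & d >= pb$delta[1L] & d <= pb$delta[2L] &
      tt >= pb$tau[1L] & tt <= pb$tau[2L]
    if (side == "inside") ok <- ok & p <= b else ok <- ok & p > b
    k <- which(ok)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      idx <- got + seq_along(take)
      out_d[idx] <- d[take]; out_t[idx] <- tt[take]; out_p[idx] <- p[take]
      got <- got + length(take)
    }
    if (tries > 100L * n && got < 0.01 * tries)
      stop_domain("rejection rate above 99%: check `param_bounds` and `cauchy_scale`")
  }
  data.frame(delta = out_d, tau = out_t, pdm = out_p)
}

signal_values <- function(x) {
  if (inherits(x, c("mixed_domain_signal", "spectrum2d"))) x$values else x
}

#' Add SNR-controlled Gaussian noise and normalize
#'
#' Adds i.i.d. Gaussian noise with standard deviation `max(abs(values))/snr`
#' independently to every element (and independently to the real and
#' imaginary parts of complex data), then rescales so that the maximum
#' absolute value is 1. With `snr = Inf` the input is only normalized.
#'
#' @param x a `mixed_domain_signal`, `spectrum2d`, or a numeric/complex array
#' @param snr target signal-to-noise ratio (> 0, or `Inf`)
#' @return object of the same type, peak-normalized
#' @export
add_noise <- function(x, snr) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop_domain("`snr` must be a single positive number (or Inf)")
  v <- signal_values(x)
  peak <- max(abs(v))
  if (peak == 0) stop_domain("all-zero signal: SNR is undefined")
  if (is.finite(snr)) {
    sigma <- peak / snr
    if (is.complex(v)) {
      v <- v + complex(real = stats::rnorm(length(v), 0, sigma),
                       imaginary = stats::rnorm(length(v), 0, sigma))
    } else {
      v <- v + stats::rnorm(length(v), 0, sigma)
    }
  }
  v <- v / max(abs(v))
  if (inherits(x, c("mixed_domain_signal", "spectrum2d"))) {
    x$values <- v
    x
  } else v
}

#' Extract a single detection-axis slice
#'
#' Returns the complex vector `S(t1, t2, .)` at one (pump-time, waiting-time)
#' grid point, with axis metadata preserved. Off-grid requests are an error;
#' no silent interpolation is performed.
#'
#' @param signal a `mixed_domain_signal`
#' @param t1,t2 pump and waiting times in ps (must lie on the grid)
#' @return an object of class `ir_slice`: list of `values` (complex vector of
#'   length `n_pad`), `omega3_axis`, `t1`, `t2`
#' @export
extract_slice <- function(signal, t1, t2) {
  stopifnot(inherits(signal, "mixed_domain_signal"))
  i <- which(abs(signal$t1_axis - t1) < 1e-9)
  j <- which(abs(signal$t2_axis - t2) < 1e-9)
  if (length(i) != 1L || length(j) != 1L)
    stop_domain("(t1, t2) = (", t1, ", ", t2, ") is not on the signal grid")
  structure(list(values = signal$values[i, j, ], omega3_axis = signal$omega3_axis,
                 t1 = t1, t2 = t2), class = "ir_slice")
}

#' Encode a payload as a real channel tensor
#'
#' Complex payloads become two channels (real, imaginary); real payloads one
#' channel. The output is an array with dims `(d1, d2, d3, channels)`,
#' retaining singleton spatial axes, ready to be stacked into a
#' classification batch.
#'
#' @param payload an `ir_slice`, `spectrum2d`, `mixed_domain_signal`, or array
#' @return real array of dim `(d1, d2, d3, channels)`
#' @export
encode_channels <- function(payload) {
  v <- if (inherits(payload, "ir_slice")) payload$values else signal_values(payload)
  if (!all(is.finite(Re(v)))) stop_domain("payload must be finite")
  d <- dim(v) %||% length(v)
  d3 <- c(d, 1L, 1L, 1L)[1:3]
  if (is.complex(v)) {
    array(c(Re(v), Im(v)), dim = c(d3, 2L))
  } else {
    array(as.numeric(v), dim = c(d3, 1L))
  }
}

#' Decode a channel tensor back to its numeric payload
#'
#' Inverse of [encode_channels()] up to (dropped) singleton spatial axes.
#'
#' @param x array of dim `(d1, d2, d3, channels)`
#' @return complex (2 channels) or numeric (1 channel) array
#' @export
decode_channels <- function(x) {
  d <- dim(x)
  spat <- d[1:3]
  v <- if (d[4L] == 2L) {
    complex(real = x[, , , 1L], imaginary = x[, , , 2L])
  } else as.numeric(x)
  keep <- spat[spat > 1L]
  if (length(keep) >= 2L) dim(v) <- keep
  v
}

#' Dataset specification for PDM-boundary classification
#'
#' @param boundary a [pdm_boundary_spec()]
#' @param n_samples total sample count (experimental protocol: 10,000; must be
#'   even when `balance = 0.5`)
#' @param balance fraction of samples inside the boundary (default 0.5)
#' @param snr target signal-to-noise ratio (default 100)
#' @param slice_selection either `"full"` (whole mixed-domain signal) or a
#'   numeric `(t1, t2)` pair naming a single slice
#' @param split training fraction (default 0.8)
#' @param sys a [system_params()] template; its varied Kubo component is
#'   replaced per sample
#' @param grid a [time_grid()]; default [screen_grid()]
#' @return an object of class `dataset_spec`
#' @export
dataset_spec <- function(boundary, n_samples = 10000L, balance = 0.5, snr = 100,
                         slice_selection = c(0, 0.75), split = 0.8,
                         sys = NULL, grid = screen_grid()) {
  stopifnot(inherits(boundary, "pdm_boundary_spec"))
  n_samples <- as.integer(n_samples)
  if (balance == 0.5 && n_samples %% 2L != 0L)
    stop_domain("`n_samples` must be even for a 50/50 balance")
  if (split <= 0 || split >= 1) stop_domain("`split` must be in (0, 1)")
  sys <- sys %||% system_params(kubo = boundary$ref)
  structure(list(boundary = boundary, n_samples = n_samples, balance = balance,
                 snr = snr, slice_selection = slice_selection, split = split,
                 sys = sys, grid = grid), class = "dataset_spec")
}

dataset_from_params <- function(par, spec) {
  n <- nrow(par)
  sys <- spec$sys; grid <- spec$grid
  if (identical(spec$slice_selection, "full")) {
    enc <- vector("list", n)
    for (i in seq_len(n)) {
      s <- sys; s$kubo <- list(kubo_component(par$delta[i], par$tau[i]))
      sig <- detect(s, grid)
      enc[[i]] <- encode_channels(add_noise(sig, spec$snr))
    }
    X <- array(unlist(enc, use.names = FALSE), dim = c(dim(enc[[1L]]), n))
  } else {
    t1 <- spec$slice_selection[1L]; t2 <- spec$slice_selection[2L]
    if (min(abs(grid$t1_axis - t1)) > 1e-9 || min(abs(grid$t2_axis - t2)) > 1e-9)
      stop_domain("slice_selection (t1, t2) must lie on the simulation grid")
    sl <- simulate_slices(par$delta, par$tau, sys, t1, t2, grid)
    np <- grid$n_pad
    X <- array(0, dim = c(np, 1L, 1L, 2L, n))
    for (i in seq_len(n)) {
      v <- add_noise(sl$values[, i], spec$snr)
      X[, 1L, 1L, 1L, i] <- Re(v)
      X[, 1L, 1L, 2L, i] <- Im(v)
    }
  }
  X
}

#' Generate a labeled PDM-boundary classification dataset
#'
#' Per-sample pipeline: boundary-focused parameter draw ([sample_params()]) ->
#' Kubo response simulation (full [detect()] signal or a single slice) ->
#' SNR-controlled noise + peak normalization ([add_noise()]) -> channel
#' encoding ([encode_channels()]). Produces exactly `balance * n` inside and
#' `(1 - balance) * n` outside samples, with a seeded, disjoint
#' train/validation split.
#'
#' @param spec a [dataset_spec()]
#' @param seed integer seed making the dataset fully reproducible
#' @return an object of class `kubonet_dataset`: list with `x` (array, last
#'   dim = samples), `y` (0/1 labels; 1 = inside), `params` (data.frame with
#'   `delta`, `tau`, `pdm`), `train_idx`, `val_idx`, `spec`, `seed`
#' @export
generate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "dataset_spec"))
  set.seed(as.integer(seed))
  n_in <- round(spec$n_samples * spec$balance)
  n_out <- spec$n_samples - n_in
  par <- rbind(sample_params(spec$boundary, "inside", n_in),
               sample_params(spec$boundary, "outside", n_out))
  y <- c(rep(1L, n_in), rep(0L, n_out))
  perm <- sample.int(spec$n_samples)
  par <- par[perm, , drop = FALSE]; rownames(par) <- NULL
  y <- y[perm]
  X <- dataset_from_params(par, spec)
  n_train <- round(spec$split * spec$n_samples)
  train_idx <- sort(sample.int(spec$n_samples, n_train))
  val_idx <- setdiff(seq_len(spec$n_samples), train_idx)
  structure(list(x = X, y = y, params = par, train_idx = train_idx,
                 val_idx = val_idx, spec = spec, seed = as.integer(seed)),
            class = "kubonet_dataset")
}

#' @export
print.kubonet_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("kubonet dataset: %d samples (%d inside / %d outside), payload %s, %d train / %d validation\n",
              length(x$y), sum(x$y == 1L), sum(x$y == 0L),
              paste(d[-length(d)], collapse = "x"),
              length(x$train_idx), length(x$val_idx)))
  invisible(x)
}

#' Uniformly distributed test set over the parameter box
#'
#' Draws `(delta, tau)` i.i.d. uniform over the given box and labels each
#' draw by its PDM against the boundary reference. Used to probe
#' training-distribution bias of models trained on boundary-focused data.
#'
#' @param bounds list with `delta` and `tau` (lo, hi) ranges
#' @param n number of samples
#' @param boundary a [pdm_boundary_spec()] providing reference and threshold
#' @param seed integer seed
#' @param spec optional [dataset_spec()]; when supplied, payloads are
#'   simulated and encoded exactly as in [generate_dataset()]
#' @return a `kubonet_dataset` (without payloads when `spec` is NULL)
#' @export
generate_uniform_testset <- function(bounds, n, boundary, seed = 1L, spec = NULL) {
  stopifnot(inherits(boundary, "pdm_boundary_spec"))
  set.seed(as.integer(seed))
  d <- stats::runif(n, bounds$delta[1L], bounds$delta[2L])
  tt <- stats::runif(n, bounds$tau[1L], bounds$tau[2L])
  p <- pdm_vec(boundary$ref, d, tt)
  par <- data.frame(delta = d, tau = tt, pdm = p)
  y <- as.integer(p <= boundary$boundary)
  X <- if (!is.null(spec)) dataset_from_params(par, spec) else NULL
  structure(list(x = X, y = y, params = par, train_idx = integer(0),
                 val_idx = seq_len(n), spec = spec, seed = as.integer(seed)),
            class = "kubonet_dataset")
}
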