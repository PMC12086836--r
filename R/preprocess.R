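#' Normalization configuration for frequency-frequency spectra
#'
#' Settings of the common-footing normalization applied to every
#' experimental-style spectrum: cropping about the fundamental peak,
#' translation of the peak to a fixed pixel, bilinear interpolation to a
#' fixed pixel grid, amplitude normalization, and Gaussian noise to a target
#' SNR. After normalization all spectra share peak pixel position, frequency
#' range, pixel density, unit maximum absolute intensity, and SNR, so only
#' line-shape differences remain available to a classifier.
#'
#' @param output_size pixels per axis of the normalized spectrum (>= 32;
#'   default 100)
#' @param peak_pixel target (row, col) of the 0->1 peak; default the center
#' @param crop_window (pump, probe) half-widths of the crop in cm^-1
#' @param target_snr SNR after noise addition (peak / noise sd); `Inf` for none
#' @return an object of class `normalization_config`
#' @export
normalization_config <- function(output_size = 100L, peak_pixel = NULL,
                                 crop_window = c(30, 30), target_snr = 100) {
  output_size <- as.integer(output_size)
  if (output_size < 32L) stop_domain("`output_size` must be at least 32")
  peak_pixel <- peak_pixel %||% rep(ceiling(output_size / 2), 2L)
  if (any(peak_pixel < 1L) || any(peak_pixel > output_size))
    stop_domain("`peak_pixel` must lie inside the output grid")
  if (length(crop_window) == 1L) crop_window <- rep(crop_window, 2L)
  structure(list(output_size = output_size, peak_pixel = as.integer(peak_pixel),
                 crop_window = crop_window, target_snr = target_snr),
            class = "normalization_config")
}

#' Normalize a frequency-frequency spectrum to the common footing
#'
#' Steps (in order): locate the global |value| maximum (the 0->1 peak; ties
#' broken toward the lowest (row, col) index, with a warning); crop to
#' `crop_window` about the peak; translate the peak to `peak_pixel`; bilinear
#' interpolation onto an `output_size^2` pixel grid; divide by the maximum
#' absolute value; add Gaussian noise to reach `target_snr`; renormalize.
#' Output axes are pixel indices (arbitrary units).
#'
#' @param raw a `spectrum2d`
#' @param cfg a [normalization_config()]
#' @return a `spectrum2d` on pixel axes with unit peak at `peak_pixel`
#' @export
normalize_spectrum <- function(raw, cfg) {
  stopifnot(inherits(raw, "spectrum2d"), inherits(cfg, "normalization_config"))
  v <- raw$values
  peak <- which(abs(v) == max(abs(v)), arr.ind = TRUE)
  if (nrow(peak) > 1L) {
    peak <- peak[order(peak[, 1L], peak[, 2L])[1L], , drop = FALSE]
    warning("multiple equal maxima: tie broken toward the lowest (row, col)")
  }
  w1p <- raw$omega1_axis[peak[1L]]; w3p <- raw$omega3_axis[peak[2L]]
  S <- cfg$output_size; pk <- cfg$peak_pixel; cw <- cfg$crop_window
  # output pixel i maps to omega = omega_peak + (i - peak_pixel) * density,
  # with density chosen so the full output grid spans 2 * crop_window
  d1 <- 2 * cw[1L] / (S - 1L); d3 <- 2 * cw[2L] / (S - 1L)
  q1 <- w1p + (seq_len(S) - pk[1L]) * d1
  q3 <- w3p + (seq_len(S) - pk[2L]) * d3
  if (min(q1) < min(raw$omega1_axis) || max(q1) > max(raw$omega1_axis) ||
      min(q3) < min(raw$omega3_axis) || max(q3) > max(raw$omega3_axis))
    stop_domain("peak too close to the spectrum border for the requested crop window")
  # pracma::interp2 is MATLAB-style: x indexes columns of Z, y indexes rows
  grid <- expand.grid(q3 = q3, q1 = q1)
  z <- pracma::interp2(x = raw$omega3_axis, y = raw$omega1_axis, Z = v,
                       xp = grid$q3, yp = grid$q1, method = "linear")
  out <- t(matrix(z, nrow = S))          # rows = pump pixels, cols = probe pixels
  out <- out / max(abs(out))
  if (is.finite(cfg$target_snr)) {
    out <- out + stats::rnorm(length(out), 0, 1 / cfg$target_snr)
    out <- out / max(abs(out))
  }
  new_spectrum2d(out, seq_len(S), seq_len(S), raw$t2, raw$params)
}

#' Degrade the SNR of a normalized spectrum
#'
#' Adds Gaussian noise with
#' `sigma = peak * sqrt(1/target_snr^2 - 1/current_snr^2)` so that the total
#' noise variance matches the target, then renormalizes the peak to 1. The
#' convention `target_snr = 0` yields a pure Gaussian noise field (peak
#' normalized to 1), the no-signal reference condition.
#'
#' @param s a `spectrum2d` (or numeric array)
#' @param current_snr SNR of the input
#' @param target_snr desired SNR (< `current_snr`; 0 for pure noise)
#' @return same type as `s`
#' @export
degrade_snr <- function(s, current_snr, target_snr) {
  v <- signal_values(s)
  peak <- max(abs(v))
  if (target_snr == 0) {
    v <- array(stats::rnorm(length(v), 0, peak), dim = dim(v) %||% length(v))
  } else {
    if (target_snr >= current_snr)
      stop_domain("`target_snr` must be below `current_snr`")
    sigma <- peak * sqrt(1 / target_snr^2 - 1 / current_snr^2)
    v <- v + stats::rnorm(length(v), 0, sigma)
  }
  v <- v / max(abs(v))
  if (inherits(s, "spectrum2d")) { s$values <- v; s } else v
}

border_noise_sd <- function(s, margin = 2L) {
  v <- signal_values(s)
  n <- nrow(v); m <- ncol(v)
  idx <- rbind(expand.grid(r = c(seq_len(margin), n - seq_len(margin) + 1L), c = seq_len(m)),
               expand.grid(r = seq_len(n), c = c(seq_len(margin), m - seq_len(margin) + 1L)))
  stats::sd(v[as.matrix(idx)])
}

#' Balance a labeled spectrum set by noise augmentation
#'
#' Appends noise-perturbed copies of randomly chosen minority-class spectra
#' (Gaussian noise added or subtracted with equal probability, with standard
#' deviation equal to the set's noise floor) until the class counts are
#' exactly 50/50. Original spectra are never modified or removed.
#'
#' @param spectra list of `spectrum2d` (or numeric matrices)
#' @param labels vector of class labels, length matching `spectra`
#' @param minority_label label of the class to augment; default the rarer one
#' @param sigma noise standard deviation; default estimated from the border
#'   pixels of the minority spectra
#' @return list with `spectra`, `labels`, and `n_augmented`
#' @export
balance_by_augmentation <- function(spectra, labels, minority_label = NULL,
                                    sigma = NULL) {
  stopifnot(length(spectra) == length(labels))
  tab <- table(labels)
  if (length(tab) != 2L) stop_domain("exactly two classes are required")
  minority_label <- minority_label %||% names(tab)[which.min(tab)]
  mino <- which(labels == minority_label)
  if (!length(mino)) stop_domain("minority class is empty")
  need <- length(labels) - 2L * length(mino)
  if (need < 0L) stop_domain("`minority_label` is the majority class")
  if (need == 0L) return(list(spectra = spectra, labels = labels, n_augmented = 0L))
  sigma <- sigma %||% stats::median(vapply(spectra[mino], border_noise_sd, numeric(1L)))
  picks <- sample(mino, need, replace = TRUE)
  signs <- sample(c(-1, 1), need, replace = TRUE)
  aug <- vector("list", need)
  for (i in seq_len(need)) {
    s <- spectra[[picks[i]]]
    v <- signal_values(s)
    v <- v + signs[i] * stats::rnorm(length(v), 0, sigma)
    if (inherits(s, "spectrum2d")) { s$values <- array(v, dim(s$values)); aug[[i]] <- s }
    else aug[[i]] <- array(v, dim(v) %||% length(v))
  }
  list(spectra = c(spectra, aug),
       labels = c(labels, rep(minority_label, need)),
       n_augmented = need)
}

#' Pearson correlation profile against a reference spectrum
#'
#' Pearson correlation coefficient of each spectrum's flattened pixel vector
#' with the reference spectrum, a repeat-detection diagnostic: effective
#' repeats form tight high-correlation groups at high SNR that dissolve as
#' noise increases.
#'
#' @param spectra list of `spectrum2d` (or matrices), identical shapes
#' @param reference a single `spectrum2d` (or matrix) of the same shape
#' @return numeric correlations in `[-1, 1]`; `NA` (with a warning) for
#'   zero-variance spectra
#' @export
pcc_profile <- function(spectra, reference) {
  rv <- as.vector(signal_values(reference))
  if (stats::sd(rv) == 0) stop_domain("reference spectrum has zero variance")
  out <- vapply(spectra, function(s) {
    v <- as.vector(signal_values(s))
    if (length(v) != length(rv)) stop_domain("spectra must share the reference's shape")
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, rv)
  }, numeric(1L))
  if (anyNA(out)) warning("zero-variance spectrum: PCC undefined (NA)")
  out
}

#' Synthetic solvent presets
#'
#' Five synthetic Kubo parameter sets emulating the line-shape diversity of a
#' nitrile chromophore in H2O, DMF, DMSO, glycerol, and the ionic liquid
#' BMIM-TFSI. The aprotic amides/sulfoxides are chosen nearest the water
#' preset (the hard discriminations) and the viscous/ionic solvents farthest,
#' reproducing the qualitative difficulty ordering of solvent classification.
#' These presets are synthetic stand-ins, not fitted solvent parameters.
#'
#' @param omega01,anharm,t1_lifetime shared system constants, see
#'   [system_params()]
#' @return named list of `system_params`, one per solvent
#' @export
solvent_presets <- function(omega01 = 2155, anharm = 25, t1_lifetime = 10) {
  mk <- function(delta, tau)
    system_params(omega01 = omega01, anharm = anharm, t1_lifetime = t1_lifetime,
                  kubo = kubo_component(delta, tau))
  list(
    H2O        = mk(5.6, 1.0),
    DMF        = mk(5.2, 1.7),
    DMSO       = mk(6.1, 1.5),
    Glycerol   = mk(8.5, 7.0),
    `BMIM-TFSI` = mk(9.5, 12.0)
  )
}

#' Simulate a normalized multi-solvent spectrum panel
#'
#' Simulates absorptive frequency-frequency spectra at a single waiting time
#' (default 1 ps) for each solvent preset, with small seeded per-sample
#' multiplicative jitter of the Kubo parameters, then applies
#' [normalize_spectrum()]. Binary water / non-water labels are attached.
#' This panel is a synthetic fixture standing in for experimental solvent
#' spectra; it emulates their class structure but not instrument artifacts.
#'
#' @param presets named list of `system_params` (see [solvent_presets()])
#' @param n_per_class samples per solvent
#' @param cfg a [normalization_config()]
#' @param t2 waiting time in ps (default 1)
#' @param jitter_sd multiplicative parameter jitter (default 0.02)
#' @param grid a [time_grid()]; default [screen_grid()] with t2 on the grid
#' @param seed integer seed
#' @return list with `spectra` (list of normalized `spectrum2d`), `solvent`
#'   (factor), `labels` (1 = water, 0 = other)
#' @export
synth_solvent_panel <- function(presets = solvent_presets(), n_per_class = 20L,
                                cfg = normalization_config(output_size = 32L,
                                                           crop_window = c(25, 35),
                                                           target_snr = 100),
                                t2 = 1, jitter_sd = 0.02, grid = NULL, seed = 1L) {
  if (length(presets) < 2L) stop_domain("at least two presets are required")
  if (is.null(names(presets)) || anyDuplicated(names(presets)))
    stop_domain("presets must be uniquely named")
  set.seed(as.integer(seed))
  grid <- grid %||% time_grid(t1_axis = seq(0, 4, by = 0.2), t2_axis = c(0, t2),
                              t3_axis = seq(0, 4, length.out = 64), n_pad = 128L)
  spectra <- list(); solvent <- character(0)
  for (nm in names(presets)) {
    p0 <- presets[[nm]]
    for (i in seq_len(n_per_class)) {
      p <- p0
      k <- p$kubo[[1L]]
      p$kubo <- list(kubo_component(k$delta * exp(stats::rnorm(1L, 0, jitter_sd)),
                                    k$tau * exp(stats::rnorm(1L, 0, jitter_sd))))
      raw <- absorptive_spectrum(p, t2, grid)
      spectra[[length(spectra) + 1L]] <- normalize_spectrum(raw, cfg)
      solvent <- c(solvent, nm)
    }
  }
  list(spectra = spectra, solvent = factor(solvent),
       labels = as.integer(solvent == "H2O"))
}
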