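#' Brier score
#'
#' Mean squared difference between forecast positive-class probabilities and
#' binary outcomes; a strictly proper scoring rule.
#'
#' @param probs positive-class probabilities in `[0, 1]` (or an `(n, 2)`
#'   probability matrix)
#' @param labels 0/1 outcomes
#' @return mean of `(p - y)^2`
#' @export
brier_score <- function(probs, labels) {
  p <- if (is.matrix(probs)) probs[, 2L] else probs
  if (length(p) != length(labels)) stop_domain("probs and labels lengths differ")
  if (any(p < 0 | p > 1)) stop_domain("probabilities must lie in [0, 1]")
  mean((p - labels)^2)
}

#' Brier Skill Score (BSS)
#'
#' `1 - BS / BS_ref`, where the reference is the constant base-rate forecast
#' of the label set (`BS_ref = pbar * (1 - pbar)`, i.e. 0.25 for balanced
#' labels). Zero indicates chance-level skill, one perfect prediction, and
#' negative values worse-than-chance forecasts. Using the observed base rate
#' keeps unbalanced diagnostic sets scoreable; single-class label sets have
#' `BS_ref = 0` and are rejected.
#'
#' @inheritParams brier_score
#' @return skill score `<= 1`
#' @export
brier_skill_score <- function(probs, labels) {
  bs <- brier_score(probs, labels)
  pbar <- mean(labels)
  bs_ref <- pbar * (1 - pbar)
  if (bs_ref == 0)
    stop_domain("degenerate single-class labels: reference Brier score is 0")
  1 - bs / bs_ref
}

#' Scan classification skill across the (pump-time, waiting-time) grid
#'
#' For each requested slice position, generates the single-slice dataset
#' (shared boundary-focused parameter draws across cells, per-cell noise),
#' trains a classifier, and records the best validation Brier Skill Score and
#' accuracy together with the training provenance. Per-cell training
#' failures are flagged and the scan continues.
#'
#' @param ds_spec a [dataset_spec()]; its `slice_selection` is overridden per
#'   cell
#' @param t1_values,t2_values slice positions (must lie on the simulation
#'   grid); default the full 21 x 21 grid of the spec's `grid`
#' @param model_cfg a [model_config()]
#' @param train_cfg a [train_config()]
#' @param seed integer seed for data generation; training seeds derive from
#'   `train_cfg$seed`
#' @param keep_fits retain the per-cell `kubonet_fit` objects (default FALSE)
#' @return an object of class `bss_map`: data.frame with columns `t1`, `t2`,
#'   `best_bss`, `final_bss`, `best_acc`, `seed`, `ok`
#' @export
slice_scan <- function(ds_spec, t1_values = NULL, t2_values = NULL,
                       model_cfg = model_config(), train_cfg = train_config(),
                       seed = 1L, keep_fits = FALSE) {
  stopifnot(inherits(ds_spec, "dataset_spec"))
  grid <- ds_spec$grid
  t1_values <- t1_values %||% grid$t1_axis
  t2_values <- t2_values %||% grid$t2_axis
  for (t1 in t1_values)
    if (min(abs(grid$t1_axis - t1)) > 1e-9) stop_domain("t1 = ", t1, " is off the grid")
  for (t2 in t2_values)
    if (min(abs(grid$t2_axis - t2)) > 1e-9) stop_domain("t2 = ", t2, " is off the grid")
  cells <- expand.grid(t1 = t1_values, t2 = t2_values)
  rows <- vector("list", nrow(cells))
  fits <- if (keep_fits) vector("list", nrow(cells)) else NULL
  for (i in seq_len(nrow(cells))) {
    spec_i <- ds_spec
    spec_i$slice_selection <- c(cells$t1[i], cells$t2[i])
    res <- tryCatch({
      ds <- generate_dataset(spec_i, seed = seed)
      fit <- train_classifier(ds, model_cfg, train_cfg)
      r <- fit$record
      if (keep_fits) fits[[i]] <- fit
      pbar <- mean(ds$y[ds$val_idx]); bs_ref <- pbar * (1 - pbar)
      data.frame(t1 = cells$t1[i], t2 = cells$t2[i],
                 best_bss = 1 - min(r$val_brier) / bs_ref,
                 final_bss = 1 - r$val_brier[nrow(r)] / bs_ref,
                 best_acc = max(r$val_acc), seed = seed, ok = TRUE)
    }, error = function(e) {
      warning("cell (", cells$t1[i], ", ", cells$t2[i], ") failed: ",
              conditionMessage(e))
      data.frame(t1 = cells$t1[i], t2 = cells$t2[i], best_bss = NA_real_,
                 final_bss = NA_real_, best_acc = NA_real_, seed = seed,
                 ok = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("bss_map", class(out))
  out
}

#' @export
plot.bss_map <- function(x, metric = "best_bss", ...) {
  t1 <- sort(unique(x$t1)); t2 <- sort(unique(x$t2))
  z <- matrix(NA_real_, length(t1), length(t2))
  for (i in seq_len(nrow(x)))
    z[match(x$t1[i], t1), match(x$t2[i], t2)] <- x[[metric]][i]
  graphics::filled.contour(t1, t2, z, color.palette = grDevices::hcl.colors,
                           xlab = "pump-time t1 (ps)",
                           ylab = "waiting-time t2 (ps)", ...)
  invisible(x)
}

#' Per-sample squared-error map over Kubo parameter space
#'
#' Attaches the squared error `(p_inside - y)^2` of a fitted classifier to
#' each validation sample's `(delta, tau, pdm)`, optionally binned on a
#' parameter grid (empty bins masked as `NA`).
#'
#' @param fit a `kubonet_fit`
#' @param dataset a `kubonet_dataset`; its validation samples are scored
#' @param bins optional bin count per axis for the binned mean map
#' @return an object of class `error_map`: data.frame with `delta`, `tau`,
#'   `pdm`, `label`, `p_inside`, `sq_error`; binned grid in attribute
#'   `binned` when `bins` is given
#' @export
error_map <- function(fit, dataset, bins = NULL) {
  idx <- dataset$val_idx
  p <- predict_proba(fit, dataset$x[, , , , idx, drop = FALSE])[, 2L]
  out <- data.frame(delta = dataset$params$delta[idx],
                    tau = dataset$params$tau[idx],
                    pdm = dataset$params$pdm[idx],
                    label = dataset$y[idx], p_inside = p,
                    sq_error = (p - dataset$y[idx])^2)
  if (!is.null(bins)) {
    bd <- cut(out$delta, bins); bt <- cut(out$tau, bins)
    binned <- tapply(out$sq_error, list(bd, bt), mean)
    attr(out, "binned") <- binned
  }
  class(out) <- c("error_map", class(out))
  out
}

#' Rank-based loss scores per category
#'
#' For each condition (column), categories are ranked by mean loss in
#' descending order: the category with the highest loss scores 0 and the one
#' with the lowest scores `m - 1`; ties share the mean of the tied ranks.
#' Scores are averaged across conditions.
#'
#' @param losses numeric matrix of mean losses, rows = categories (named),
#'   columns = conditions
#' @return named numeric vector of mean scores per category
#' @export
loss_rank_scores <- function(losses) {
  losses <- as.matrix(losses)
  if (nrow(losses) < 2L || ncol(losses) < 1L)
    stop_domain("need >= 2 categories and >= 1 condition")
  if (anyNA(losses)) stop_domain("NaN/NA losses are not scoreable")
  scores <- apply(losses, 2L, function(l) rank(-l) - 1)
  out <- rowMeans(scores)
  names(out) <- rownames(losses)
  out
}

#' Classification skill as a function of SNR
#'
#' Trains one classifier per requested SNR on a fixed slice position and
#' returns the best validation BSS (and accuracy) per SNR. Across the
#' decades of SNR the skill is expected to grow approximately logarithmically
#' until it saturates.
#'
#' @param ds_spec a [dataset_spec()] fixing everything but the SNR
#' @param slice_position numeric `(t1, t2)` slice
#' @param snr_values positive SNRs, sorted increasing
#' @param model_cfg a [model_config()]
#' @param train_cfg a [train_config()]
#' @param seed integer data seed
#' @return data.frame with `snr`, `best_bss`, `best_acc`, `seed`
#' @export
snr_bss_curve <- function(ds_spec, slice_position, snr_values,
                          model_cfg = model_config(),
                          train_cfg = train_config(), seed = 1L) {
  if (any(snr_values <= 0) || is.unsorted(snr_values))
    stop_domain("`snr_values` must be positive and sorted increasing")
  rows <- lapply(snr_values, function(s) {
    spec_i <- ds_spec
    spec_i$snr <- s
    spec_i$slice_selection <- slice_position
    ds <- generate_dataset(spec_i, seed = seed)
    fit <- train_classifier(ds, model_cfg, train_cfg)
    r <- fit$record
    pbar <- mean(ds$y[ds$val_idx]); bs_ref <- pbar * (1 - pbar)
    data.frame(snr = s, best_bss = 1 - min(r$val_brier) / bs_ref,
               best_acc = max(r$val_acc), seed = seed)
  })
  do.call(rbind, rows)
}

#' Enumerate the slice-scan grid
#'
#' Cells of the (pump-time, waiting-time) scan for a given simulation grid.
#' The default grid (21 pump-times x 21 waiting-times) yields 441 cells, i.e.
#' 441 networks per data set.
#'
#' @param grid a [time_grid()]
#' @return data.frame with columns `t1`, `t2`, one row per scan cell
#' @export
slice_grid <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  expand.grid(t1 = grid$t1_axis, t2 = grid$t2_axis)
}

#' Reference Kubo parameter panel
#'
#' The 15 reference (delta, tau) combinations used to probe how the choice of
#' reference sample affects single-slice classification: Kubo amplitudes
#' {3.3, 6.7, 13.3} cm^-1 crossed with time constants
#' {0.8, 1.5, 2.8, 5.0, 10.0} ps (approximately log-spaced). Data set 1 is
#' the (6.7 cm^-1, 5.0 ps) reference; data set 15 has the smallest amplitude
#' and smallest time constant.
#'
#' @return data.frame with columns `id`, `delta`, `tau` (15 rows)
#' @export
reference_panel <- function() {
  combos <- expand.grid(delta = c(3.3, 6.7, 13.3), tau = c(0.8, 1.5, 2.8, 5.0, 10.0))
  first <- combos$delta == 6.7 & combos$tau == 5.0
  last <- combos$delta == 3.3 & combos$tau == 0.8
  mid <- combos[!(first | last), ]
  mid <- mid[order(-mid$delta, -mid$tau), ]
  out <- rbind(combos[first, ], mid, combos[last, ])
  out <- data.frame(id = 1:15, delta = out$delta, tau = out$tau)
  rownames(out) <- NULL
  out
}
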