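# Plain-text serialization of datasets and training records: a CSV manifest
# (index, delta, tau, pdm, label, split), a flattened payload CSV, and a JSON
# metadata file carrying the generating spec, seed, and array dimensions.

spec_meta <- function(spec) {
  if (is.null(spec)) return(NULL)
  list(reference = c(delta = spec$boundary$ref$delta, tau = spec$boundary$ref$tau),
       boundary = spec$boundary$boundary,
       cauchy_scale = spec$boundary$cauchy_scale,
       n_samples = spec$n_samples, balance = spec$balance, snr = spec$snr,
       slice_selection = spec$slice_selection, split = spec$split)
}

#' Write a dataset to a plain-text directory container
#'
#' Writes `manifest.csv` (per-sample parameters, PDM, label, split),
#' `payload.csv` (flattened channel tensors, one row per sample), and
#' `meta.json` (generating spec, seed, payload dimensions).
#'
#' @param ds a `kubonet_dataset`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  split <- rep("train", length(ds$y))
  split[ds$val_idx] <- "validation"
  manifest <- cbind(data.frame(index = seq_along(ds$y)), ds$params,
                    data.frame(label = ds$y, split = split))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(ds$x)) {
    d <- dim(ds$x)
    m <- t(matrix(ds$x, prod(d[-length(d)]), d[length(d)]))
    utils::write.csv(m, file.path(dir, "payload.csv"), row.names = FALSE)
  }
  meta <- list(seed = ds$seed, dims = dim(ds$x), spec = spec_meta(ds$spec))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`, `payload.csv`, `meta.json`
#' @return a `kubonet_dataset` (without the generating spec object)
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  x <- NULL
  pf <- file.path(dir, "payload.csv")
  if (file.exists(pf)) {
    m <- as.matrix(utils::read.csv(pf))
    x <- array(t(m), dim = meta$dims)
  }
  structure(list(x = x, y = manifest$label,
                 params = manifest[, c("delta", "tau", "pdm")],
                 train_idx = which(manifest$split == "train"),
                 val_idx = which(manifest$split == "validation"),
                 spec = meta$spec, seed = meta$seed),
            class = "kubonet_dataset")
}

#' Write a training record to CSV + JSON
#'
#' @param fit a `kubonet_fit`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_train_record <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$record, file.path(dir, "record.csv"), row.names = FALSE)
  meta <- list(best_epoch = fit$best_epoch, stop_epoch = fit$stop_epoch,
               train_config = unclass(fit$train_cfg),
               model_config = unclass(fit$model$cfg))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
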