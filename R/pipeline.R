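config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

pipeline_dataset_spec <- function(cfg) {
  ref <- kubo_component(cfg$reference$delta %||% 20 / 3, cfg$reference$tau %||% 5)
  bspec <- pdm_boundary_spec(ref, boundary = cfg$boundary %||% 0.10,
                             cauchy_scale = cfg$cauchy_scale %||% 0.05)
  slice <- cfg$slice %||% c(0, 0.75)
  if (is.list(slice)) slice <- unlist(slice)
  dataset_spec(bspec, n_samples = cfg$n_samples %||% 2000L,
               snr = cfg$snr %||% 100, slice_selection = slice,
               split = cfg$split %||% 0.8)
}

#' Run a configured end-to-end pipeline
#'
#' Executes an ordered subset of the stages `make-dataset`, `train`, `scan`,
#' writing each stage's CSV/JSON artifacts and a manifest with config hashes
#' and derived seeds under `out_dir`. A stage whose manifest entry matches
#' the current config hash is skipped (cache hit). A single global seed
#' derives per-stage seeds by a fixed offset per stage index, so adding a
#' stage does not perturb earlier stages' randomness.
#'
#' @param config a named list (or path to a YAML file) with a `stages`
#'   character vector and per-stage settings under `dataset`, `train`, `scan`
#' @param out_dir output directory
#' @param seed global integer seed
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("make-dataset", "train")
  known <- c("make-dataset", "train", "scan")
  if (!all(stages %in% known))
    stop_domain("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  dspec <- pipeline_dataset_spec(config$dataset %||% list())
  ds <- NULL
  for (i in seq_along(stages)) {
    stage <- stages[i]
    stage_seed <- as.integer(seed) + 1000L * (match(stage, known) - 1L)
    h <- config_hash(list(stage = stage, cfg = config[[gsub("-", "_", stage)]],
                          dataset = config$dataset, seed = stage_seed))
    cached <- identical(manifest[[stage]]$hash, as.vector(h))
    if (stage == "make-dataset") {
      ddir <- file.path(out_dir, "dataset")
      if (cached && file.exists(file.path(ddir, "manifest.csv"))) {
        message("stage make-dataset: cache hit")
        ds <- read_dataset(ddir)
      } else {
        ds <- generate_dataset(dspec, seed = stage_seed)
        write_dataset(ds, ddir)
      }
      manifest[[stage]] <- list(hash = h, seed = stage_seed, path = ddir)
    } else if (stage == "train") {
      tdir <- file.path(out_dir, "train")
      if (cached && file.exists(file.path(tdir, "record.csv"))) {
        message("stage train: cache hit")
      } else {
        if (is.null(ds)) ds <- generate_dataset(dspec, seed = as.integer(seed))
        tc <- config$train %||% list()
        fit <- train_classifier(ds,
                                model_config(width = tc$width %||% 8L),
                                train_config(max_epochs = tc$max_epochs %||% 60L,
                                             batch_size = tc$batch_size %||% 100L,
                                             patience_epochs = tc$patience %||% 30L,
                                             seed = stage_seed))
        write_train_record(fit, tdir)
      }
      manifest[[stage]] <- list(hash = h, seed = stage_seed, path = tdir)
    } else if (stage == "scan") {
      sdir <- file.path(out_dir, "scan")
      if (cached && file.exists(file.path(sdir, "bss_map.csv"))) {
        message("stage scan: cache hit")
      } else {
        sc <- config$scan %||% list()
        map <- slice_scan(dspec,
                          t1_values = unlist(sc$t1_values) %||% c(0, 1, 2),
                          t2_values = unlist(sc$t2_values) %||% c(0.75, 3, 6),
                          model_cfg = model_config(width = sc$width %||% 8L),
                          train_cfg = train_config(max_epochs = sc$max_epochs %||% 60L,
                                                   batch_size = 100L,
                                                   patience_epochs = sc$patience %||% 30L,
                                                   seed = stage_seed),
                          seed = stage_seed)
        dir.create(sdir, showWarnings = FALSE)
        utils::write.csv(as.data.frame(map), file.path(sdir, "bss_map.csv"),
                         row.names = FALSE)
      }
      manifest[[stage]] <- list(hash = h, seed = stage_seed, path = sdir)
    }
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
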