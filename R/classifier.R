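#' Training protocol configuration
#'
#' Defaults mirror the experimental protocol: up to 1000 epochs with
#' Brier-score early stopping (patience 100 epochs on the smoothed validation
#' Brier score). The optimizer (Adam), learning rate, and batch size are
#' configurable defaults of this implementation, recorded with every run.
#'
#' @param max_epochs maximum training epochs (default 1000)
#' @param batch_size minibatch size (default 64)
#' @param learning_rate Adam learning rate (default 1e-3)
#' @param early_stop enable Brier-score early stopping (default TRUE)
#' @param patience_epochs early-stopping patience in epochs (default 100)
#' @param smoothing_window centered moving-average window for the validation
#'   Brier score, in epochs (odd; default 21)
#' @param k_folds number of cross-validation folds for [cross_validate()]
#'   (default NULL: single split)
#' @param seed integer seed controlling initialization and batch order
#' @param lr_decay_epoch optional epoch from which the learning rate is
#'   multiplied by `lr_decay_factor` (a single step decay; default none)
#' @param lr_decay_factor multiplier applied from `lr_decay_epoch` on
#' @return an object of class `train_config`
#' @export
train_config <- function(max_epochs = 1000L, batch_size = 64L,
                         learning_rate = 1e-3, early_stop = TRUE,
                         patience_epochs = 100L, smoothing_window = 21L,
                         k_folds = NULL, seed = 1L,
                         lr_decay_epoch = NULL, lr_decay_factor = 0.3) {
  if (patience_epochs < 1L) stop_domain("`patience_epochs` must be >= 1")
  if (learning_rate <= 0) stop_domain("`learning_rate` must be positive")
  if (smoothing_window %% 2L == 0L) stop_domain("`smoothing_window` must be odd")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, early_stop = early_stop,
                 patience_epochs = as.integer(patience_epochs),
                 smoothing_window = as.integer(smoothing_window),
                 k_folds = k_folds, seed = as.integer(seed),
                 lr_decay_epoch = lr_decay_epoch,
                 lr_decay_factor = lr_decay_factor),
            class = "train_config")
}

#' Softmax class pseudoprobabilities
#'
#' Runs a forward pass and rescales the two logits by the softmax function
#' into pseudoprobabilities summing to one per sample.
#'
#' @param object a `kubonet_model` or fitted `kubonet_fit`
#' @param batch 5-D input array `(d1, d2, d3, channels, n)`
#' @return matrix `(n, 2)` of class probabilities, columns = classes (0, 1)
#' @export
predict_proba <- function(object, batch) {
  if (inherits(object, "kubonet_fit")) {
    model <- object$model
    par <- object$par_best; bn <- object$bn_best
  } else if (inherits(object, "kubonet_model")) {
    model <- object; par <- model$par; bn <- model$bn
  } else stop_domain("`object` must be a kubonet_model or kubonet_fit")
  batch <- as_batch_5d(batch)
  n <- dim(batch)[5L]
  out <- matrix(NA_real_, n, 2L)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    r <- nn_logits(model, batch[, , , , idx, drop = FALSE], par = par, bn = bn,
                   train = FALSE)
    out[idx, ] <- softmax_rows(r$logits)
  }
  colnames(out) <- c("p0", "p1")
  out
}

#' Thresholded binary accuracy
#'
#' Fraction of samples whose predicted class (the class with the larger
#' softmax pseudoprobability, i.e. positive-class probability above the
#' threshold) matches the label. Exact ties at the threshold are broken
#' toward class 0.
#'
#' @param probs matrix `(n, 2)` of class probabilities, or a vector of
#'   positive-class probabilities
#' @param labels 0/1 labels of length n
#' @param threshold decision threshold (default 0.5)
#' @return accuracy in `[0, 1]`
#' @export
binary_accuracy <- function(probs, labels, threshold = 0.5) {
  p1 <- if (is.matrix(probs)) probs[, 2L] else probs
  if (!length(p1)) stop_domain("empty input")
  if (length(p1) != length(labels)) stop_domain("probs and labels lengths differ")
  pred <- as.integer(p1 > threshold)   # tie (p1 == threshold) -> class 0
  mean(pred == labels)
}

#' Disjoint k-fold index split
#'
#' Randomly partitions `1:n` into `k` folds with sizes differing by at most
#' one; each fold serves once as the validation set.
#'
#' @param n number of samples (>= k)
#' @param k number of folds (default 5)
#' @param seed integer seed
#' @return list of k integer index vectors
#' @export
kfold_split <- function(n, k = 5L, seed = 1L) {
  if (n < k) stop_domain("`n` must be at least `k`")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}

smooth_centered <- function(x, window) {
  if (length(x) < window) return(rep(NA_real_, length(x)))
  as.vector(stats::filter(x, rep(1 / window, window), sides = 2))
}

#' Brier-score early-stopping rule
#'
#' Smooths the per-epoch validation Brier history by a centered moving
#' average, then halts iff (a) the minimum of the smoothed score over the
#' last `patience` epochs is no lower than the minimum over all earlier
#' epochs, and (b) the finite-difference slope of the smoothed tail (least
#' squares over the last `slope_window` points) is positive. Histories
#' shorter than the smoothing window plus patience never halt.
#'
#' @param brier_history per-epoch validation Brier scores
#' @param patience patience in epochs (default 100)
#' @param smoothing_window centered moving-average window (odd; default 21)
#' @param slope_window points used for the tail slope (default 11)
#' @return logical halt decision, with attributes `smoothed` and `slope`
#' @export
early_stop_check <- function(brier_history, patience = 100L,
                             smoothing_window = 21L, slope_window = 11L) {
  sm <- smooth_centered(brier_history, smoothing_window)
  sm <- sm[!is.na(sm)]
  res <- FALSE
  slope <- NA_real_
  if (length(sm) > patience && length(sm) >= slope_window) {
    tail_min <- min(sm[(length(sm) - patience + 1L):length(sm)])
    head_min <- min(sm[1:(length(sm) - patience)])
    tl <- sm[(length(sm) - slope_window + 1L):length(sm)]
    slope <- unname(coef(lm(tl ~ seq_along(tl)))[2L])
    res <- tail_min >= head_min && slope > 0
  }
  attr(res, "smoothed") <- sm
  attr(res, "slope") <- slope
  res
}

eval_metrics <- function(model, par, bn, x, y, batch = 512L) {
  n <- length(y)
  p1 <- numeric(n); loss <- 0
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    r <- nn_logits(model, x[, , , , idx, drop = FALSE], par = par, bn = bn,
                   train = FALSE)
    lg <- xent_loss_grad(r$logits, y[idx])
    loss <- loss + lg$loss * length(idx)
    p1[idx] <- lg$p[, 2L]
  }
  list(loss = loss / n, brier = mean((p1 - y)^2),
       acc = binary_accuracy(p1, y), p1 = p1)
}

#' Train a residual convolutional classifier
#'
#' Fits the network by minibatch Adam on softmax cross-entropy, recording
#' per-epoch training and validation cross-entropy, Brier score, and
#' thresholded accuracy. The returned fit carries the parameter state of the
#' best epoch (minimum validation Brier score). When `early_stop` is enabled,
#' training halts as soon as [early_stop_check()] fires on the validation
#' Brier history.
#'
#' @param dataset a `kubonet_dataset` (from [generate_dataset()]), or a list
#'   with elements `x` (5-D array), `y`, `train_idx`, `val_idx`
#' @param model_cfg a [model_config()]; `channels_in` is taken from the data
#' @param train_cfg a [train_config()]
#' @return an object of class `kubonet_fit` with elements `model`,
#'   `par_best`, `bn_best`, `record` (per-epoch data.frame), `best_epoch`,
#'   `stop_epoch`, `train_cfg`
#' @export
train_classifier <- function(dataset, model_cfg = model_config(),
                             train_cfg = train_config()) {
  x <- dataset$x; y <- dataset$y
  d <- dim(x)
  if (length(d) != 5L) stop_domain("dataset payload must be a 5-D array")
  set.seed(train_cfg$seed)
  cfg <- model_cfg
  cfg$channels_in <- d[4L]
  model <- build_classifier(cfg, input_shape = d[1:3])
  par <- model$par; bn <- model$bn
  opt <- adam_init(par)
  tr <- dataset$train_idx; va <- dataset$val_idx
  if (!length(tr) || !length(va)) stop_domain("dataset must carry a train/validation split")

  rec <- vector("list", train_cfg$max_epochs)
  best_brier <- Inf; best_epoch <- NA_integer_
  par_best <- par; bn_best <- bn
  stop_epoch <- train_cfg$max_epochs
  for (epoch in seq_len(train_cfg$max_epochs)) {
    lr_now <- train_cfg$learning_rate
    if (!is.null(train_cfg$lr_decay_epoch) && epoch >= train_cfg$lr_decay_epoch)
      lr_now <- lr_now * train_cfg$lr_decay_factor
    ord <- sample(tr)
    tl <- 0; tn <- 0L; tcorrect <- 0; tbrier <- 0
    for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
      xb <- x[, , , , idx, drop = FALSE]; yb <- y[idx]
      fw <- nn_logits(model, xb, par = par, bn = bn, train = TRUE)
      bn <- fw$bn
      lg <- xent_loss_grad(fw$logits, yb)
      if (!is.finite(lg$loss))
        stop_domain("training diverged (non-finite loss) at epoch ", epoch,
                    "; lower the learning rate")
      bw <- nn_backward_nodes(model$nodes, fw$caches, lg$dlogits, par, list(),
                              root = TRUE)
      st <- adam_step(par, bw$grads, opt, lr_now)
      par <- st$par; opt <- st$state
      nb <- length(idx)
      tl <- tl + lg$loss * nb; tn <- tn + nb
      tbrier <- tbrier + sum((lg$p[, 2L] - yb)^2)
      tcorrect <- tcorrect + sum(as.integer(lg$p[, 2L] > 0.5) == yb)
    }
    vm <- eval_metrics_subset(model, par, bn, x, y, va)
    rec[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / tn,
                               train_brier = tbrier / tn, train_acc = tcorrect / tn,
                               val_loss = vm$loss, val_brier = vm$brier,
                               val_acc = vm$acc)
    if (vm$brier < best_brier) {
      best_brier <- vm$brier; best_epoch <- epoch
      par_best <- par; bn_best <- bn
    }
    if (train_cfg$early_stop) {
      hist <- vapply(rec[seq_len(epoch)], function(r) r$val_brier, numeric(1L))
      if (isTRUE(early_stop_check(hist, train_cfg$patience_epochs,
                                  train_cfg$smoothing_window)[1L])) {
        stop_epoch <- epoch
        break
      }
    }
  }
  record <- do.call(rbind, rec[!vapply(rec, is.null, logical(1L))])
  record$smoothed_val_brier <- smooth_centered(record$val_brier,
                                               min(train_cfg$smoothing_window,
                                                   (nrow(record) %/% 2L) * 2L + 1L))
  model$par <- par; model$bn <- bn
  structure(list(model = model, par_best = par_best, bn_best = bn_best,
                 record = record, best_epoch = best_epoch,
                 stop_epoch = min(stop_epoch, nrow(record)),
                 train_cfg = train_cfg),
            class = "kubonet_fit")
}

eval_metrics_subset <- function(model, par, bn, x, y, idx) {
  eval_metrics(model, par, bn, x[, , , , idx, drop = FALSE], y[idx])
}

#' @export
print.kubonet_fit <- function(x, ...) {
  r <- x$record
  cat(sprintf("kubonet fit: %d epochs (best %d), best val Brier %.4f, best val accuracy %.3f\n",
              nrow(r), x$best_epoch, min(r$val_brier), max(r$val_acc)))
  invisible(x)
}

#' @export
summary.kubonet_fit <- function(object, ...) {
  r <- object$record
  out <- list(epochs = nrow(r), best_epoch = object$best_epoch,
              stop_epoch = object$stop_epoch,
              best_val_brier = min(r$val_brier),
              best_val_acc = max(r$val_acc),
              final_val_acc = r$val_acc[nrow(r)],
              best_val_bss = 1 - min(r$val_brier) / 0.25)
  class(out) <- "summary.kubonet_fit"
  out
}

#' @export
print.summary.kubonet_fit <- function(x, ...) {
  cat(sprintf(paste0("Residual classifier training summary\n",
                     "  epochs run:        %d (stopped at %d, best %d)\n",
                     "  best val Brier:    %.4f\n",
                     "  best val accuracy: %.3f (final %.3f)\n"),
              x$epochs, x$stop_epoch, x$best_epoch, x$best_val_brier,
              x$best_val_acc, x$final_val_acc))
  invisible(x)
}

#' @export
predict.kubonet_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "kubonet_dataset")) newdata <- newdata$x
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p[, 2L] > 0.5)
}

#' @export
plot.kubonet_fit <- function(x, ...) {
  r <- x$record
  graphics::matplot(r$epoch, cbind(r$train_brier, r$val_brier, r$smoothed_val_brier),
                    type = "l", lty = c(2, 1, 1), lwd = c(1, 1, 2),
                    col = c("grey50", "black", "firebrick"),
                    xlab = "epoch", ylab = "Brier score", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation", "smoothed validation"),
                   lty = c(2, 1, 1), col = c("grey50", "black", "firebrick"),
                   bty = "n")
  invisible(x)
}

#' k-fold cross-validated training
#'
#' Trains one classifier per fold, each fold serving once as the validation
#' set, and reports per-fold best validation metrics.
#'
#' @param dataset a `kubonet_dataset`; its own split is ignored
#' @param model_cfg a [model_config()]
#' @param train_cfg a [train_config()]; `k_folds` (default 5) folds are used
#' @return list with `fits` (per-fold `kubonet_fit`) and `metrics`
#'   (data.frame of per-fold best validation Brier/accuracy)
#' @export
cross_validate <- function(dataset, model_cfg = model_config(),
                           train_cfg = train_config()) {
  k <- train_cfg$k_folds %||% 5L
  folds <- kfold_split(length(dataset$y), k, seed = train_cfg$seed)
  fits <- vector("list", k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    ds <- dataset
    ds$val_idx <- sort(folds[[i]])
    ds$train_idx <- sort(unlist(folds[-i], use.names = FALSE))
    cfg_i <- train_cfg
    cfg_i$seed <- train_cfg$seed + i
    fits[[i]] <- train_classifier(ds, model_cfg, cfg_i)
    r <- fits[[i]]$record
    rows[[i]] <- data.frame(fold = i, best_val_brier = min(r$val_brier),
                            best_val_acc = max(r$val_acc))
  }
  list(fits = fits, metrics = do.call(rbind, rows))
}
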