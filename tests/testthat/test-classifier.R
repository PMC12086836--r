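test_that("forward pass yields two logits and softmax pseudoprobabilities", {
  set.seed(1)
  m <- build_classifier(model_config(width = 4), input_shape = c(32, 1, 1))
  x <- array(rnorm(32 * 2 * 7), dim = c(32, 1, 1, 2, 7))
  lg <- kubonet:::nn_logits(m, x)$logits
  expect_equal(dim(lg), c(7L, 2L))
  p <- predict_proba(m, x)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  # softmax symmetry and monotonicity
  expect_equal(kubonet:::softmax_rows(matrix(0, 1, 2)), matrix(0.5, 1, 2))
  s <- kubonet:::softmax_rows(matrix(c(2, 1), 1))
  expect_gt(s[1], s[2])
})

test_that("rank-3 configuration accepts and squeezes singleton spatial axes", {
  set.seed(1)
  m <- build_classifier(model_config(input_rank = 3, width = 4),
                        input_shape = c(32, 1, 1))
  x <- array(rnorm(32 * 2 * 3), dim = c(32, 1, 1, 2, 3))
  expect_equal(dim(kubonet:::nn_logits(m, x)$logits), c(3L, 2L))
  # 2-D input under a rank-2 config
  m2 <- build_classifier(model_config(input_rank = 2, channels_in = 1, width = 4),
                         input_shape = c(16, 16, 1))
  x2 <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 1, 1, 3))
  expect_equal(dim(kubonet:::nn_logits(m2, x2)$logits), c(3L, 2L))
  # too-small input rejected
  expect_error(build_classifier(model_config(width = 4), input_shape = c(4, 1, 1)),
               "receptive field")
  # more non-singleton axes than the configured rank rejected
  expect_error(build_classifier(model_config(input_rank = 1, width = 4),
                                input_shape = c(16, 16, 1)), "non-singleton")
})

test_that("identical seeds build identical models", {
  set.seed(42); m1 <- build_classifier(model_config(width = 4), c(32, 1, 1))
  set.seed(42); m2 <- build_classifier(model_config(width = 4), c(32, 1, 1))
  expect_identical(m1$par, m2$par)
  x <- array(rnorm(32 * 2 * 4), dim = c(32, 1, 1, 2, 4))
  expect_identical(predict_proba(m1, x), predict_proba(m2, x))
})

test_that("analytic gradients match finite differences through every layer type", {
  set.seed(7)
  m <- build_classifier(model_config(width = 4), input_shape = c(16, 1, 1))
  x <- array(rnorm(16 * 2 * 5), dim = c(16, 1, 1, 2, 5))
  y <- c(0, 1, 1, 0, 1)
  fw <- kubonet:::nn_logits(m, x, train = TRUE)
  lg <- kubonet:::xent_loss_grad(fw$logits, y)
  bw <- kubonet:::nn_backward_nodes(m$nodes, fw$caches, lg$dlogits, m$par, list())
  for (id in names(m$par)) {
    for (slot in names(m$par[[id]])) {
      idx <- sample(length(m$par[[id]][[slot]]), 1L)
      ng <- kubonet:::numeric_grad(m, x, y, id, slot, idx)
      ag <- unname(bw$grads[[id]][[slot]][idx])
      expect_equal(ag, ng, tolerance = 1e-4,
                   label = sprintf("grad %s/%s", id, slot))
    }
  }
})

test_that("binary accuracy applies the 0.5 threshold with ties toward class 0", {
  probs <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(binary_accuracy(probs, c(0, 1)), 1)
  expect_equal(binary_accuracy(probs, c(1, 0)), 0)
  # exact ties predict class 0
  tied <- matrix(0.5, 4, 2)
  expect_equal(binary_accuracy(tied, c(0, 1, 0, 1)), 0.5)
  expect_error(binary_accuracy(matrix(numeric(0), 0, 2), integer(0)), "empty")
})

test_that("k-fold splits partition the indices nearly evenly", {
  folds <- kfold_split(1126, 5, seed = 3)
  expect_equal(sort(unname(lengths(folds)), decreasing = TRUE),
               c(226L, 225L, 225L, 225L, 225L))
  all_idx <- sort(unlist(folds, use.names = FALSE))
  expect_identical(all_idx, 1:1126)
  expect_identical(kfold_split(100, 5, seed = 9), kfold_split(100, 5, seed = 9))
  expect_error(kfold_split(3, 5), "at least")
})

test_that("Brier early stopping fires exactly where a brute-force replay says", {
  # strictly decreasing history: never halts
  expect_false(early_stop_check(seq(1, 0.1, length.out = 300), patience = 50,
                                smoothing_window = 21)[1])
  # flat then rising history halts
  set.seed(2)
  hist <- c(seq(0.5, 0.2, length.out = 100), rep(0.2, 120),
            seq(0.2, 0.4, length.out = 50)) + rnorm(270, 0, 1e-4)
  expect_true(early_stop_check(hist, patience = 50, smoothing_window = 21)[1])
  # V-shaped history: replay the rule epoch by epoch and compare first halt
  v <- c(seq(0.6, 0.1, length.out = 80), seq(0.1, 0.5, length.out = 120)) +
    rnorm(200, 0, 1e-4)
  replay_halt <- function(h, patience, window, slope_window = 11L) {
    for (e in seq_along(h)) {
      if (e < window) next
      sm <- stats::filter(h[1:e], rep(1 / window, window), sides = 2)
      sm <- as.vector(sm); sm <- sm[!is.na(sm)]
      if (length(sm) <= patience || length(sm) < slope_window) next
      tail_min <- min(sm[(length(sm) - patience + 1):length(sm)])
      head_min <- min(sm[1:(length(sm) - patience)])
      tl <- sm[(length(sm) - slope_window + 1):length(sm)]
      sl <- unname(coef(lm(tl ~ seq_along(tl)))[2])
      if (tail_min >= head_min && sl > 0) return(e)
    }
    NA_integer_
  }
  expected <- replay_halt(v, patience = 40, window = 21)
  expect_false(is.na(expected))
  for (e in seq_len(length(v))) {
    got <- isTRUE(early_stop_check(v[1:e], patience = 40, smoothing_window = 21)[1])
    expect_equal(got, e >= expected, label = paste("epoch", e))
    if (got) break
  }
  # histories shorter than the window never halt
  expect_false(early_stop_check(rep(0.3, 5), patience = 3, smoothing_window = 21)[1])
})

test_that("training separates well-separated classes and is seed-deterministic", {
  # two PDM-separated parameter clouds at high SNR, full mixed-domain
  # signals: near-perfect classification within a few epochs
  ref <- kubo_component(20 / 3, 5)
  small_grid <- time_grid(t1_axis = seq(0, 4, by = 1), t2_axis = c(0, 1.5, 3),
                          t3_axis = seq(0, 4, length.out = 32), n_pad = 32L)
  spec <- dataset_spec(pdm_boundary_spec(ref, boundary = 0.25, cauchy_scale = 0.2),
                       n_samples = 200L, snr = 100, slice_selection = "full",
                       grid = small_grid)
  set.seed(1)
  n <- 200L
  inside <- data.frame(delta = rep(ref$delta, n / 2), tau = rep(ref$tau, n / 2),
                       pdm = 0)
  th <- runif(n / 2, 0, 2 * pi)
  outside <- data.frame(delta = ref$delta * (1 + 0.5 * cos(th)),
                        tau = ref$tau * (1 + 0.5 * sin(th)), pdm = 0.5)
  par <- rbind(inside, outside)
  y <- rep(c(1L, 0L), each = n / 2)
  perm <- sample.int(n)
  x <- kubonet:::dataset_from_params(par[perm, ], spec)
  ds <- list(x = x, y = y[perm], params = par[perm, ],
             train_idx = 1:160, val_idx = 161:200)
  fit <- train_classifier(ds, model_config(input_rank = 3, width = 8),
                          fast_train_cfg(epochs = 25L))
  expect_gte(max(fit$record$val_acc), 0.99)
  # chance level on permuted labels
  ds_perm <- ds
  set.seed(33)
  ds_perm$y <- sample(ds$y)
  fit_perm <- train_classifier(ds_perm, model_config(input_rank = 3, width = 8),
                               fast_train_cfg(epochs = 10L))
  acc <- fit_perm$record$val_acc[fit_perm$best_epoch]
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
  # same seed, same data: identical record
  f1 <- train_classifier(ds, model_config(input_rank = 3, width = 4),
                         fast_train_cfg(epochs = 4L))
  f2 <- train_classifier(ds, model_config(input_rank = 3, width = 4),
                         fast_train_cfg(epochs = 4L))
  expect_identical(f1$record, f2$record)
  expect_identical(f1$par_best, f2$par_best)
  # fit object interface
  expect_s3_class(fit, "kubonet_fit")
  p <- predict(fit, ds$x[, , , , 1:5, drop = FALSE])
  expect_equal(dim(p), c(5L, 2L))
  expect_output(print(fit), "kubonet fit")
  expect_output(print(summary(fit)), "best val accuracy")
})
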