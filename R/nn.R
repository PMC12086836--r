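# Residual convolutional network internals.
#
# Tensors are stored as 5-D arrays (d1, d2, d3, C, N) with singleton spatial
# dims for inputs of lower rank; convolutions run through the compiled
# im2col/GEMM kernels in src/conv.cpp. The model is a small explicit graph
# (conv / bn / relu / res / gap / fc nodes) with parameters held in a named
# list so they can be snapshotted, flattened for Adam, and gradient-checked.

bn_forward <- function(x, gamma, beta, run, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[4L]; N <- d[5L]; spat <- prod(d[1:3])
  if (train) {
    st <- .bn_stats(x, spat, C, N)
    mu <- st$mean; va <- st$var
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * va
  } else {
    mu <- run$mean; va <- run$var
  }
  invstd <- 1 / sqrt(va + eps)
  y <- .bn_fwd(x, spat, C, N, gamma * invstd, beta - gamma * invstd * mu)
  dim(y) <- d
  list(y = y, cache = list(x = x, mu = mu, invstd = invstd, gamma = gamma,
                           dims = d), run = run)
}

bn_backward <- function(dy, cache) {
  d <- cache$dims
  g <- .bn_bwd(cache$x, dy, prod(d[1:3]), d[4L], d[5L], cache$gamma,
               cache$mu, cache$invstd)
  dx <- g$dx
  dim(dx) <- d
  list(dx = dx, dgamma = g$dgamma, dbeta = g$dbeta)
}

nn_forward_nodes <- function(nodes, x, par, bn, train) {
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$type == "conv") {
      p <- par[[nd$id]]
      if (train) {
        r <- .conv_forward(x, p$W, p$b, nd$k, nd$stride, nd$pad, keep_cols = TRUE)
        caches[[i]] <- list(x = x, cols = r$cols)
        x <- r$y
      } else {
        caches[[i]] <- NULL
        x <- .conv_forward(x, p$W, p$b, nd$k, nd$stride, nd$pad)
      }
    } else if (nd$type == "bn") {
      p <- par[[nd$id]]
      r <- bn_forward(x, p$gamma, p$beta, bn[[nd$id]], train)
      bn[[nd$id]] <- r$run
      caches[[i]] <- r$cache
      x <- r$y
    } else if (nd$type == "relu") {
      d <- dim(x)
      x <- .relu_fwd(x)
      dim(x) <- d
      caches[[i]] <- list(y = x)
    } else if (nd$type == "res") {
      main <- nn_forward_nodes(nd$main, x, par, bn, train)
      bn <- main$bn
      short <- if (!is.null(nd$shortcut)) {
        s <- nn_forward_nodes(nd$shortcut, x, par, bn, train)
        bn <- s$bn
        s
      } else NULL
      y <- main$out + if (is.null(short)) x else short$out
      d <- dim(y)
      y <- .relu_fwd(y)
      dim(y) <- d
      caches[[i]] <- list(main = main$caches, short = short$caches,
                          y = y, identity = is.null(short))
      x <- y
    } else if (nd$type == "gap") {
      d <- dim(x); spat <- prod(d[1:3])
      caches[[i]] <- list(dims = d)
      x <- t(matrix(.colMeans(matrix(x, spat, d[4L] * d[5L]), spat, d[4L] * d[5L]),
                    d[4L], d[5L]))               # (N x C)
    } else if (nd$type == "fc") {
      caches[[i]] <- list(x = x)
      p <- par[[nd$id]]
      x <- x %*% t(p$W) + matrix(p$b, nrow(x), length(p$b), byrow = TRUE)
    } else stop("unknown node type: ", nd$type)
  }
  list(out = x, caches = caches, bn = bn)
}

nn_backward_nodes <- function(nodes, caches, dout, par, grads, root = FALSE) {
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]; ch <- caches[[i]]
    if (nd$type == "conv") {
      p <- par[[nd$id]]
      need_dx <- !(root && i == 1L)   # the stem conv needs no input gradient
      g <- .conv_backward(ch$x, p$W, dout, nd$k, nd$stride, nd$pad,
                          cols_cache = ch$cols, need_dx = need_dx)
      grads[[nd$id]] <- list(W = g$dW + (grads[[nd$id]]$W %||% 0),
                             b = g$db + (grads[[nd$id]]$b %||% 0))
      dout <- g$dX
    } else if (nd$type == "bn") {
      g <- bn_backward(dout, ch)
      grads[[nd$id]] <- list(gamma = g$dgamma + (grads[[nd$id]]$gamma %||% 0),
                             beta = g$dbeta + (grads[[nd$id]]$beta %||% 0))
      dout <- g$dx
    } else if (nd$type == "relu") {
      d <- dim(dout)
      dout <- .relu_bwd(dout, ch$y)
      dim(dout) <- d
    } else if (nd$type == "res") {
      d <- dim(dout)
      dy <- .relu_bwd(dout, ch$y)
      dim(dy) <- d
      bm <- nn_backward_nodes(nd$main, ch$main, dy, par, grads)
      grads <- bm$grads
      if (ch$identity) {
        dout <- bm$dx + dy
      } else {
        bs <- nn_backward_nodes(nd$shortcut, ch$short, dy, par, grads)
        grads <- bs$grads
        dout <- bm$dx + bs$dx
      }
    } else if (nd$type == "gap") {
      d <- ch$dims; spat <- prod(d[1:3])
      dm <- t(dout) / spat                        # (C x N)
      dout <- array(rep(as.vector(dm), each = spat), dim = d)
    } else if (nd$type == "fc") {
      p <- par[[nd$id]]
      grads[[nd$id]] <- list(W = t(dout) %*% ch$x + (grads[[nd$id]]$W %||% 0),
                             b = colSums(dout) + (grads[[nd$id]]$b %||% 0))
      dout <- dout %*% p$W
    }
  }
  list(dx = dout, grads = grads)
}

#' Classifier architecture configuration
#'
#' @param input_rank number of spatial dimensions of the convolutions (1-3);
#'   inputs with singleton spatial axes are accepted and squeezed
#' @param channels_in input channels (1 for real, 2 for complex payloads)
#' @param width base filter count (>= 4); stage widths are width, 2*width,
#'   4*width
#' @param depth residual blocks per stage (default 1)
#' @param n_classes number of output classes (fixed at 2)
#' @return an object of class `model_config`
#' @export
model_config <- function(input_rank = 1L, channels_in = 2L, width = 8L,
                         depth = 1L, n_classes = 2L) {
  if (!input_rank %in% 1:3) stop_domain("`input_rank` must be 1, 2, or 3")
  if (width < 4L) stop_domain("`width` must be at least 4")
  if (n_classes != 2L) stop_domain("only binary classification is supported")
  structure(list(input_rank = as.integer(input_rank),
                 channels_in = as.integer(channels_in),
                 width = as.integer(width), depth = as.integer(depth),
                 n_classes = 2L), class = "model_config")
}

he_init <- function(nrow, ncol) matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / ncol)), nrow, ncol)

#' Build a compact residual convolutional classifier
#'
#' Constructs a ResNet-style network sized for the actual input: a strided
#' stem convolution, three stages of residual blocks (widths `w`, `2w`, `4w`;
#' the last two stages downsample by 2 with projection shortcuts), global
#' average pooling, and a final two-logit linear layer. Convolutions act only
#' on the non-singleton spatial axes of `input_shape`, so a rank-3
#' configuration fed 1-D slices squeezes naturally. Parameters are
#' He-initialized from the R random stream (seed it for reproducibility).
#'
#' @param cfg a [model_config()]
#' @param input_shape spatial dimensions of one payload (singletons allowed)
#' @return an object of class `kubonet_model`
#' @export
build_classifier <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "model_config"))
  spat <- c(input_shape, 1L, 1L, 1L)[1:3]
  active <- spat > 1L
  if (!any(active)) stop_domain("input has no non-singleton spatial axis")
  if (sum(active) > cfg$input_rank)
    stop_domain("input has more non-singleton spatial axes than `input_rank`")
  if (max(spat[active]) < 8L)
    stop_domain("input spatial extent below the network's minimum receptive field (8)")
  kv <- function(k) ifelse(active, k, 1L)
  sv <- function(s) ifelse(active, s, 1L)
  pv <- function(k) ifelse(active, (k - 1L) %/% 2L, 0L)

  par <- list(); bn <- list(); id_n <- 0L
  new_id <- function(prefix) { id_n <<- id_n + 1L; paste0(prefix, id_n) }
  conv_node <- function(cin, cout, k, s) {
    id <- new_id("conv")
    kk <- kv(k)
    par[[id]] <<- list(W = he_init(cout, cin * prod(kk)), b = numeric(cout))
    list(type = "conv", id = id, k = kk, stride = sv(s), pad = pv(k),
         cin = cin, cout = cout)
  }
  bn_node <- function(c_) {
    id <- new_id("bn")
    par[[id]] <<- list(gamma = rep(1, c_), beta = numeric(c_))
    bn[[id]] <<- list(mean = numeric(c_), var = rep(1, c_))
    list(type = "bn", id = id)
  }
  res_node <- function(cin, cout, s) {
    main <- list(conv_node(cin, cout, 3L, s), bn_node(cout), list(type = "relu"),
                 conv_node(cout, cout, 3L, 1L), bn_node(cout))
    shortcut <- if (s > 1L || cin != cout)
      list(conv_node(cin, cout, 1L, s), bn_node(cout)) else NULL
    list(type = "res", main = main, shortcut = shortcut)
  }

  w <- cfg$width
  nodes <- list(conv_node(cfg$channels_in, w, 5L, 2L), bn_node(w), list(type = "relu"))
  widths <- c(w, 2L * w, 4L * w); strides <- c(1L, 2L, 2L)
  cin <- w
  for (st in 1:3) {
    for (blk in seq_len(cfg$depth)) {
      s <- if (blk == 1L) strides[st] else 1L
      nodes[[length(nodes) + 1L]] <- res_node(cin, widths[st], s)
      cin <- widths[st]
    }
  }
  nodes[[length(nodes) + 1L]] <- list(type = "gap")
  fc_id <- new_id("fc")
  par[[fc_id]] <- list(W = he_init(cfg$n_classes, cin), b = numeric(cfg$n_classes))
  nodes[[length(nodes) + 1L]] <- list(type = "fc", id = fc_id, cin = cin,
                                      cout = cfg$n_classes)
  structure(list(cfg = cfg, input_shape = spat, nodes = nodes, par = par, bn = bn),
            class = "kubonet_model")
}

#' @export
print.kubonet_model <- function(x, ...) {
  np <- sum(vapply(unlist(x$par, recursive = FALSE), length, integer(1L)))
  cat(sprintf("Residual convolutional classifier: width %d, depth %d, input %s, %d parameters\n",
              x$cfg$width, x$cfg$depth, paste(x$input_shape, collapse = "x"), np))
  invisible(x)
}

as_batch_5d <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) { dim(x) <- c(d, 1L); return(x) }  # single sample
  if (length(d) == 5L) return(x)
  stop_domain("batch must be a 5-D array (d1, d2, d3, channels, n); got dims ",
              paste(d, collapse = "x"))
}

nn_logits <- function(model, x, par = model$par, bn = model$bn, train = FALSE) {
  r <- nn_forward_nodes(model$nodes, x, par, bn, train)
  list(logits = r$out, caches = r$caches, bn = r$bn)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

xent_loss_grad <- function(logits, y) {
  # y in {0, 1}; class order (0, 1) in columns
  p <- softmax_rows(logits)
  n <- nrow(logits)
  onehot <- cbind(1 - y, y)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], eps)))
  list(loss = loss, dlogits = (p - onehot) / n, p = p)
}

# Adam optimizer state and step over the nested parameter list
adam_init <- function(par) {
  zeros <- function(x) lapply(x, function(v) array(0, dim = dim(v) %||% length(v)))
  list(m = lapply(par, zeros), v = lapply(par, zeros), t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (id in names(grads)) {
    for (slot in names(grads[[id]])) {
      g <- grads[[id]][[slot]]
      m <- beta1 * state$m[[id]][[slot]] + (1 - beta1) * g
      v <- beta2 * state$v[[id]][[slot]] + (1 - beta2) * g * g
      state$m[[id]][[slot]] <- m
      state$v[[id]][[slot]] <- v
      par[[id]][[slot]] <- par[[id]][[slot]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(par = par, state = state)
}

# finite-difference gradient check used by the test suite
numeric_grad <- function(model, x, y, id, slot, idx, h = 1e-5) {
  f <- function(val) {
    par <- model$par
    par[[id]][[slot]][idx] <- val
    r <- nn_logits(model, x, par = par, train = TRUE)
    xent_loss_grad(r$logits, y)$loss
  }
  v0 <- model$par[[id]][[slot]][idx]
  (f(v0 + h) - f(v0 - h)) / (2 * h)
}
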