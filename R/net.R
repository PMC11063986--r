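#' Network configuration for the multi-scale 1D CNN
#'
#' The classifier is an inception-style 1D convolutional network for
#' multivariate time series: each block passes its input through a 1x1
#' bottleneck convolution followed by three parallel convolutions at distinct
#' kernel lengths plus a max-pool branch with its own 1x1 convolution; the
#' four branches are concatenated and rectified, with a projected residual
#' connection every `residual_every` blocks. Global average pooling over time
#' feeds a single linear softmax layer, the arrangement that makes class
#' activation maps exact (see [compute_cam()]). All convolutions use same
#' padding, so feature maps keep the input's temporal length.
#'
#' @param depth number of inception blocks (default 6).
#' @param filters filters per convolutional branch (default 32); the block
#'   output has `4 * filters` channels.
#' @param kernel_lengths three distinct kernel lengths (default 10, 20, 40).
#' @param bottleneck bottleneck channels (default 32).
#' @param residual_every add a projected shortcut every this many blocks (3).
#' @param epochs training epochs (default 1500; reduce for quick runs).
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-3), halved by
#'   `lr_factor` after `lr_patience` epochs without loss improvement, down to
#'   `lr_min`.
#' @param lr_patience,lr_factor,lr_min plateau-scheduler knobs.
#' @param seed integer seed governing initialization and batch shuffling.
#' @return a list of class `net_config`.
#' @export
net_config <- function(depth = 6L, filters = 32L,
                       kernel_lengths = c(10L, 20L, 40L), bottleneck = 32L,
                       residual_every = 3L, epochs = 1500L, batch_size = 64L,
                       learning_rate = 1e-3, lr_patience = 50L,
                       lr_factor = 0.5, lr_min = 1e-5, seed = 1L) {
  cfg <- list(depth = as.integer(depth), filters = as.integer(filters),
              kernel_lengths = as.integer(kernel_lengths),
              bottleneck = as.integer(bottleneck),
              residual_every = as.integer(residual_every),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              lr_patience = as.integer(lr_patience), lr_factor = lr_factor,
              lr_min = lr_min, seed = as.integer(seed))
  stopifnot(cfg$depth >= 1L, cfg$filters >= 1L, cfg$bottleneck >= 1L,
            cfg$residual_every >= 1L, cfg$epochs >= 0L, cfg$batch_size >= 1L)
  if (anyDuplicated(cfg$kernel_lengths))
    stop("kernel_lengths must be distinct", call. = FALSE)
  structure(cfg, class = "net_config")
}

rand_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Does block i receive a projected residual connection?
has_residual <- function(i, cfg) {
  i %% cfg$residual_every == 0L && i >= cfg$residual_every
}

# Channel count entering block i (1-based).
block_in_channels <- function(i, n_channels, cfg) {
  if (i == 1L) n_channels else 4L * cfg$filters
}

# Initialize all parameters; consumes the current RNG stream.
init_params <- function(cfg, n_channels, n_classes, input_length) {
  if (max(cfg$kernel_lengths) > input_length)
    stop(sprintf("kernel length %d exceeds input length %d",
                 max(cfg$kernel_lengths), input_length), call. = FALSE)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  f <- cfg$filters
  blocks <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    cin <- block_in_channels(i, n_channels, cfg)
    blk <- list(
      Wb = rand_mat(cin, cfg$bottleneck, cin), bb = numeric(cfg$bottleneck),
      conv = lapply(cfg$kernel_lengths, function(k)
        list(W = rand_mat(cfg$bottleneck * k, f, cfg$bottleneck * k),
             b = numeric(f))),
      Wp = rand_mat(cin, f, cin), bp = numeric(f))
    if (has_residual(i, cfg)) {
      csrc <- block_in_channels(i - cfg$residual_every + 1L, n_channels, cfg)
      blk$Wr <- rand_mat(csrc, 4L * f, csrc)
      blk$br <- numeric(4L * f)
    }
    blocks[[i]] <- blk
  }
  M <- 4L * f
  list(blocks = blocks,
       Wout = matrix(stats::rnorm(n_classes * M, 0, sqrt(1 / M)),
                     n_classes, M),
       bout = numeric(n_classes))
}

concat_channels <- function(cubes) {
  d1 <- dim(cubes[[1L]])[1L]; d3 <- dim(cubes[[1L]])[3L]
  out <- array(0, c(d1, sum(vapply(cubes, function(x) dim(x)[2L], 1L)), d3))
  at <- 0L
  for (x in cubes) {
    out[, at + seq_len(dim(x)[2L]), ] <- x
    at <- at + dim(x)[2L]
  }
  out
}

# Full forward pass on a batch cube in time-major layout (time x channels x
# n). Returns activations needed by the backward pass when keep = TRUE.
net_forward <- function(params, X, cfg, keep = FALSE) {
  depth <- cfg$depth
  Z <- vector("list", depth + 1L)
  Z[[1L]] <- X
  caches <- if (keep) vector("list", depth) else NULL
  for (i in seq_len(depth)) {
    blk <- params$blocks[[i]]
    Zin <- Z[[i]]
    B <- conv1d_fwd_cpp(Zin, blk$Wb, blk$bb, 1L)
    Cs <- lapply(seq_along(cfg$kernel_lengths), function(j)
      conv1d_fwd_cpp(B, blk$conv[[j]]$W, blk$conv[[j]]$b,
                     cfg$kernel_lengths[j]))
    mp <- maxpool1d_fwd_cpp(Zin, 3L)
    Q <- conv1d_fwd_cpp(mp$Y, blk$Wp, blk$bp, 1L)
    S <- concat_channels(c(Cs, list(Q)))
    if (has_residual(i, cfg)) {
      src <- i + 1L - cfg$residual_every
      S <- S + conv1d_fwd_cpp(Z[[src]], blk$Wr, blk$br, 1L)
    }
    Z[[i + 1L]] <- S * (S > 0)
    if (keep) caches[[i]] <- list(B = B, P = mp$Y, pidx = mp$idx, S = S)
  }
  A <- Z[[depth + 1L]]
  g <- apply(A, 3L, colMeans)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)   # single-filter edge case
  logits <- params$Wout %*% g + params$bout
  out <- list(g = g, logits = logits, A = A)
  if (keep) { out$Z <- Z; out$caches <- caches }
  out
}

softmax_cols <- function(L) {
  L <- sweep(L, 2L, apply(L, 2L, max))
  E <- exp(L)
  sweep(E, 2L, colSums(E), "/")
}

zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0

acc_or <- function(a, b) if (is.null(a)) b else a + b

# Cross-entropy loss and full gradient for a batch; the workhorse of
# training, also exercised directly by the finite-difference gradient test.
net_loss_grad <- function(params, X, Y, cfg) {
  fw <- net_forward(params, X, cfg, keep = TRUE)
  N <- ncol(fw$logits)
  T_ <- dim(X)[1L]
  P <- softmax_cols(fw$logits)
  loss <- -mean(log(pmax(colSums(Y * P), 1e-12)))
  grads <- zero_like(params)
  dlogits <- (P - Y) / N
  grads$Wout <- dlogits %*% t(fw$g)
  grads$bout <- rowSums(dlogits)
  dg <- t(params$Wout) %*% dlogits
  M <- nrow(dg)
  dZ <- vector("list", cfg$depth + 1L)
  dZ[[cfg$depth + 1L]] <- aperm(array(dg / T_, c(M, N, T_)), c(3L, 1L, 2L))
  f <- cfg$filters
  for (i in cfg$depth:1L) {
    blk <- params$blocks[[i]]
    cache <- fw$caches[[i]]
    dS <- dZ[[i + 1L]] * (cache$S > 0)
    if (has_residual(i, cfg)) {
      src <- i + 1L - cfg$residual_every
      bw <- conv1d_bwd_cpp(fw$Z[[src]], blk$Wr, dS, 1L)
      grads$blocks[[i]]$Wr <- bw$dW
      grads$blocks[[i]]$br <- as.numeric(bw$db)
      dZ[[src]] <- acc_or(dZ[[src]], bw$dX)
    }
    dB <- NULL
    for (j in seq_along(cfg$kernel_lengths)) {
      dCj <- dS[, (j - 1L) * f + seq_len(f), , drop = FALSE]
      bw <- conv1d_bwd_cpp(cache$B, blk$conv[[j]]$W, dCj,
                           cfg$kernel_lengths[j])
      grads$blocks[[i]]$conv[[j]]$W <- bw$dW
      grads$blocks[[i]]$conv[[j]]$b <- as.numeric(bw$db)
      dB <- acc_or(dB, bw$dX)
    }
    dQ <- dS[, 3L * f + seq_len(f), , drop = FALSE]
    bwp <- conv1d_bwd_cpp(cache$P, blk$Wp, dQ, 1L)
    grads$blocks[[i]]$Wp <- bwp$dW
    grads$blocks[[i]]$bp <- as.numeric(bwp$db)
    dZin <- maxpool1d_bwd_cpp(cache$pidx, bwp$dX)
    bwb <- conv1d_bwd_cpp(fw$Z[[i]], blk$Wb, dB, 1L)
    grads$blocks[[i]]$Wb <- bwb$dW
    grads$blocks[[i]]$bb <- as.numeric(bwb$db)
    dZin <- dZin + bwb$dX
    dZ[[i]] <- acc_or(dZ[[i]], dZin)
  }
  list(loss = loss, grads = grads)
}

# Bias vectors come back from the compiled trainer as 1-column matrices;
# restore the plain-vector shapes init_params uses.
repair_param_shapes <- function(p) {
  p$bout <- as.numeric(p$bout)
  for (i in seq_along(p$blocks)) {
    b <- p$blocks[[i]]
    b$bb <- as.numeric(b$bb)
    b$bp <- as.numeric(b$bp)
    for (j in seq_along(b$conv)) b$conv[[j]]$b <- as.numeric(b$conv[[j]]$b)
    if (!is.null(b$br)) b$br <- as.numeric(b$br)
    p$blocks[[i]] <- b
  }
  p
}

#' Fit the inception-style time-series classifier
#'
#' Trains the network of [net_config()] with Adam on softmax cross-entropy.
#' With `config$epochs = 0` the untrained (randomly initialized) model is
#' returned, which is still a valid classifier object — useful for
#' structural checks and as the input of a manual training loop.
#'
#' @param x a [labeled_dataset()] (z-normalized traces expected), or a
#'   numeric array `channels x time x n`.
#' @param y labels (ignored when `x` is a `labeled_dataset`); a factor whose
#'   levels fix the output classes, including classes that may have zero
#'   training prevalence.
#' @param config a [net_config()].
#' @return an object of class `inception_time` with components `params`,
#'   `config`, `classes`, `history` (per-epoch training loss) and the input
#'   geometry; see [predict.inception_time()], [feature_maps()],
#'   [compute_cam()].
#' @export
inception_time <- function(x, y = NULL, config = net_config()) {
  if (inherits(x, "labeled_dataset")) { y <- x$labels; x <- x$values }
  stopifnot(length(dim(x)) == 3L)
  if (!is.factor(y)) y <- factor(y)
  if (config$epochs > 0L && length(unique(as.character(y))) < 2L)
    stop("training set holds a single class; cannot fit a classifier",
         call. = FALSE)
  classes <- levels(y)
  n_ch <- dim(x)[1L]; T_ <- dim(x)[2L]; n <- dim(x)[3L]
  x <- aperm(x, c(2L, 1L, 3L))   # internal time-major layout
  model <- with_seed(config$seed, {
    params <- init_params(config, n_ch, length(classes), T_)
    history <- numeric(0)
    if (config$epochs > 0L) {
      Y_all <- matrix(0, length(classes), n)
      Y_all[cbind(as.integer(y), seq_len(n))] <- 1
      tr <- net_train_cpp(params, x, Y_all, config$kernel_lengths,
                          config$filters, config$residual_every,
                          config$epochs, config$batch_size,
                          config$learning_rate, config$lr_patience,
                          config$lr_factor, config$lr_min)
      params <- repair_param_shapes(tr$params)
      history <- as.numeric(tr$history)
    }
    list(params = params, history = history)
  })
  structure(list(params = model$params, config = config, classes = classes,
                 n_channels = n_ch, input_length = T_,
                 history = model$history, n_train = n),
            class = "inception_time")
}

#' Predict method for inception_time models
#'
#' @param object an [inception_time()] model.
#' @param newdata a `labeled_dataset`, a 3D array `channels x time x n`, or a
#'   single `channels x time` matrix.
#' @param type `"class"` (factor), `"prob"` (n x classes matrix) or
#'   `"logit"`.
#' @param ... unused.
#' @return predictions as requested.
#' @export
predict.inception_time <- function(object, newdata,
                                   type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "labeled_dataset")) newdata$values else newdata
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  stopifnot(dim(X)[1L] == object$n_channels,
            dim(X)[2L] == object$input_length)
  n <- dim(X)[3L]
  X <- aperm(X, c(2L, 1L, 3L))
  cfg <- object$config
  logits <- matrix(NA_real_, length(object$classes), n)
  for (start in seq(1L, n, by = 256L)) {
    b <- start:min(start + 255L, n)
    logits[, b] <- net_fwd_cpp(object$params, X[, , b, drop = FALSE],
                               cfg$kernel_lengths, cfg$filters,
                               cfg$residual_every, FALSE)$logits
  }
  if (type == "logit") return(t(logits))
  pr <- t(softmax_cols(logits))
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  factor(object$classes[max.col(pr, ties.method = "first")],
         levels = object$classes)
}

#' Last-layer feature maps of a trace
#'
#' Returns the output of the final convolutional block, an `M x T` matrix of
#' feature maps `A_m(t)` whose temporal length equals the input length; the
#' weighted sum of its rows by the output-layer weights is the class
#' activation map.
#'
#' @param model an [inception_time()] model.
#' @param trace a `channels x time` matrix (one trace).
#' @return numeric matrix `M x T`.
#' @export
feature_maps <- function(model, trace) {
  stopifnot(is.matrix(trace), nrow(trace) == model$n_channels,
            ncol(trace) == model$input_length)
  X <- array(t(trace), c(ncol(trace), nrow(trace), 1L))
  cfg <- model$config
  A <- net_fwd_cpp(model$params, X, cfg$kernel_lengths, cfg$filters,
                   cfg$residual_every, TRUE)$A
  t(A[, , 1L])
}

#' Output-layer coefficients (the CAM weights)
#' @param object an [inception_time()] model.
#' @param ... unused.
#' @return list with `weights` (classes x M matrix) and `bias`.
#' @export
coef.inception_time <- function(object, ...) {
  W <- object$params$Wout
  rownames(W) <- object$classes
  list(weights = W, bias = stats::setNames(object$params$bout,
                                           object$classes))
}

#' @export
print.inception_time <- function(x, ...) {
  cat(sprintf(
    "<inception_time> %d blocks, %d filters/branch (M = %d), kernels {%s}\n",
    x$config$depth, x$config$filters, 4L * x$config$filters,
    paste(x$config$kernel_lengths, collapse = ", ")))
  cat(sprintf("  input: %d channels x %d samples; classes: %s\n",
              x$n_channels, x$input_length, paste(x$classes, collapse = ", ")))
  if (length(x$history))
    cat(sprintf("  trained %d epochs (final loss %.4f)\n",
                length(x$history), utils::tail(x$history, 1L)))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.inception_time <- function(object, ...) {
  n_par <- 0L
  rec <- function(p) for (q in p)
    if (is.list(q)) rec(q) else n_par <<- n_par + length(q)
  rec(object$params)
  print(object)
  cat(sprintf("  %d trainable parameters\n", n_par))
  invisible(object)
}

#' Plot the training-loss history
#' @param x an [inception_time()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.inception_time <- function(x, ...) {
  if (!length(x$history)) stop("model is untrained", call. = FALSE)
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}

#' Train an ensemble of independent fits
#'
#' Fits the same architecture `n_fits` times with independently derived
#' seeds (initialization and batch order both differ) and returns all fits;
#' pick the deployment model with [select_best()].
#'
#' @param train a [labeled_dataset()].
#' @param config a [net_config()]; per-fit seeds are derived from
#'   `config$seed`.
#' @param n_fits number of independent fits (default 5).
#' @return an object of class `inception_ensemble` (list of fits).
#' @export
train_ensemble <- function(train, config = net_config(), n_fits = 5L) {
  stopifnot(length(train) >= 1L, n_fits >= 1L)
  if (length(unique(as.character(train$labels))) < 2L)
    stop("training set holds a single class; cannot fit a classifier",
         call. = FALSE)
  fits <- vector("list", n_fits)
  for (i in seq_len(n_fits)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, 0L, i)
    fits[[i]] <- inception_time(train, config = cfg_i)
  }
  structure(list(fits = fits, config = config), class = "inception_ensemble")
}

#' @export
print.inception_ensemble <- function(x, ...) {
  cat(sprintf("<inception_ensemble> %d fits\n", length(x$fits)))
  invisible(x)
}

#' Select the best model of an ensemble
#'
#' Evaluates every fit on `eval_ds` and returns the one maximizing
#' (accuracy, precision, recall) lexicographically; ties resolve to the
#' lowest fit index.
#'
#' @param models an `inception_ensemble` or list of [inception_time()] fits.
#' @param eval_ds a [labeled_dataset()] to score on.
#' @return the winning model, with attributes `fit_index` and `metrics` (the
#'   per-fit metric table).
#' @export
select_best <- function(models, eval_ds) {
  fits <- if (inherits(models, "inception_ensemble")) models$fits else models
  stopifnot(length(fits) >= 1L)
  mets <- lapply(fits, evaluate, ds = eval_ds)
  key <- vapply(mets, function(m)
    c(m$accuracy, m$precision, m$recall), numeric(3L))
  best <- 1L
  for (i in seq_along(fits)[-1L]) {
    d <- key[, i] - key[, best]
    nz <- which(abs(d) > 0)[1L]
    if (!is.na(nz) && d[nz] > 0) best <- i
  }
  out <- fits[[best]]
  attr(out, "fit_index") <- best
  tab <- do.call(cbind, lapply(mets, function(m)
    c(accuracy = m$accuracy, precision = m$precision, recall = m$recall)))
  colnames(tab) <- sprintf("fit_%d", seq_along(fits))
  attr(out, "metrics") <- tab
  out
}
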