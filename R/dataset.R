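#' Labeled multivariate time-series dataset
#'
#' The common currency of the package: a set of fixed-length multichannel
#' traces, each carrying a class label and optional provenance metadata.
#' Values are stored as a 3D array `channels x time x traces`.
#'
#' @param values numeric array of dimension `c(n_channels, trace_length, n)`.
#' @param labels factor (or coercible) of length `n`; the factor levels define
#'   the label space, which may include classes with zero prevalence.
#' @param ids character vector of trace identifiers; generated when `NULL`.
#' @param channel_names optional character vector, one per channel.
#' @param meta optional list of provenance metadata (generator, config, seed).
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(values, labels, ids = NULL, channel_names = NULL,
                            meta = list()) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array (channels x time x traces)", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  n <- dim(values)[3L]
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(labels) != n)
    stop("length(labels) must equal the number of traces", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("trace_%04d", seq_len(n))
  if (is.null(channel_names))
    channel_names <- sprintf("ch%d", seq_len(dim(values)[1L]))
  structure(
    list(values = values, labels = labels, ids = as.character(ids),
         channel_names = channel_names, meta = meta),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<labeled_dataset> %d traces, %d channels, length %d\n",
              d[3L], d[1L], d[2L]))
  tab <- table(x$labels)
  cat("  classes:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) dim(x$values)[3L]

#' Subset a labeled dataset by trace index
#'
#' @param x a `labeled_dataset`.
#' @param i integer or logical trace indices.
#' @param ... unused.
#' @return a `labeled_dataset` holding the selected traces.
#' @export
`[.labeled_dataset` <- function(x, i, ...) {
  labeled_dataset(x$values[, , i, drop = FALSE],
                  x$labels[i], x$ids[i], x$channel_names, x$meta)
}

#' Number of channels and trace length
#' @param x a `labeled_dataset`.
#' @return integer.
#' @export
n_channels <- function(x) dim(x$values)[1L]

#' @rdname n_channels
#' @export
trace_length <- function(x) dim(x$values)[2L]

#' Combine datasets with identical shape and label space
#' @param ... `labeled_dataset` objects.
#' @return a `labeled_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "labeled_dataset")) parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L)
  d1 <- dim(parts[[1L]]$values)[1:2]
  for (p in parts)
    if (!identical(dim(p$values)[1:2], d1))
      stop("datasets differ in channels or length", call. = FALSE)
  vals <- array(unlist(lapply(parts, function(p) p$values)),
                dim = c(d1, sum(vapply(parts, length, 1L))))
  levs <- unique(unlist(lapply(parts, function(p) levels(p$labels))))
  labs <- factor(unlist(lapply(parts, function(p) as.character(p$labels))),
                 levels = levs)
  labeled_dataset(vals, labs, unlist(lapply(parts, function(p) p$ids)),
                  parts[[1L]]$channel_names, parts[[1L]]$meta)
}

#' Z-normalize each channel of each trace
#'
#' Standardizes every channel of every trace to mean 0 and sample standard
#' deviation 1 (divisor `n - 1`, so the channel `[1, 2, 3]` maps to
#' `[-1, 0, 1]`). A constant channel, whose standard deviation is zero, maps
#' to all zeros.
#'
#' @param x a `labeled_dataset`, or a numeric matrix `channels x time`.
#' @return an object of the same type with standardized channels.
#' @export
z_normalize <- function(x) {
  if (inherits(x, "labeled_dataset")) {
    for (i in seq_len(length(x)))
      x$values[, , i] <- z_normalize(x$values[, , i, drop = TRUE])
    return(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (n - 1))
  out <- (x - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Split a dataset into train and test parts
#'
#' Assignment is uniform at random without stratification; the training part
#' receives `round(train_fraction * n)` traces and the two parts partition the
#' input exactly.
#'
#' @param ds a `labeled_dataset`.
#' @param train_fraction proportion in (0, 1); default 0.7.
#' @param seed integer seed controlling the assignment.
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(ds, train_fraction = 0.7, seed = 1L) {
  if (length(ds) == 0L) stop("cannot split an empty dataset", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  n <- length(ds)
  n_train <- round(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = ds[sort(idx)], test = ds[sort(setdiff(seq_len(n), idx))])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
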