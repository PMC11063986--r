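#' Class activation map of a trace
#'
#' The CAM for class c is the weighted sum of the last-convolution feature
#' maps, `CAM_c(t) = sum_m w_m^c A_m(t)`, where `w^c` are the output-layer
#' weights. Because the network global-average-pools the feature maps into a
#' single linear layer, the time-mean of the unnormalized CAM equals the
#' class logit minus its bias — an exact identity used as a self-check.
#'
#' @param model an [inception_time()] model.
#' @param trace a `channels x time` matrix.
#' @param cls class name (one of `model$classes`).
#' @return an object of class `cam_profile`: list with `values` (length =
#'   trace length), `class`, `normalized` flag and default `threshold`.
#' @export
compute_cam <- function(model, trace, cls) {
  ci <- match(cls, model$classes)
  if (is.na(ci))
    stop(sprintf("unknown class '%s'", cls), call. = FALSE)
  A <- feature_maps(model, trace)
  cam_profile(cam_from_maps(A, model$params$Wout[ci, ]), cls)
}

#' Weighted sum of feature maps
#'
#' The raw CAM arithmetic: given the `M x T` feature maps `A` and the `M`
#' output-layer weights of one class, returns `sum_m w_m A_m(t)`.
#'
#' @param A numeric matrix `M x T` of feature maps.
#' @param w numeric vector of length `M`.
#' @return numeric vector of length `T`.
#' @export
cam_from_maps <- function(A, w) {
  stopifnot(is.matrix(A), length(w) == nrow(A))
  as.numeric(w %*% A)
}

#' Construct a CAM profile
#' @param values numeric relevance series.
#' @param class class label.
#' @param normalized has min-max normalization been applied?
#' @param threshold relevance cutoff used by [relevant_regions()] (0.5).
#' @return object of class `cam_profile`.
#' @export
cam_profile <- function(values, class, normalized = FALSE, threshold = 0.5) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  structure(list(values = as.numeric(values), class = class,
                 normalized = normalized, threshold = threshold),
            class = "cam_profile")
}

#' @export
print.cam_profile <- function(x, ...) {
  cat(sprintf("<cam_profile> class %s, %d samples%s, range [%.3g, %.3g]\n",
              x$class, length(x$values),
              if (x$normalized) " (normalized)" else "",
              min(x$values), max(x$values)))
  invisible(x)
}

# Centered moving mean of window w with shrunken windows at the edges: each
# output point averages only the in-range samples of its window.
moving_mean <- function(x, w = 3L) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + (w - 1L - half))
    mean(x[lo:hi])
  }, numeric(1))
}

#' Average the CAMs of one class and smooth
#'
#' Pointwise mean of the given CAM profiles followed by a centered moving
#' mean of window 3 (shrunken windows at the edges, so the length is
#' preserved without padding artifacts).
#'
#' @param cams nonempty list of `cam_profile`s of a single class, equal
#'   lengths.
#' @param window moving-mean window in samples (default 3).
#' @return a `cam_profile` (unnormalized).
#' @export
average_class_cams <- function(cams, window = 3L) {
  stopifnot(length(cams) >= 1L)
  cls <- unique(vapply(cams, function(x) x$class, ""))
  if (length(cls) != 1L)
    stop("cannot average CAMs of mixed classes", call. = FALSE)
  lens <- unique(vapply(cams, function(x) length(x$values), 1L))
  if (length(lens) != 1L)
    stop("CAM lengths differ", call. = FALSE)
  avg <- rowMeans(vapply(cams, function(x) x$values, numeric(lens)))
  cam_profile(moving_mean(avg, window), cls)
}

#' Min-max normalize a CAM to [0, 1]
#'
#' After normalization the relevance threshold of [relevant_regions()] is
#' scale-free across classes. A constant CAM carries no localization
#' information: it maps to all zeros and the `degenerate` flag is set (with
#' a warning).
#'
#' @param cam a `cam_profile`.
#' @return a normalized `cam_profile` (idempotent on already-normalized
#'   profiles spanning [0, 1]).
#' @export
normalize_cam <- function(cam) {
  v <- cam$values
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant CAM: normalization is degenerate, returning zeros",
            call. = FALSE)
    out <- cam_profile(rep(0, length(v)), cam$class, normalized = TRUE,
                       threshold = cam$threshold)
    out$degenerate <- TRUE
    return(out)
  }
  cam_profile((v - rng[1L]) / diff(rng), cam$class, normalized = TRUE,
              threshold = cam$threshold)
}

#' Maximal above-threshold runs of a normalized CAM
#'
#' Finds the maximal runs of consecutive samples whose relevance is at or
#' above the threshold, reported as half-open 0-based index intervals
#' `[start, end)` — the convention of the exported time indices, which start
#' at 0.
#'
#' @param cam a normalized `cam_profile`.
#' @param threshold relevance cutoff (defaults to `cam$threshold`, 0.5).
#' @return data.frame with columns `start`, `end`, `peak_value`; zero rows
#'   when nothing exceeds the threshold.
#' @export
relevant_regions <- function(cam, threshold = cam$threshold) {
  if (!isTRUE(cam$normalized))
    stop("relevant_regions expects a normalized CAM; call normalize_cam()",
         call. = FALSE)
  above <- cam$values >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = starts[keep] - 1L, end = ends[keep],
                    peak_value = vapply(keep, function(k)
                      max(cam$values[starts[k]:ends[k]]), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Mean CAM relevance inside named regions
#'
#' @param cam a `cam_profile`.
#' @param regions named list of half-open 0-based index windows
#'   `c(start, end)`, e.g. `list(R1 = c(0, 100), R2 = c(100, 200), R3 =
#'   c(200, 300))`. Overlaps are allowed; out-of-range windows are an error.
#' @return named numeric vector of per-region means.
#' @export
region_relevance <- function(cam, regions) {
  n <- length(cam$values)
  vapply(regions, function(w) {
    if (w[1L] < 0 || w[2L] > n || w[1L] >= w[2L])
      stop(sprintf("region [%d, %d) out of range for length %d",
                   w[1L], w[2L], n), call. = FALSE)
    mean(cam$values[(w[1L] + 1L):w[2L]])
  }, numeric(1))
}

#' Class-averaged CAMs over a dataset
#'
#' Computes, for every class present in `ds`, the CAM of each trace of that
#' class (with respect to its true class by default), then averages, smooths
#' and min-max normalizes per class.
#'
#' @param model an [inception_time()] model.
#' @param ds a [labeled_dataset()].
#' @param use_predicted average traces by predicted instead of true class.
#' @param normalize apply [normalize_cam()] per class (default `TRUE`).
#' @return named list of `cam_profile`s, one per class with support.
#' @export
class_average_cams <- function(model, ds, use_predicted = FALSE,
                               normalize = TRUE) {
  groups <- if (use_predicted) predict(model, ds) else ds$labels
  out <- list()
  for (cl in levels(groups)) {
    idx <- which(groups == cl)
    if (!length(idx)) next
    cams <- lapply(idx, function(i)
      compute_cam(model, ds$values[, , i, drop = TRUE], cl))
    avg <- average_class_cams(cams)
    out[[cl]] <- if (normalize) normalize_cam(avg) else avg
  }
  out
}

#' Plot a CAM with its relevance threshold
#' @param x a `cam_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cam_profile <- function(x, ...) {
  graphics::plot(seq_along(x$values) - 1L, x$values, type = "l",
                 xlab = "time index", ylab = "relevance",
                 main = sprintf("CAM, class %s", x$class), ...)
  if (isTRUE(x$normalized))
    graphics::abline(h = x$threshold, lty = 3, col = "darkblue")
  invisible(x)
}
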