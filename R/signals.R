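#' Configuration of the waveform benchmark
#'
#' The benchmark generates traces whose three temporal regions R1/R2/R3 are a
#' constant baseline except for R2, which carries one of three waveforms
#' (sine, square, sawtooth). Because class information is confined to R2, a
#' class activation map of a well-trained classifier should peak there.
#'
#' @param n_traces number of traces (default 500).
#' @param n_channels channels per trace (default 3); each channel draws its
#'   own frequency, amplitude and phase of the same class waveform.
#' @param trace_length samples per channel (default 300).
#' @param region_bounds two sample indices (0-based, half-open) splitting the
#'   trace into R1 = `[0, b1)`, R2 = `[b1, b2)`, R3 = `[b2, length)`.
#' @param freq_range frequency interval in Hz, drawn on a grid of step
#'   `grid_step` (default `[0.5, 5]`).
#' @param amp_range amplitude interval, same grid convention (default `[1, 100]`).
#' @param grid_step grid resolution of frequency and amplitude draws (0.1).
#' @param noise_sd standard deviation of optional additive Gaussian noise on
#'   the raw trace (default 0, i.e. noiseless flanks).
#' @param sample_rate sampling rate in Hz used to map sample index to time
#'   (default 100, so a 300-sample trace spans 3 s).
#' @param seed master seed for dataset generation.
#' @return a list of class `signal_config`.
#' @export
signal_config <- function(n_traces = 500L, n_channels = 3L,
                          trace_length = 300L, region_bounds = c(100L, 200L),
                          freq_range = c(0.5, 5), amp_range = c(1, 100),
                          grid_step = 0.1, noise_sd = 0, sample_rate = 100,
                          seed = 1L) {
  cfg <- list(n_traces = as.integer(n_traces),
              n_channels = as.integer(n_channels),
              trace_length = as.integer(trace_length),
              region_bounds = as.integer(region_bounds),
              freq_range = freq_range, amp_range = amp_range,
              grid_step = grid_step, noise_sd = noise_sd,
              sample_rate = sample_rate, seed = as.integer(seed))
  if (!(cfg$region_bounds[1L] > 0L &&
        cfg$region_bounds[1L] < cfg$region_bounds[2L] &&
        cfg$region_bounds[2L] < cfg$trace_length))
    stop("region_bounds must satisfy 0 < b1 < b2 < trace_length", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "signal_config")
}

#' @export
waveform_classes <- function() c("sine", "square", "sawtooth")

# Draw a value from [lo, hi] restricted to the grid lo, lo+step, ..., hi.
draw_on_grid <- function(range, step) {
  n_levels <- floor(round((range[2L] - range[1L]) / step, 9)) + 1L
  range[1L] + (sample.int(n_levels, 1L) - 1L) * step
}

# Waveform value at time t (seconds) for unit amplitude.
waveform_value <- function(cls, f, phase, t) {
  u <- f * t + phase / (2 * pi)
  switch(cls,
         sine = sin(2 * pi * u),
         square = ifelse(sin(2 * pi * u) >= 0, 1, -1),
         sawtooth = 2 * (u %% 1) - 1,
         stop(sprintf("unknown waveform class '%s'", cls), call. = FALSE))
}

#' Generate one benchmark trace
#'
#' Draws, for each channel, a frequency and an amplitude on the configured
#' grids and a phase uniform in `[0, 2*pi)`, then writes the class waveform
#' into region R2 only; R1 and R3 stay at a constant zero baseline (plus
#' optional Gaussian noise). Consumes the current RNG stream.
#'
#' @param cls one of `"sine"`, `"square"`, `"sawtooth"`.
#' @param cfg a [signal_config()].
#' @return numeric matrix `n_channels x trace_length` of raw (un-normalized)
#'   values, with attributes `freq`, `amp`, `phase` (one per channel).
#' @export
generate_trace <- function(cls, cfg) {
  if (!cls %in% waveform_classes())
    stop(sprintf("unknown waveform class '%s'", cls), call. = FALSE)
  T_ <- cfg$trace_length
  b <- cfg$region_bounds
  x <- matrix(0, nrow = cfg$n_channels, ncol = T_)
  freq <- amp <- phase <- numeric(cfg$n_channels)
  idx_r2 <- (b[1L] + 1L):b[2L]                 # 1-based columns of [b1, b2)
  t_r2 <- (idx_r2 - 1L - b[1L]) / cfg$sample_rate
  for (c in seq_len(cfg$n_channels)) {
    freq[c] <- draw_on_grid(cfg$freq_range, cfg$grid_step)
    amp[c] <- draw_on_grid(cfg$amp_range, cfg$grid_step)
    phase[c] <- stats::runif(1, 0, 2 * pi)
    x[c, idx_r2] <- amp[c] * waveform_value(cls, freq[c], phase[c], t_r2)
  }
  if (cfg$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, cfg$noise_sd), nrow = nrow(x))
  attr(x, "freq") <- freq; attr(x, "amp") <- amp; attr(x, "phase") <- phase
  x
}

#' Generate the sine/square/sawtooth benchmark dataset
#'
#' Classes are as balanced as possible (counts differ by at most one, with the
#' remainder going to the first classes in enum order: sine, square,
#' sawtooth). Deterministic under `cfg$seed`. Traces are returned raw; apply
#' [z_normalize()] before training, as the classification pipeline does.
#'
#' @param cfg a [signal_config()].
#' @return a [labeled_dataset()] with `cfg$n_traces` traces.
#' @export
generate_signals_dataset <- function(cfg = signal_config()) {
  stopifnot(cfg$n_traces >= 3L)
  classes <- waveform_classes()
  base <- cfg$n_traces %/% 3L
  extra <- cfg$n_traces %% 3L
  counts <- base + as.integer(seq_along(classes) <= extra)
  labels <- rep(classes, counts)
  vals <- array(0, dim = c(cfg$n_channels, cfg$trace_length, cfg$n_traces))
  with_seed(cfg$seed, {
    for (i in seq_along(labels))
      vals[, , i] <- generate_trace(labels[i], cfg)
  })
  labeled_dataset(vals, factor(labels, levels = classes),
                  meta = list(generator = "signals_benchmark",
                              config = unclass(cfg), seed = cfg$seed))
}
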