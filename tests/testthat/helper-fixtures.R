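# Small shared fixtures: tiny network configurations and datasets that keep
# unit tests fast while exercising every architectural feature.

merged_call <- function(fn, defaults, overrides) {
  do.call(fn, utils::modifyList(defaults, overrides))
}

tiny_net <- function(...) {
  merged_call(net_config, list(
    depth = 1L, filters = 2L, kernel_lengths = c(2L, 3L, 5L),
    bottleneck = 2L, residual_every = 3L, epochs = 0L, batch_size = 8L,
    seed = 11L), list(...))
}

# depth 3 with residual_every 3 so the shortcut path is exercised
residual_net <- function(...) {
  merged_call(net_config, list(
    depth = 3L, filters = 2L, kernel_lengths = c(2L, 3L, 5L),
    bottleneck = 2L, residual_every = 3L, epochs = 0L, batch_size = 8L,
    seed = 13L), list(...))
}

random_dataset <- function(n = 12L, channels = 2L, len = 30L, seed = 5L,
                           classes = c("a", "b")) {
  set.seed(seed)
  vals <- array(rnorm(channels * len * n), c(channels, len, n))
  labeled_dataset(vals, factor(rep_len(classes, n), levels = classes))
}

# linearly separable toy: constant-level traces, one level per class
separable_dataset <- function(n_per_class = 10L, channels = 2L, len = 30L,
                              seed = 9L) {
  set.seed(seed)
  n <- 2L * n_per_class
  vals <- array(0, c(channels, len, n))
  vals[, , seq_len(n_per_class)] <- 0 +
    rnorm(channels * len * n_per_class, sd = 0.05)
  vals[, , n_per_class + seq_len(n_per_class)] <- 1 +
    rnorm(channels * len * n_per_class, sd = 0.05)
  labeled_dataset(vals, factor(rep(c("lo", "hi"), each = n_per_class),
                               levels = c("lo", "hi")))
}

# a quick simulator parameterization: coarse grid, short run
quick_sim <- function(...) {
  merged_call(sim_params, list(
    grid_shape = c(12L, 12L, 12L), duration = 24, initial_cells = 80L,
    seed = 21L), list(...))
}
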