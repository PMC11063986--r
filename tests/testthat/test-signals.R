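test_that("waveforms occupy R2 only, on the stated parameter grids", {
  cfg <- signal_config(n_channels = 3L, noise_sd = 0, seed = 1L)
  b <- cfg$region_bounds
  set.seed(42)
  for (cls in waveform_classes()) {
    x <- generate_trace(cls, cfg)
    # flanks are an exact constant-zero baseline
    expect_identical(unname(x[, c(seq_len(b[1L]), (b[2L] + 1L):cfg$trace_length)]),
                     matrix(0, nrow = 3L,
                            ncol = cfg$trace_length - (b[2L] - b[1L])))
    f <- attr(x, "freq"); a <- attr(x, "amp")
    expect_true(all(f >= 0.5 & f <= 5))
    expect_true(all(abs((f - 0.5) / 0.1 - round((f - 0.5) / 0.1)) < 1e-9))
    expect_true(all(a >= 1 & a <= 100))
    expect_true(all(abs((a - 1) / 0.1 - round((a - 1) / 0.1)) < 1e-9))
  }
  expect_error(generate_trace("triangle", cfg), "unknown waveform")
})

test_that("a noiseless square wave takes exactly the values +/- amplitude", {
  cfg <- signal_config(seed = 2L)
  b <- cfg$region_bounds
  set.seed(7)
  for (i in 1:20) {
    x <- generate_trace("square", cfg)
    a <- attr(x, "amp")
    for (c in 1:3) {
      vals <- unique(x[c, (b[1L] + 1L):b[2L]])
      expect_true(all(vals %in% c(-a[c], a[c])))
    }
  }
})

test_that("dataset has balanced classes and is seed-deterministic", {
  ds <- generate_signals_dataset(signal_config(seed = 3L))
  expect_equal(length(ds), 500L)
  expect_equal(n_channels(ds), 3L)
  expect_equal(as.integer(table(ds$labels)),
               c(167L, 167L, 166L))  # sine, square, sawtooth
  expect_identical(levels(ds$labels), c("sine", "square", "sawtooth"))

  ds2 <- generate_signals_dataset(signal_config(seed = 3L))
  expect_identical(ds$values, ds2$values)
  expect_identical(ds$labels, ds2$labels)

  ds3 <- generate_signals_dataset(signal_config(n_traces = 3L, seed = 4L))
  expect_equal(as.integer(table(ds3$labels)), c(1L, 1L, 1L))
})

test_that("z-normalization follows the sample-sd convention and is idempotent", {
  expect_equal(as.numeric(z_normalize(matrix(c(1, 2, 3), 1L))), c(-1, 0, 1))
  expect_equal(as.numeric(z_normalize(matrix(c(5, 5, 5), 1L))), c(0, 0, 0))

  set.seed(8)
  x <- matrix(rnorm(60, mean = 3, sd = 7), nrow = 2L)
  z <- z_normalize(x)
  expect_equal(rowMeans(z), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(z, 1L, sd), c(1, 1), tolerance = 1e-9)
  expect_equal(z_normalize(z), z, tolerance = 1e-9)
})

test_that("train/test split partitions the data with the requested sizes", {
  ds <- generate_signals_dataset(signal_config(seed = 5L))
  sp <- split_train_test(ds, 0.7, seed = 1L)
  expect_equal(length(sp$train), 350L)
  expect_equal(length(sp$test), 150L)
  expect_setequal(c(sp$train$ids, sp$test$ids), ds$ids)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0L)

  sp2 <- split_train_test(ds, 0.7, seed = 1L)
  expect_identical(sp$train$ids, sp2$train$ids)
  sp3 <- split_train_test(ds, 0.7, seed = 2L)
  expect_false(identical(sp$train$ids, sp3$train$ids))

  tiny <- ds[1:2]
  sp4 <- split_train_test(tiny, 0.5, seed = 1L)
  expect_equal(length(sp4$train), 1L)
  expect_equal(length(sp4$test), 1L)
  expect_error(split_train_test(ds[integer(0)], 0.7), "empty")
  expect_error(split_train_test(ds, 1.2), "between 0 and 1")
})

test_that("class information is confined to R2", {
  # with zero noise, R1/R3 are class-independent constants: once normalized,
  # any discriminative signal must live in R2
  cfg <- signal_config(n_traces = 9L, seed = 6L)
  ds <- generate_signals_dataset(cfg)
  b <- cfg$region_bounds
  flank <- ds$values[, c(seq_len(b[1L]), (b[2L] + 1L):cfg$trace_length), ]
  expect_true(all(flank == 0))
})
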