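test_that("the CAM is the weighted sum of feature maps", {
  # hand-built stub: A_1 = [1, 2], A_2 = [3, 4], w = (0.5, -1)
  A <- rbind(c(1, 2), c(3, 4))
  expect_equal(cam_from_maps(A, c(0.5, -1)), c(-2.5, -3))
  # linearity in the feature maps
  set.seed(12)
  A2 <- matrix(rnorm(8), 2)
  B <- matrix(rnorm(8), 2)
  w <- rnorm(2)
  expect_equal(cam_from_maps(A2 + B, w),
               cam_from_maps(A2, w) + cam_from_maps(B, w), tolerance = 1e-12)

  # zero output weights give an identically zero CAM on a real model
  ds <- random_dataset(n = 4L, len = 24L)
  m <- inception_time(ds, config = tiny_net())
  m$params$Wout["a" == m$classes, ] <- 0
  cam <- compute_cam(m, ds$values[, , 1L], "a")
  expect_equal(cam$values, rep(0, 24L))
  expect_length(compute_cam(m, ds$values[, , 2L], "b")$values, 24L)
  expect_error(compute_cam(m, ds$values[, , 1L], "zebra"), "unknown class")
})

test_that("class averaging smooths with shrunken edge windows", {
  c1 <- cam_profile(c(2, 2, 2, 2), "a")
  expect_equal(average_class_cams(list(c1))$values, c(2, 2, 2, 2))

  c2 <- cam_profile(c(0, 3, 0), "a")
  expect_equal(average_class_cams(list(c2))$values, c(1.5, 1, 1.5))

  # average-then-smooth equals elementwise mean before smoothing
  set.seed(5)
  a <- cam_profile(rnorm(20), "a")
  b <- cam_profile(rnorm(20), "a")
  avg <- average_class_cams(list(a, b))
  expect_equal(avg$values,
               camsched:::moving_mean((a$values + b$values) / 2, 3L),
               tolerance = 1e-12)
  expect_error(average_class_cams(list(a, cam_profile(rnorm(20), "b"))),
               "mixed classes")

  # smoothing never extends the value range
  x <- rnorm(50)
  sm <- camsched:::moving_mean(x, 3L)
  expect_true(all(sm >= min(x) - 1e-12 & sm <= max(x) + 1e-12))
})

test_that("min-max normalization and its degenerate case", {
  n <- normalize_cam(cam_profile(c(-2, 0, 2), "a"))
  expect_equal(n$values, c(0, 0.5, 1))
  expect_true(n$normalized)
  expect_equal(normalize_cam(n)$values, n$values)  # idempotent on [0, 1]

  expect_warning(d <- normalize_cam(cam_profile(c(7, 7), "a")), "constant")
  expect_equal(d$values, c(0, 0))
  expect_true(d$degenerate)
})

test_that("relevant regions are the maximal above-threshold runs", {
  cam <- cam_profile(c(0, 0.6, 0.7, 0.2, 0.9), "a", normalized = TRUE)
  rr <- relevant_regions(cam, 0.5)
  expect_equal(rr$start, c(1L, 4L))
  expect_equal(rr$end, c(3L, 5L))
  expect_equal(rr$peak_value, c(0.7, 0.9))

  low <- cam_profile(rep(0.1, 6), "a", normalized = TRUE)
  expect_equal(nrow(relevant_regions(low, 0.5)), 0L)
  high <- cam_profile(rep(0.9, 6), "a", normalized = TRUE)
  rh <- relevant_regions(high, 0.5)
  expect_equal(c(rh$start, rh$end), c(0L, 6L))

  expect_error(relevant_regions(cam_profile(1:3, "a")), "normalized")

  # partition property: the union of regions recovers the threshold set
  set.seed(99)
  for (i in 1:20) {
    v <- runif(40)
    cp <- cam_profile(v, "a", normalized = TRUE)
    rr <- relevant_regions(cp, 0.5)
    covered <- unlist(lapply(seq_len(nrow(rr)), function(k)
      (rr$start[k] + 1L):rr$end[k]))
    expect_setequal(covered, which(v >= 0.5))
    if (nrow(rr) > 1L)  # maximality: runs are separated by gaps
      expect_true(all(rr$start[-1L] > rr$end[-nrow(rr)]))
  }
})

test_that("region relevance averages named windows", {
  v <- c(rep(0, 10), rep(1, 10), rep(0, 10))
  cam <- cam_profile(v, "a")
  wins <- list(R1 = c(0, 10), R2 = c(10, 20), R3 = c(20, 30))
  expect_equal(region_relevance(cam, wins), c(R1 = 0, R2 = 1, R3 = 0))
  u <- cam_profile(rep(0.4, 30), "a")
  expect_equal(unname(region_relevance(u, wins)), rep(0.4, 3))
  expect_error(region_relevance(cam, list(R1 = c(20, 40))), "out of range")
})
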