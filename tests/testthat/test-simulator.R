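test_that("explicit diffusion matches the hand-evaluated stencil", {
  # uniform field: zero Laplacian
  u <- array(3.7, c(4, 4, 4))
  expect_equal(diffuse(u, 0.2, 0.5), u)

  # two-cell lattice [1, 0]: u1' = 1 - D*dt, u2' = D*dt
  v <- array(c(1, 0), c(2, 1, 1))
  out <- diffuse(v, 0.25, 0.5)
  expect_equal(as.numeric(out), c(1 - 0.125, 0.125))

  # fixed-concentration faces clamp after the step
  w <- diffuse(array(0, c(3, 3, 3)), 0.1, 0.5, fixed_value = 1)
  expect_equal(w[2, 2, 2], 0)
  expect_true(all(w[1, , ] == 1))

  expect_error(diffuse(u, 1, 0.5), "stability bound")
})

test_that("diffusion conserves mass under reflecting boundaries", {
  set.seed(17)
  u <- array(runif(5 * 5 * 5), c(5, 5, 5))
  total <- sum(u)
  for (i in 1:100) u <- diffuse(u, 0.3, 0.5)
  expect_lt(abs(sum(u) - total) / total, 1e-9)

  # point mass on a 3x3x3 lattice
  p <- array(0, c(3, 3, 3)); p[2, 2, 2] <- 1
  p1 <- diffuse(p, 0.2, 0.5)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
})

test_that("death probability follows the Hill model and its monotonicities", {
  p <- sim_params()
  base <- p$death_prob_base
  expect_identical(death_probability(0, FALSE, 0, p), base)
  expect_identical(death_probability(0, TRUE, 50, p), base)

  # sigmoid midpoint at the configured EC50s (zero exposure)
  expect_equal(death_probability(p$dox_ec50_sensitive, FALSE, 0, p),
               base + (1 - base) / 2, tolerance = 1e-9)
  expect_equal(death_probability(p$dox_ec50_resistant, TRUE, 0, p),
               base + (1 - base) / 2, tolerance = 1e-9)

  # non-decreasing in dose, and in exposure for resistant cells
  doses <- seq(0, 2, by = 0.05)
  expect_false(is.unsorted(death_probability(doses, FALSE, 0, p)))
  exposures <- seq(0, 400, by = 5)
  for (d in c(0.1, 0.3, 1)) {
    pr <- death_probability(rep(d, length(exposures)), TRUE, exposures, p)
    expect_false(is.unsorted(pr))
    # resistant EC50 >= sensitive EC50 at every exposure level
    ps <- death_probability(rep(d, length(exposures)), FALSE, exposures, p)
    expect_true(all(pr <= ps + 1e-12))
  }
})

test_that("simulation sampling contract and determinism hold", {
  p <- sim_params(seed = 4L)
  ts <- run_simulation(p, make_schedule("T1", 0.15, 2))
  expect_equal(ncol(ts$series), 73L)
  expect_equal(nrow(ts$series), 5L)
  expect_equal(ts$time, 0:72)

  ts2 <- run_simulation(p, make_schedule("T1", 0.15, 2))
  expect_identical(ts$series, ts2$series)

  # dead cells never decrease; bookkeeping identity at every sample
  dead <- ts$series["dead_cells", ]
  expect_false(is.unsorted(dead))
  expect_equal(ts$series["living_cells", ] + ts$conservation["cum_deaths", ],
               p$initial_cells + ts$conservation["cum_divisions", ])
  # stiffness only accumulates
  expect_false(is.unsorted(ts$series["mean_youngs_modulus", ]))
})

test_that("edge regimes behave: empty culture and division-free decay", {
  p0 <- quick_sim(initial_cells = 0L)
  ts <- run_simulation(p0, make_schedule("T1", 0.3, 5))
  expect_true(all(ts$series["living_cells", ] == 0))
  expect_true(all(ts$series["dead_cells", ] == 0))

  pd <- quick_sim(division_prob_base = 0, growth_variability = 0)
  tsd <- run_simulation(pd, make_schedule("T1", 0, 0))
  expect_false(is.unsorted(-tsd$series["living_cells", ]))
  expect_false(is.unsorted(tsd$series["dead_cells", ]))
})

test_that("a single cell's lineage replays the branching RNG stream", {
  g <- c(9L, 9L, 9L)
  p <- sim_params(grid_shape = g, dt = 0.5, duration = 5, sample_every = 0.5,
                  initial_cells = 1L, death_prob_base = 0,
                  division_prob_base = 0.5,
                  division_sat_k = c(oxygen = 0, glucose = 0),
                  oxygen_consumption = 0, glucose_consumption = 0,
                  survival_oxygen = 0, survival_glucose = 0,
                  hypoxia_switch_prob = 0, growth_variability = 0, seed = 99L)
  ts <- run_simulation(p, make_schedule("T1", 0, 0))

  # independent replay: same RNG stream, geometry rebuilt from scratch
  idx0 <- seq_len(prod(g)) - 1L
  cx <- idx0 %% g[1]; cy <- (idx0 %/% g[1]) %% g[2]; cz <- idx0 %/% (g[1] * g[2])
  ctr <- (g - 1) / 2
  ball <- which((cx - ctr[1])^2 + (cy - ctr[2])^2 + (cz - ctr[3])^2 <= 4)
  # neighbour list in the order -x,+x,-y,+y,-z,+z
  neighbors_of <- function(v) {
    i <- v - 1L
    x <- i %% g[1]; y <- (i %/% g[1]) %% g[2]; z <- i %/% (g[1] * g[2])
    nb <- c(if (x > 0) v - 1L else NA, if (x < g[1] - 1) v + 1L else NA,
            if (y > 0) v - g[1] else NA, if (y < g[2] - 1) v + g[1] else NA,
            if (z > 0) v - g[1] * g[2] else NA,
            if (z < g[3] - 1) v + g[1] * g[2] else NA)
    nb[!is.na(nb)]
  }
  set.seed(99L)
  occ <- logical(prod(g))
  occ[sample(ball, 1L)] <- TRUE
  for (step in 1:10) {
    alive <- which(occ)
    runif(length(alive))                       # death draws (p = 0)
    u <- runif(length(alive))
    for (v in alive[u < 0.5]) {
      nb <- neighbors_of(v)
      free <- nb[!occ[nb]]
      if (length(free)) {
        d <- if (length(free) == 1L) free else sample(free, 1L)
        occ[d] <- TRUE
      }
    }
  }
  expect_equal(unname(ts$series["living_cells", 11L]), sum(occ))
})

test_that("population-level dose response is monotone for sensitive cultures", {
  doses <- c(0, 0.03, 0.15, 0.3)
  finals <- sapply(doses, function(d) {
    mean(sapply(1:20, function(r) {
      p <- sim_params(seed = 3000L + 17L * r, resistant_fraction = 0)
      run_simulation(p, make_schedule("T1", d, 0))$series["living_cells", 73]
    }))
  })
  expect_false(is.unsorted(rev(finals)))
  # growth regime sanity: untreated cultures grow
  expect_gt(finals[1], 500)
})

test_that("the factorial design enumerates the full study and labels runs", {
  des <- factorial_design(replicates = 50L)
  expect_equal(nrow(des), 1800L)
  expect_equal(length(unique(des$condition)), 36L)
  expect_true(all(des$seed >= 0 & des$seed < 2^31))
  expect_equal(nrow(factorial_design(replicates = 1L)), 36L)

  small <- factorial_design(replicates = 1L, master_seed = 5L)
  ds <- generate_factorial_dataset(quick_sim(), small)
  expect_equal(length(ds), 36L)
  expect_equal(n_channels(ds), 5L)
  expect_true(all(as.character(ds$labels) %in% outcome_classes()))
  expect_identical(levels(ds$labels), outcome_classes())
  # exported traces are z-normalized per channel (constant channels -> 0)
  m <- ds$values[, , 1L]
  expect_true(all(abs(rowMeans(m)) < 1e-9))
})
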