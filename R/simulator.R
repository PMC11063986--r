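#' Parameters of the lattice culture simulator
#'
#' A hybrid discrete/continuous cellular automaton of a 3D cancer-cell
#' culture: cells live on a cubic lattice (at most one cell per voxel) and
#' continuous fields for oxygen, glucose, doxorubicin, BAPN and matrix
#' stiffness evolve around them. Nutrients diffuse from fixed-concentration
#' boundary faces and are consumed by living cells; drugs are administered as
#' instantaneous uniform increments and diffuse under reflecting boundaries.
#' Doxorubicin drives a sigmoid (Hill) kill probability and is taken up by
#' living cells, so its availability is transient. Hypoxic sensitive cells can
#' switch to a LOX-mediated resistant phenotype with an elevated EC50; BAPN
#' (a LOX inhibitor, non-cytotoxic by itself) lowers that EC50 back toward
#' the sensitive value as a monotone function of cumulative exposure, and
#' slows stiffness deposition.
#'
#' Probabilities marked "per step" refer to one `dt` step.
#'
#' @param grid_shape lattice dimensions (default `c(20, 20, 20)`).
#' @param dt time step in hours (default 0.5).
#' @param duration simulated time in hours (default 72); must be a multiple
#'   of `sample_every`.
#' @param sample_every sampling interval of the output series in hours (1).
#' @param initial_cells number of cells seeded in a central ball (500).
#' @param resistant_fraction proportion of seeded cells that start resistant.
#' @param diffusion named diffusion coefficients (lattice units^2/h) for
#'   `oxygen`, `glucose`, `doxorubicin`, `bapn`.
#' @param boundary_conc fixed-edge replenishment concentrations for `oxygen`
#'   and `glucose` (normalized units).
#' @param oxygen_consumption,glucose_consumption amount removed per living
#'   cell per hour from the cell's voxel.
#' @param dox_uptake_rate fractional doxorubicin removal per hour in voxels
#'   holding a living cell (cellular uptake/sequestration).
#' @param division_prob_base maximal per-step division probability, scaled
#'   down by local oxygen and glucose saturation.
#' @param division_sat_k half-saturation constants of the division scaling.
#' @param death_prob_base baseline per-step death probability.
#' @param dox_ec50_sensitive,dox_ec50_resistant Hill EC50 (ug/ml) of the
#'   per-step kill probability for sensitive and resistant cells.
#' @param hill_k Hill exponent of the kill sigmoid.
#' @param bapn_resens_e50 cumulative BAPN exposure (mM h) at which the
#'   resistant EC50 is halfway back to the sensitive one.
#' @param bapn_resens_hill Hill exponent of the resensitization curve.
#' @param bapn_penetration_e50,bapn_penetration_hill cumulative-exposure
#'   scale (mM h) and Hill exponent of the penetration improvement; slower
#'   than resensitization, since it requires bulk ECM turnover.
#' @param bapn_penetration_floor fraction of the sensitive EC50 left at
#'   saturating BAPN exposure (matrix softening improves penetration).
#' @param hypoxia_threshold oxygen level below which sensitive cells may
#'   switch to the resistant phenotype.
#' @param hypoxia_switch_prob per-step probability of that switch.
#' @param survival_oxygen,survival_glucose starvation thresholds.
#' @param starvation_death_prob per-step death probability while starving.
#' @param stiffness_baseline initial matrix Young's modulus (kPa).
#' @param stiffness_remodel_rate stiffness deposited per living cell per hour
#'   (kPa), attenuated by BAPN (LOX inhibition).
#' @param bapn_lox_k BAPN concentration (mM) halving stiffness deposition.
#' @param growth_variability log-scale standard deviation of a per-run
#'   multiplier on `division_prob_base`, emulating replicate-to-replicate
#'   differences in proliferative capacity (default 0.15; 0 disables).
#' @param seed integer seed for the run.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(grid_shape = c(20L, 20L, 20L), dt = 0.5, duration = 72,
                       sample_every = 1, initial_cells = 500L,
                       resistant_fraction = 0,
                       diffusion = c(oxygen = 0.3, glucose = 0.3,
                                     doxorubicin = 0.3, bapn = 0.3),
                       boundary_conc = c(oxygen = 1, glucose = 1),
                       oxygen_consumption = 0.045, glucose_consumption = 0.02,
                       dox_uptake_rate = 0.65,
                       division_prob_base = 0.011,
                       division_sat_k = c(oxygen = 0.15, glucose = 0.15),
                       death_prob_base = 0.002,
                       dox_ec50_sensitive = 2.3, dox_ec50_resistant = 25,
                       hill_k = 1.5,
                       bapn_resens_e50 = 68, bapn_resens_hill = 8,
                       bapn_penetration_e50 = 95, bapn_penetration_hill = 2,
                       bapn_penetration_floor = 0.3,
                       hypoxia_threshold = 0.3, hypoxia_switch_prob = 0.05,
                       survival_oxygen = 0.02, survival_glucose = 0.02,
                       starvation_death_prob = 0.3,
                       stiffness_baseline = 0.3,
                       stiffness_remodel_rate = 0.01, bapn_lox_k = 1,
                       growth_variability = 0.15,
                       seed = 1L) {
  p <- as.list(environment())
  p$grid_shape <- as.integer(grid_shape)
  p$seed <- as.integer(seed)
  if (p$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (abs(p$duration / p$sample_every -
          round(p$duration / p$sample_every)) > 1e-9)
    stop("duration must be a multiple of sample_every", call. = FALSE)
  if (abs(p$sample_every / p$dt - round(p$sample_every / p$dt)) > 1e-9)
    stop("sample_every must be a multiple of dt", call. = FALSE)
  if (!(p$resistant_fraction >= 0 && p$resistant_fraction <= 1))
    stop("resistant_fraction must lie in [0, 1]", call. = FALSE)
  rates <- c(p$diffusion, p$oxygen_consumption, p$glucose_consumption,
             p$dox_uptake_rate, p$stiffness_remodel_rate)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  structure(p, class = "sim_params")
}

#' One explicit diffusion step on a 3D lattice
#'
#' Explicit finite-difference step of the heat equation with the 6-neighbour
#' stencil and unit lattice spacing. Boundaries are reflecting (zero-flux), so
#' total mass is conserved; optionally, all six faces are then clamped to a
#' fixed concentration, modeling replenishment from the surrounding medium.
#'
#' The explicit scheme is stable only for `D * dt <= 1/6` (in lattice units,
#' three dimensions); violating the bound is an error, not a warning.
#'
#' @param field 3D numeric array of concentrations.
#' @param D diffusion coefficient (lattice units^2 / h).
#' @param dt time step (h).
#' @param fixed_value if non-`NULL`, the boundary faces are set to this value
#'   after the step.
#' @return the updated field.
#' @export
diffuse <- function(field, D, dt, fixed_value = NULL) {
  stopifnot(length(dim(field)) == 3L)
  if (D * dt > 1 / 6 + 1e-12)
    stop(sprintf(
      "explicit diffusion unstable: D*dt = %.4g exceeds the stability bound 1/6 (3D, unit spacing)",
      D * dt), call. = FALSE)
  out <- diffuse_step_cpp(field, D, dt)
  out <- array(out, dim = dim(field))
  if (!is.null(fixed_value)) {
    d <- dim(out)
    out[c(1L, d[1L]), , ] <- fixed_value
    out[, c(1L, d[2L]), ] <- fixed_value
    out[, , c(1L, d[3L])] <- fixed_value
  }
  out
}

# EC50 reduction factors in (0, 1]: 1 at zero exposure, decreasing in E.
resens_factor <- function(E, p) {
  1 / (1 + (E / p$bapn_resens_e50)^p$bapn_resens_hill)
}

penetration_factor <- function(E, p) {
  1 / (1 + (E / p$bapn_penetration_e50)^p$bapn_penetration_hill)
}

#' Per-step death probability under doxorubicin
#'
#' `baseline + (1 - baseline) * dox^h / (dox^h + EC50^h)`. Cumulative BAPN
#' exposure `E` acts on the EC50 through the LOX/ECM axis in two ways:
#' \itemize{
#'   \item matrix softening improves drug penetration for every cell, pulling
#'     the sensitive EC50 down to a floor:
#'     `EC50_s(E) = EC50_s * (floor + (1 - floor) * f(E))` with
#'     `f(E) = 1 / (1 + (E/E50)^q)`;
#'   \item resistant cells are additionally resensitized, their EC50 falling
#'     from `dox_ec50_resistant` toward the (current) sensitive value:
#'     `EC50_r(E) = EC50_s(E) + (EC50_r - EC50_s) * f(E)`.
#' }
#' The resistant EC50 never falls below the sensitive one, and the
#' probability is non-decreasing in both dose and exposure.
#'
#' @param dox_local local doxorubicin concentration (ug/ml); vectorized.
#' @param is_resistant logical, resistant phenotype.
#' @param bapn_exposure cumulative BAPN exposure (mM h).
#' @param p a [sim_params()].
#' @return probability in `[0, 1]`, per `dt` step.
#' @export
death_probability <- function(dox_local, is_resistant, bapn_exposure, p) {
  stopifnot(all(dox_local >= 0), all(bapn_exposure >= 0))
  f_res <- resens_factor(bapn_exposure, p)
  f_pen <- penetration_factor(bapn_exposure, p)
  ec50_s <- p$dox_ec50_sensitive *
    (p$bapn_penetration_floor + (1 - p$bapn_penetration_floor) * f_pen)
  ec50 <- ifelse(is_resistant,
                 ec50_s +
                   (p$dox_ec50_resistant - p$dox_ec50_sensitive) * f_res,
                 ec50_s)
  dh <- dox_local^p$hill_k
  sig <- ifelse(dox_local > 0, dh / (dh + ec50^p$hill_k), 0)
  p$death_prob_base + (1 - p$death_prob_base) * sig
}

# Precompute the 6-neighbour table: n_voxels x 6 linear indices, NA outside.
neighbor_table <- function(g) {
  n <- prod(g)
  idx <- seq_len(n) - 1L
  x <- idx %% g[1L]
  y <- (idx %/% g[1L]) %% g[2L]
  z <- idx %/% (g[1L] * g[2L])
  lin <- function(x, y, z, ok) {
    out <- x + g[1L] * (y + g[2L] * z) + 1L
    out[!ok] <- NA_integer_
    out
  }
  cbind(lin(x - 1L, y, z, x > 0L), lin(x + 1L, y, z, x < g[1L] - 1L),
        lin(x, y - 1L, z, y > 0L), lin(x, y + 1L, z, y < g[2L] - 1L),
        lin(x, y, z - 1L, z > 0L), lin(x, y, z + 1L, z < g[3L] - 1L))
}

# Seed `n` cells in distinct voxels of a central ball.
seed_positions <- function(g, n) {
  r <- 2
  repeat {
    idx <- seq_len(prod(g)) - 1L
    x <- idx %% g[1L] - (g[1L] - 1) / 2
    y <- (idx %/% g[1L]) %% g[2L] - (g[2L] - 1) / 2
    z <- idx %/% (g[1L] * g[2L]) - (g[3L] - 1) / 2
    ball <- which(x^2 + y^2 + z^2 <= r^2)
    if (length(ball) >= 1.5 * n || r > max(g)) break
    r <- r + 0.5
  }
  if (length(ball) < n)
    stop("grid too small for initial_cells", call. = FALSE)
  sample(ball, n)
}

new_sim_state <- function(p) {
  g <- p$grid_shape
  occ <- array(0L, dim = g)          # 0 empty, 1 alive, 2 dead
  resistant <- array(FALSE, dim = g)
  pos <- seed_positions(g, p$initial_cells)
  occ[pos] <- 1L
  n_res <- round(p$resistant_fraction * p$initial_cells)
  if (n_res > 0) resistant[sample(pos, n_res)] <- TRUE
  list(occ = occ, resistant = resistant,
       oxygen = array(p$boundary_conc[["oxygen"]], dim = g),
       glucose = array(p$boundary_conc[["glucose"]], dim = g),
       dox = array(0, dim = g), bapn = array(0, dim = g),
       bapn_exp = array(0, dim = g),
       stiffness = array(p$stiffness_baseline, dim = g),
       clock = 0, dead = 0L, cum_divisions = 0L, cum_deaths = 0L,
       nbr = neighbor_table(g))
}

# Advance the state by one dt step. Order: schedule events, diffusion,
# consumption/uptake, death, division, hypoxia-induced resistance, stiffness.
sim_step <- function(state, schedule, p) {
  t0 <- state$clock
  ev <- schedule$events
  due <- which(ev$time >= t0 - 1e-9 & ev$time < t0 + p$dt - 1e-9)
  for (i in due) {
    if (ev$drug[i] == "doxorubicin") state$dox <- state$dox + ev$dose[i]
    else state$bapn <- state$bapn + ev$dose[i]
  }

  state$oxygen <- diffuse(state$oxygen, p$diffusion[["oxygen"]], p$dt,
                          fixed_value = p$boundary_conc[["oxygen"]])
  state$glucose <- diffuse(state$glucose, p$diffusion[["glucose"]], p$dt,
                           fixed_value = p$boundary_conc[["glucose"]])
  state$dox <- diffuse(state$dox, p$diffusion[["doxorubicin"]], p$dt)
  state$bapn <- diffuse(state$bapn, p$diffusion[["bapn"]], p$dt)

  alive <- which(state$occ == 1L)
  if (length(alive)) {
    state$oxygen[alive] <- pmax(0, state$oxygen[alive] -
                                  p$oxygen_consumption * p$dt)
    state$glucose[alive] <- pmax(0, state$glucose[alive] -
                                   p$glucose_consumption * p$dt)
    state$dox[alive] <- state$dox[alive] * exp(-p$dox_uptake_rate * p$dt)
  }
  state$bapn_exp <- state$bapn_exp + state$bapn * p$dt

  if (length(alive)) {
    p_drug <- death_probability(state$dox[alive], state$resistant[alive],
                                state$bapn_exp[alive], p)
    starving <- state$oxygen[alive] < p$survival_oxygen |
      state$glucose[alive] < p$survival_glucose
    p_die <- 1 - (1 - p_drug) * (1 - ifelse(starving,
                                            p$starvation_death_prob, 0))
    dies <- stats::runif(length(alive)) < p_die
    if (any(dies)) {
      state$occ[alive[dies]] <- 2L
      state$dead <- state$dead + sum(dies)
      state$cum_deaths <- state$cum_deaths + sum(dies)
      alive <- alive[!dies]
    }
  }

  if (length(alive) && p$division_prob_base > 0) {
    sat <- (state$oxygen[alive] /
              (state$oxygen[alive] + p$division_sat_k[["oxygen"]])) *
      (state$glucose[alive] /
         (state$glucose[alive] + p$division_sat_k[["glucose"]]))
    dividing <- alive[stats::runif(length(alive)) < p$division_prob_base * sat]
    for (v in dividing) {
      nb <- state$nbr[v, ]
      nb <- nb[!is.na(nb)]
      free <- nb[state$occ[nb] == 0L]
      if (length(free)) {
        d <- if (length(free) == 1L) free else sample(free, 1L)
        state$occ[d] <- 1L
        state$resistant[d] <- state$resistant[v]
        state$cum_divisions <- state$cum_divisions + 1L
      }
    }
    alive <- which(state$occ == 1L)
  }

  if (length(alive) && p$hypoxia_switch_prob > 0) {
    candidates <- alive[!state$resistant[alive] &
                          state$oxygen[alive] < p$hypoxia_threshold]
    if (length(candidates)) {
      sw <- candidates[stats::runif(length(candidates)) <
                         p$hypoxia_switch_prob]
      state$resistant[sw] <- TRUE
    }
  }

  if (length(alive) && p$stiffness_remodel_rate > 0) {
    lox <- 1 / (1 + state$bapn[alive] / p$bapn_lox_k)
    state$stiffness[alive] <- state$stiffness[alive] +
      p$stiffness_remodel_rate * p$dt * lox
  }

  state$clock <- t0 + p$dt
  state
}

sample_state <- function(state) {
  c(living_cells = sum(state$occ == 1L),
    dead_cells = state$dead,
    mean_glucose = mean(state$glucose),
    mean_oxygen = mean(state$oxygen),
    mean_youngs_modulus = mean(state$stiffness))
}

#' Run one culture simulation
#'
#' Advances the lattice automaton for `duration` hours under the given
#' treatment schedule and samples the five tracked series every
#' `sample_every` hours (including t = 0), yielding
#' `duration / sample_every + 1` samples per series. Reproducible under
#' `p$seed`.
#'
#' @param p a [sim_params()].
#' @param schedule a [make_schedule()] or custom `treatment_schedule`.
#' @return an object of class `trace_set`: a list with `series` (5 x samples
#'   matrix), `time` (hours), `label` (outcome class via [label_outcome()]),
#'   and condition metadata.
#' @export
run_simulation <- function(p = sim_params(), schedule = make_schedule("T1", 0, 0)) {
  stopifnot(inherits(p, "sim_params"), inherits(schedule, "treatment_schedule"))
  n_samples <- as.integer(round(p$duration / p$sample_every)) + 1L
  steps_per_sample <- as.integer(round(p$sample_every / p$dt))
  series <- matrix(NA_real_, nrow = 5L, ncol = n_samples,
                   dimnames = list(c("living_cells", "dead_cells",
                                     "mean_glucose", "mean_oxygen",
                                     "mean_youngs_modulus"), NULL))
  conservation <- matrix(NA_real_, nrow = 2L, ncol = n_samples,
                         dimnames = list(c("cum_divisions", "cum_deaths"),
                                         NULL))
  with_seed(p$seed, {
    if (p$growth_variability > 0)
      p$division_prob_base <- p$division_prob_base *
        exp(stats::rnorm(1L, 0, p$growth_variability))
    state <- new_sim_state(p)
    series[, 1L] <- sample_state(state)
    conservation[, 1L] <- c(state$cum_divisions, state$cum_deaths)
    for (s in seq_len(n_samples - 1L)) {
      for (k in seq_len(steps_per_sample))
        state <- sim_step(state, schedule, p)
      series[, s + 1L] <- sample_state(state)
      conservation[, s + 1L] <- c(state$cum_divisions, state$cum_deaths)
    }
  })
  initial <- series["living_cells", 1L]
  final <- series["living_cells", n_samples]
  label <- if (initial > 0) label_outcome(initial, final)
  else factor(NA_character_, levels = outcome_classes())
  structure(
    list(series = series, time = seq(0, p$duration, by = p$sample_every),
         label = label,
         conservation = conservation,
         condition = list(resistant_fraction = p$resistant_fraction,
                          protocol = schedule$protocol_id,
                          doses = schedule$events, seed = p$seed)),
    class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  n <- ncol(x$series)
  cat(sprintf(
    "<trace_set> %d samples over %g h | protocol %s | outcome %s\n",
    n, max(x$time), x$condition$protocol, as.character(x$label)))
  cat(sprintf("  living %d -> %d, dead %d\n",
              as.integer(x$series["living_cells", 1L]),
              as.integer(x$series["living_cells", n]),
              as.integer(x$series["dead_cells", n])))
  invisible(x)
}

#' Plot the five tracked series of a simulation
#' @param x a `trace_set`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trace_set <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in rownames(x$series))
    graphics::plot(x$time, x$series[v, ], type = "l", xlab = "time (h)",
                   ylab = v, main = v, ...)
  invisible(x)
}

#' Factorial design of the simulation study
#'
#' Expands resistant fraction x doxorubicin dose x BAPN dose x replicate into
#' one row per run, with a deterministic per-run seed derived from the master
#' seed, the condition index and the replicate index.
#'
#' @param resistant_fractions,dox_doses,bapn_doses design levels; defaults are
#'   the full study grid (3 x 4 x 3 conditions).
#' @param replicates replicates per condition.
#' @param master_seed integer master seed.
#' @return data.frame with one row per simulation run.
#' @export
factorial_design <- function(resistant_fractions = c(0, 0.5, 1),
                             dox_doses = c(0, 0.03, 0.15, 0.3),
                             bapn_doses = c(0, 2, 5),
                             replicates = 50L, master_seed = 1L) {
  grid <- expand.grid(dox = dox_doses, bapn = bapn_doses,
                      resistant_fraction = resistant_fractions,
                      KEEP.OUT.ATTRS = FALSE)
  grid$condition <- seq_len(nrow(grid))
  out <- grid[rep(seq_len(nrow(grid)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), times = nrow(grid))
  out$seed <- derive_seed(master_seed, out$condition, out$replicate)
  rownames(out) <- NULL
  out
}

# Deterministic per-run seed, kept inside the 32-bit integer range.
derive_seed <- function(master, condition, replicate) {
  as.integer((as.numeric(master) %% 2147483629 +
                1000003 * as.numeric(condition) +
                7919 * as.numeric(replicate)) %% 2147483629)
}

#' Generate a labeled dataset from the factorial design
#'
#' Runs one simulation per design row under the given protocol and collects
#' the five series of each run into a [labeled_dataset()] labeled with the
#' outcome class. With the default design and 50 replicates this is the
#' 1800-run study; tests and examples use reduced replicate counts.
#'
#' @param params a [sim_params()] template; per-run fields
#'   (`resistant_fraction`, `seed`) are overwritten from the design.
#' @param design a [factorial_design()] data.frame.
#' @param protocol protocol id passed to [make_schedule()] (default `"T1"`).
#' @param normalize z-normalize traces on export (default `TRUE`, matching
#'   the classifier input contract).
#' @return a [labeled_dataset()] with one 5-channel trace per design row and
#'   outcome-class labels CR/PR/SNG/PNG.
#' @export
generate_factorial_dataset <- function(params = sim_params(),
                                       design = factorial_design(),
                                       protocol = "T1", normalize = TRUE) {
  stopifnot(nrow(design) >= 1L)
  n_samples <- as.integer(round(params$duration / params$sample_every)) + 1L
  vals <- array(NA_real_, dim = c(5L, n_samples, nrow(design)))
  labels <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    p <- params
    p$resistant_fraction <- design$resistant_fraction[i]
    p$seed <- design$seed[i]
    ts <- run_simulation(p, make_schedule(protocol, design$dox[i],
                                          design$bapn[i]))
    vals[, , i] <- ts$series
    labels[i] <- as.character(ts$label)
  }
  ds <- labeled_dataset(
    vals, factor(labels, levels = outcome_classes()),
    ids = sprintf("sim_%04d", seq_len(nrow(design))),
    channel_names = c("living_cells", "dead_cells", "mean_glucose",
                      "mean_oxygen", "mean_youngs_modulus"),
    meta = list(generator = "culture_simulator", protocol = protocol,
                design = design))
  if (normalize) z_normalize(ds) else ds
}
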