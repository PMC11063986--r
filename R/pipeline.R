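#' Top-level pipeline configuration
#'
#' Bundles the per-stage configurations. A stage set to `NULL` is skipped:
#' a signals-only run trains and explains the waveform benchmark, a
#' schedules-only run compares treatment protocols on the culture simulator,
#' and a full configuration does both.
#'
#' @param signals a [signal_config()], or `NULL` to skip the benchmark stage.
#' @param network a [net_config()] used wherever a classifier is trained.
#' @param simulator a [sim_params()] template for the simulation stages.
#' @param schedules a list with `protocols` (default `c("T1","T2")`),
#'   `replicates`, `reference` and `both_drugs_only`, or `NULL` to skip.
#' @param n_fits ensemble size (default 5).
#' @param train_fraction train split fraction (default 0.7).
#' @param cam_threshold relevance cutoff for region reports (default 0.5).
#' @param seed master seed; stage seeds derive from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(signals = signal_config(), network = net_config(),
                       simulator = sim_params(), schedules = NULL,
                       n_fits = 5L, train_fraction = 0.7,
                       cam_threshold = 0.5, seed = 1L) {
  structure(list(signals = signals, network = network, simulator = simulator,
                 schedules = schedules, n_fits = as.integer(n_fits),
                 train_fraction = train_fraction,
                 cam_threshold = cam_threshold, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — generate, split, train the
#' ensemble, select the best fit, evaluate, compute class-averaged CAMs and
#' region reports, and compare treatment schedules — and optionally writes
#' the report bundle (manifest, per-fit metric table, CAM and region CSVs,
#' prevalence and change tables, reproducibility log) to `out_dir`.
#'
#' @param cfg a [run_config()].
#' @param out_dir directory for the report bundle, or `NULL` for none.
#' @return list with the per-stage results, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  res <- list(config_hash = config_hash(lapply(unclass(cfg), unclass)),
              seed = cfg$seed)
  if (!is.null(cfg$signals)) {
    res$signals <- stage("signals", {
      ds <- z_normalize(generate_signals_dataset(cfg$signals))
      sp <- split_train_test(ds, cfg$train_fraction,
                             seed = derive_seed(cfg$seed, 1L, 1L))
      ens <- train_ensemble(sp$train, cfg$network, n_fits = cfg$n_fits)
      best <- select_best(ens, sp$test)
      cams <- class_average_cams(best, sp$test)
      regions <- do.call(rbind, lapply(names(cams), function(cl) {
        rr <- relevant_regions(cams[[cl]], cfg$cam_threshold)
        if (nrow(rr)) cbind(class = cl, rr) else NULL
      }))
      b <- cfg$signals$region_bounds
      windows <- list(R1 = c(0L, b[1L]), R2 = b,
                      R3 = c(b[2L], cfg$signals$trace_length))
      relevance <- t(vapply(cams, region_relevance, numeric(3L),
                            regions = windows))
      list(dataset = ds, split = sp, ensemble = ens, best = best,
           metrics = evaluate(best, sp$test),
           fit_metrics = attr(best, "metrics"), cams = cams,
           regions = regions, region_relevance = relevance,
           manifest = dataset_manifest(ds, cfg$seed))
    })
  }
  if (!is.null(cfg$schedules)) {
    res$schedules <- stage("schedules", {
      sch <- cfg$schedules
      design <- factorial_design(
        replicates = if (is.null(sch$replicates)) 10L else sch$replicates,
        master_seed = derive_seed(cfg$seed, 2L, 1L))
      compare_protocols(
        params = cfg$simulator,
        protocols = if (is.null(sch$protocols)) c("T1", "T2") else
          sch$protocols,
        design = design,
        reference = if (is.null(sch$reference)) "T1" else sch$reference,
        both_drugs_only = !isFALSE(sch$both_drugs_only))
    })
  }
  if (!is.null(out_dir)) {
    stage("report", write_report_bundle(res, out_dir))
    return(invisible(res))
  }
  res
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(config_hash = res$config_hash, seed = res$seed),
                       file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  if (!is.null(res$signals)) {
    s <- res$signals
    jsonlite::write_json(s$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(s$fit_metrics, file.path(out_dir, "fit_metrics.csv"))
    for (cl in names(s$cams))
      utils::write.csv(
        data.frame(time_index = seq_along(s$cams[[cl]]$values) - 1L,
                   value = s$cams[[cl]]$values),
        file.path(out_dir, sprintf("cam_%s.csv", cl)), row.names = FALSE)
    if (!is.null(s$regions))
      utils::write.csv(s$regions, file.path(out_dir, "cam_regions.csv"),
                       row.names = FALSE)
  }
  if (!is.null(res$schedules)) {
    utils::write.csv(res$schedules$prevalence,
                     file.path(out_dir, "prevalence.csv"), row.names = FALSE)
    utils::write.csv(res$schedules$change,
                     file.path(out_dir, "change_vs_reference.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
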