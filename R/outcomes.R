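#' Treatment-outcome classes
#'
#' Four classes partition every (initial > 0, final >= 0) pair: complete
#' response (CR, population eliminated), partial response (PR, decrease of at
#' least 30 %), stable neoplastic growth (SNG, change in (-30 %, +20 %]) and
#' progressive neoplastic growth (PNG, increase over 20 %).
#'
#' @return character vector of the four class names.
#' @export
outcome_classes <- function() c("CR", "PR", "SNG", "PNG")

#' Classify a treatment outcome from initial and final population size
#'
#' Boundary semantics follow the class definitions literally: a decrease of
#' at least 30 % (change `<= -0.3`) is PR, an increase of over 20 % (change
#' `> +0.2`) is PNG, and SNG takes everything in between, both boundaries
#' included on its side where not claimed. CR (final = 0) is checked before
#' PR, being the stricter class. Vectorized over both arguments.
#'
#' @param initial_living living-cell count at the start of the simulation.
#' @param final_living living-cell count at the end.
#' @return factor with levels CR, PR, SNG, PNG.
#' @export
label_outcome <- function(initial_living, final_living) {
  if (any(initial_living <= 0))
    stop("initial_living must be > 0: relative change is undefined",
         call. = FALSE)
  if (any(final_living < 0)) stop("final_living must be >= 0", call. = FALSE)
  change <- (final_living - initial_living) / initial_living
  out <- ifelse(final_living == 0, "CR",
                ifelse(change <= -0.3, "PR",
                       ifelse(change > 0.2, "PNG", "SNG")))
  factor(out, levels = outcome_classes())
}

#' Build one of the five named treatment schedules
#'
#' The reference protocol T1 administers both drugs at t = 0 h. The
#' alternatives shift or repeat administrations around t = 17 h:
#' \itemize{
#'   \item T1: BAPN at 0 h, doxorubicin at 0 h;
#'   \item T2: BAPN at 0 h, doxorubicin at 17 h;
#'   \item T3: BAPN at 0 h and 17 h, doxorubicin at 17 h;
#'   \item T4: BAPN at 0 h, doxorubicin at 0 h and 17 h;
#'   \item T5: BAPN and doxorubicin both at 0 h and 17 h.
#' }
#' A repeated administration adds the same per-administration dose again (two
#' events), doubling the cumulative dose.
#'
#' @param protocol one of `"T1"` ... `"T5"`.
#' @param dox_dose doxorubicin dose per administration (ug/ml).
#' @param bapn_dose BAPN dose per administration (mM).
#' @return an object of class `treatment_schedule` with an `events`
#'   data.frame (`drug`, `dose`, `time`) sorted by time.
#' @export
make_schedule <- function(protocol, dox_dose, bapn_dose) {
  stopifnot(dox_dose >= 0, bapn_dose >= 0)
  ev <- switch(protocol,
    T1 = list(c("bapn", bapn_dose, 0), c("doxorubicin", dox_dose, 0)),
    T2 = list(c("bapn", bapn_dose, 0), c("doxorubicin", dox_dose, 17)),
    T3 = list(c("bapn", bapn_dose, 0), c("bapn", bapn_dose, 17),
              c("doxorubicin", dox_dose, 17)),
    T4 = list(c("bapn", bapn_dose, 0), c("doxorubicin", dox_dose, 0),
              c("doxorubicin", dox_dose, 17)),
    T5 = list(c("bapn", bapn_dose, 0), c("doxorubicin", dox_dose, 0),
              c("bapn", bapn_dose, 17), c("doxorubicin", dox_dose, 17)),
    stop(sprintf("unknown protocol '%s' (expected T1..T5)", protocol),
         call. = FALSE))
  events <- data.frame(drug = vapply(ev, `[`, "", 1L),
                       dose = as.numeric(vapply(ev, `[`, "", 2L)),
                       time = as.numeric(vapply(ev, `[`, "", 3L)))
  treatment_schedule(events, protocol_id = protocol)
}

#' Construct a custom treatment schedule
#'
#' @param events data.frame with columns `drug` (`"doxorubicin"` or
#'   `"bapn"`), `dose` (>= 0) and `time` (hours, >= 0).
#' @param protocol_id label for reports (default `"custom"`).
#' @return an object of class `treatment_schedule`, events sorted by time.
#' @export
treatment_schedule <- function(events, protocol_id = "custom") {
  stopifnot(is.data.frame(events),
            all(c("drug", "dose", "time") %in% names(events)))
  if (!all(events$drug %in% c("doxorubicin", "bapn")))
    stop("drug must be 'doxorubicin' or 'bapn'", call. = FALSE)
  if (any(events$time < 0) || any(events$dose < 0))
    stop("doses and times must be >= 0", call. = FALSE)
  events <- events[order(events$time, events$drug), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, protocol_id = protocol_id),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("<treatment_schedule> %s\n", x$protocol_id))
  for (i in seq_len(nrow(x$events)))
    cat(sprintf("  %5.1f h  %-12s %g\n", x$events$time[i], x$events$drug[i],
                x$events$dose[i]))
  invisible(x)
}

#' Outcome prevalence per protocol and stratum
#'
#' Tabulates, within each resistance stratum, the percentage of simulations
#' falling in each outcome class under each protocol. Rows sum to 100.
#'
#' @param labels data.frame with columns `protocol`, `stratum` and `class`
#'   (values in [outcome_classes()]).
#' @return a data.frame of class `prevalence_table` with columns `protocol`,
#'   `stratum`, one percentage column per outcome class, and `n`.
#' @export
prevalence_table <- function(labels) {
  stopifnot(nrow(labels) >= 1L,
            all(c("protocol", "stratum", "class") %in% names(labels)))
  cls <- outcome_classes()
  groups <- unique(labels[c("protocol", "stratum")])
  groups <- groups[order(groups$stratum, groups$protocol), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- labels$protocol == groups$protocol[i] &
      labels$stratum == groups$stratum[i]
    counts <- table(factor(labels$class[sel], levels = cls))
    pct <- 100 * as.numeric(counts) / sum(counts)
    names(pct) <- cls
    data.frame(protocol = groups$protocol[i], stratum = groups$stratum[i],
               as.list(pct), n = sum(sel), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Per-class change in simulation counts relative to a reference protocol
#'
#' For each protocol and outcome class (within each stratum), reports the
#' change in the number of simulations relative to the reference protocol's
#' count for that class, as a percentage of the reference count — the
#' normalization under which a PR count rising from 40 to 66 reads +65 %.
#' When the reference count is zero and the protocol count is positive the
#' change is undefined: the value is `NA` and the `undefined` flag is set.
#'
#' @param labels the same data.frame accepted by [prevalence_table()].
#' @param reference reference protocol id (default `"T1"`).
#' @return data.frame with columns `stratum`, `protocol`, `class`,
#'   `ref_count`, `count`, `change_pct`, `undefined`.
#' @export
percent_change_vs_reference <- function(labels, reference = "T1") {
  stopifnot(all(c("protocol", "stratum", "class") %in% names(labels)))
  if (!reference %in% labels$protocol)
    stop(sprintf("reference protocol '%s' not present", reference),
         call. = FALSE)
  cls <- outcome_classes()
  out <- list()
  for (st in unique(labels$stratum)) {
    sub <- labels[labels$stratum == st, , drop = FALSE]
    ref_counts <- table(factor(sub$class[sub$protocol == reference],
                               levels = cls))
    for (pr in unique(sub$protocol)) {
      counts <- table(factor(sub$class[sub$protocol == pr], levels = cls))
      ref <- as.numeric(ref_counts)
      cnt <- as.numeric(counts)
      undef <- ref == 0 & cnt > 0
      change <- ifelse(ref > 0, 100 * (cnt - ref) / ref,
                       ifelse(cnt == 0, 0, NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, protocol = pr, class = cls, ref_count = ref,
        count = cnt, change_pct = change, undefined = undef)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run and compare treatment protocols
#'
#' Simulates every (protocol, design row) combination and returns the pooled
#' outcome labels, the prevalence table per stratum and the change report
#' versus the reference protocol. By default only dose combinations with both
#' drugs present are compared (`both_drugs_only = TRUE`), the subset on which
#' published schedule comparisons are made; pass `FALSE` to keep zero-dose
#' levels.
#'
#' @param params a [sim_params()] template.
#' @param protocols protocol ids (subset of T1..T5).
#' @param design a [factorial_design()]; its seeds are reused across
#'   protocols so protocol contrasts are paired.
#' @param reference reference protocol for the change report.
#' @param both_drugs_only drop design rows where either dose is zero.
#' @return list with `labels`, `prevalence` ([prevalence_table()]) and
#'   `change` ([percent_change_vs_reference()]).
#' @export
compare_protocols <- function(params = sim_params(),
                              protocols = c("T1", "T2"),
                              design = factorial_design(replicates = 10L),
                              reference = protocols[1L],
                              both_drugs_only = TRUE) {
  if (both_drugs_only)
    design <- design[design$dox > 0 & design$bapn > 0, , drop = FALSE]
  stopifnot(nrow(design) >= 1L)
  rows <- list()
  for (pr in protocols) {
    for (i in seq_len(nrow(design))) {
      p <- params
      p$resistant_fraction <- design$resistant_fraction[i]
      p$seed <- design$seed[i]
      ts <- run_simulation(p, make_schedule(pr, design$dox[i],
                                            design$bapn[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = pr, stratum = design$resistant_fraction[i],
        class = as.character(ts$label), dox = design$dox[i],
        bapn = design$bapn[i], replicate = design$replicate[i])
    }
  }
  labels <- do.call(rbind, rows)
  list(labels = labels, prevalence = prevalence_table(labels),
       change = percent_change_vs_reference(labels, reference))
}
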