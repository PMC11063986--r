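#' Write a labeled dataset to ARFF
#'
#' Serializes labeled multivariate series in the relational-attribute ARFF
#' dialect used by common time-series-ML toolkits: a single relational
#' attribute whose inner attributes are the time points, one quoted block per
#' instance with channels as newline-separated rows, followed by a nominal
#' class attribute.
#'
#' @param ds a [labeled_dataset()] (nonempty, consistent shape).
#' @param path output file path.
#' @param relation relation name written in the header.
#' @return `path`, invisibly.
#' @export
write_arff <- function(ds, path, relation = "camsched") {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (length(ds) == 0L) stop("refusing to write an empty dataset",
                             call. = FALSE)
  d <- dim(ds$values)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("@relation '%s'", relation),
    "",
    "@attribute series relational"), con)
  writeLines(sprintf("  @attribute t%d numeric", seq_len(d[2L]) - 1L), con)
  writeLines(c("@end series",
               sprintf("@attribute class {%s}",
                       paste(levels(ds$labels), collapse = ",")),
               "", "@data"), con)
  for (i in seq_len(d[3L])) {
    rows <- apply(ds$values[, , i, drop = FALSE], 1L, function(ch)
      paste(format(ch, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = ","))
    writeLines(sprintf("'%s',%s", paste(rows, collapse = "\\n"),
                       as.character(ds$labels[i])), con)
  }
  invisible(path)
}

arff_error <- function(line_no, msg) {
  stop(sprintf("malformed ARFF at line %d: %s", line_no, msg), call. = FALSE)
}

#' Read a labeled dataset from ARFF
#'
#' Parses two dialects, auto-detected from the header: the relational
#' dialect written by [write_arff()] (channels nested per instance), and a
#' flat wide dialect in which each instance is a channel-major concatenation
#' of `n_channels * trace_length` numeric attributes named `ch<i>_t<j>`,
#' followed by a nominal class attribute. Unknown layouts, missing class
#' attributes and ragged series are rejected with the offending line number.
#'
#' @param path ARFF file path.
#' @return a [labeled_dataset()].
#' @export
read_arff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  strip <- trimws(lines)
  lower <- tolower(strip)
  data_at <- which(lower == "@data")[1L]
  if (is.na(data_at)) arff_error(length(lines), "missing @data section")
  head_idx <- seq_len(data_at - 1L)
  attr_idx <- head_idx[startsWith(lower[head_idx], "@attribute")]
  if (!length(attr_idx)) arff_error(1L, "no @attribute declarations")
  class_line <- attr_idx[grepl("\\{.*\\}", strip[attr_idx])]
  if (!length(class_line))
    arff_error(data_at, "label (nominal class) attribute missing")
  class_line <- class_line[length(class_line)]
  class_levels <- strsplit(sub("^.*\\{(.*)\\}.*$", "\\1",
                               strip[class_line]), ",")[[1L]]
  class_levels <- trimws(class_levels)
  body <- strip[(data_at + 1L):length(strip)]
  body_lines <- (data_at + 1L):length(strip)
  keep <- nzchar(body) & !startsWith(body, "%")
  body <- body[keep]; body_lines <- body_lines[keep]
  if (!length(body)) arff_error(data_at, "no data rows")

  relational <- any(grepl("relational", lower[attr_idx]))
  if (relational) {
    parse_row <- function(row, ln) {
      if (!grepl("^'", row)) arff_error(ln, "expected quoted relational value")
      close_q <- regexpr("',", row, fixed = TRUE)
      if (close_q < 0) arff_error(ln, "unterminated relational value")
      payload <- substr(row, 2L, close_q - 1L)
      label <- trimws(substr(row, close_q + 2L, nchar(row)))
      channels <- strsplit(payload, "\\\\n|\n")[[1L]]
      vals <- lapply(channels, function(ch) {
        v <- suppressWarnings(as.numeric(strsplit(ch, ",")[[1L]]))
        if (anyNA(v)) arff_error(ln, "non-numeric value in series")
        v
      })
      if (length(unique(lengths(vals))) != 1L)
        arff_error(ln, "ragged series: channels differ in length")
      list(values = do.call(rbind, vals), label = label)
    }
    parsed <- Map(parse_row, body, body_lines)
    lens <- vapply(parsed, function(p) ncol(p$values), 1L)
    chs <- vapply(parsed, function(p) nrow(p$values), 1L)
    if (length(unique(lens)) != 1L || length(unique(chs)) != 1L)
      arff_error(body_lines[1L], "instances differ in shape")
  } else {
    # flat wide dialect: ch<i>_t<j> numeric attributes, channel-major
    num_attrs <- strip[setdiff(attr_idx, class_line)]
    names_flat <- sub("^@attribute\\s+(\\S+)\\s.*$", "\\1", num_attrs,
                      ignore.case = TRUE)
    m <- regmatches(names_flat,
                    regexec("^ch([0-9]+)_t([0-9]+)$", names_flat))
    if (any(lengths(m) != 3L))
      arff_error(attr_idx[1L],
                 "unknown flat layout: expected attributes ch<i>_t<j>")
    ch_i <- as.integer(vapply(m, `[`, "", 2L))
    n_ch <- max(ch_i)
    T_ <- length(names_flat) / n_ch
    if (T_ != round(T_))
      arff_error(attr_idx[1L], "attribute count not divisible by channels")
    parsed <- Map(function(row, ln) {
      parts <- strsplit(row, ",")[[1L]]
      if (length(parts) != length(names_flat) + 1L)
        arff_error(ln, sprintf("expected %d fields, found %d",
                               length(names_flat) + 1L, length(parts)))
      v <- suppressWarnings(as.numeric(parts[-length(parts)]))
      if (anyNA(v)) arff_error(ln, "non-numeric value in series")
      list(values = matrix(v, nrow = n_ch, ncol = T_, byrow = TRUE),
           label = trimws(parts[length(parts)]))
    }, body, body_lines)
  }
  n <- length(parsed)
  d1 <- nrow(parsed[[1L]]$values); d2 <- ncol(parsed[[1L]]$values)
  vals <- array(NA_real_, c(d1, d2, n))
  for (i in seq_len(n)) vals[, , i] <- parsed[[i]]$values
  labs <- vapply(parsed, function(p) p$label, "")
  bad <- which(!labs %in% class_levels)
  if (length(bad))
    arff_error(body_lines[bad[1L]],
               sprintf("label '%s' not among declared class values",
                       labs[bad[1L]]))
  labeled_dataset(vals, factor(labs, levels = class_levels))
}

#' Long-format CSV serialization
#'
#' One row per (trace, channel, time point): columns `trace_id`, `channel`,
#' `time_index` (0-based), `value`, `label`.
#'
#' @param ds a [labeled_dataset()].
#' @param path output path.
#' @return `path` invisibly (writer); a [labeled_dataset()] (reader).
#' @export
write_long_csv <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"), length(ds) >= 1L)
  d <- dim(ds$values)
  df <- data.frame(
    trace_id = rep(ds$ids, each = d[1L] * d[2L]),
    channel = rep(rep(ds$channel_names, each = d[2L]), times = d[3L]),
    time_index = rep(seq_len(d[2L]) - 1L, times = d[1L] * d[3L]),
    value = as.vector(aperm(ds$values, c(2L, 1L, 3L))),
    label = rep(as.character(ds$labels), each = d[1L] * d[2L]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_long_csv
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "channel", "time_index", "value", "label")
  if (!all(need %in% names(df)))
    stop(sprintf("long CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  ids <- unique(df$trace_id)
  channels <- unique(df$channel)
  times <- sort(unique(df$time_index))
  vals <- array(NA_real_, c(length(channels), length(times), length(ids)))
  df$ci <- match(df$channel, channels)
  df$ti <- match(df$time_index, times)
  df$ii <- match(df$trace_id, ids)
  vals[cbind(df$ci, df$ti, df$ii)] <- df$value
  if (anyNA(vals)) stop("ragged long CSV: missing (trace, channel, time) cells",
                        call. = FALSE)
  labs <- df$label[!duplicated(df$ii)][order(unique(df$ii))]
  labeled_dataset(vals, labs, ids = ids, channel_names = channels)
}

#' Dataset manifest
#'
#' Summary of a serialized dataset, always recomputed from the payload:
#' shape, class prevalences (percent, summing to 100), generator provenance
#' and a configuration hash.
#'
#' @param ds a [labeled_dataset()].
#' @param master_seed seed recorded as provenance.
#' @return a list; write with [jsonlite::write_json()].
#' @export
dataset_manifest <- function(ds, master_seed = NULL) {
  tab <- table(ds$labels)
  prev <- round(100 * as.numeric(tab) / length(ds), 4)
  names(prev) <- names(tab)
  list(n_traces = length(ds), n_channels = n_channels(ds),
       trace_length = trace_length(ds),
       classes = names(tab), prevalence_pct = prev,
       generator = ds$meta$generator,
       config_hash = config_hash(ds$meta$config),
       master_seed = if (is.null(master_seed)) ds$meta$seed else master_seed)
}

# Stable md5 hash of a configuration list (NULL-safe).
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}
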