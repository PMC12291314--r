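# I/O and validation for OJIP transients and tidy trait tables.
#
# All times are microseconds on disk and in memory; fluorescence is in
# instrument-arbitrary units (every JIP quantity downstream is a ratio, so
# no rescaling is ever applied on input).

#' Construct a fluorescence transient
#'
#' A `fluor_transient` holds one replicate's fast fluorescence induction
#' trace together with its grouping metadata (variety, treatment,
#' replicate). Times are in microseconds; a valid OJIP trace must start at
#' or before 50 us (so the origin F0 can be read) and extend to at least
#' 300 ms (beyond the I step).
#'
#' @param times numeric vector of sampling times in microseconds, strictly
#'   increasing, first element <= 50, last element >= 3e5.
#' @param fluorescence numeric vector of fluorescence readings (arbitrary
#'   units, all finite and > 0), same length as `times`.
#' @param variety variety/cultivar label.
#' @param treatment treatment label (e.g. `"0h"`, `"24h"`). Treatment
#'   ordering is never inferred lexically; pass an explicit level order to
#'   downstream functions.
#' @param replicate positive integer replicate id.
#' @return An object of class `fluor_transient`.
#' @export
fluorescence_transient <- function(times, fluorescence,
                                   variety = "V1", treatment = "0h",
                                   replicate = 1L) {
  times <- as.numeric(times)
  fluorescence <- as.numeric(fluorescence)
  x <- structure(
    list(times = times, fluorescence = fluorescence,
         variety = as.character(variety), treatment = as.character(treatment),
         replicate = as.integer(replicate)),
    class = "fluor_transient")
  validate_transient(x)
  x
}

#' Validate a fluorescence transient
#'
#' Checks the `fluor_transient` invariants: strictly increasing times,
#' finite positive fluorescence, matching lengths with at least 30 samples,
#' first time <= 50 us and last time >= 300 ms.
#'
#' @param x a `fluor_transient`.
#' @return `x`, invisibly. Errors (class `ojip_validation_error`) otherwise.
#' @export
validate_transient <- function(x) {
  stopifnot(inherits(x, "fluor_transient"))
  lab <- sprintf("%s/%s rep %s", x$variety, x$treatment, x$replicate)
  fail <- function(msg) {
    stop(structure(class = c("ojip_validation_error", "error", "condition"),
                   list(message = sprintf("invalid transient [%s]: %s", lab, msg),
                        call = sys.call(-1))))
  }
  if (length(x$times) != length(x$fluorescence))
    fail("times and fluorescence differ in length")
  if (length(x$times) < 30L)
    fail(sprintf("only %d samples; need >= 30", length(x$times)))
  if (anyNA(x$times) || any(!is.finite(x$times)))
    fail("non-finite times")
  d <- diff(x$times)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L] + 1L
    fail(sprintf("time not strictly increasing at sample %d (replicate %s)",
                 i, x$replicate))
  }
  if (any(!is.finite(x$fluorescence)) || any(x$fluorescence <= 0))
    fail("fluorescence must be finite and > 0")
  if (x$times[1L] > 50)
    fail(sprintf("first sample at %g us; need <= 50 us", x$times[1L]))
  if (x$times[length(x$times)] < 3e5)
    fail(sprintf("last sample at %g us; need >= 3e5 us", x$times[length(x$times)]))
  invisible(x)
}

#' @export
print.fluor_transient <- function(x, ...) {
  cat(sprintf(
    "<fluor_transient> %s / %s / rep %d: %d samples, %.3g-%.3g us, F %.4g-%.4g\n",
    x$variety, x$treatment, x$replicate, length(x$times),
    x$times[1L], x$times[length(x$times)],
    min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

stop_format <- function(msg) {
  stop(structure(class = c("ojip_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read OJIP transients from delimited text
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`long_csv`}{columns `variety,treatment,replicate,time_us,fluorescence`,
#'     one row per sample.}
#'   \item{`wide_csv`}{first column `time_us`; each further column holds one
#'     trace and is named `variety|treatment|replicate`.}
#' }
#' Rows are never silently dropped: in the long dialect the sum of output
#' trace lengths equals the input row count.
#'
#' @param path path to a CSV file.
#' @param dialect `"long_csv"` or `"wide_csv"`.
#' @return A list of [fluorescence_transient()] objects.
#' @export
read_transients <- function(path, dialect = c("long_csv", "wide_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "long_csv") {
    need <- c("variety", "treatment", "replicate", "time_us", "fluorescence")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop_format(sprintf("long_csv is missing column(s): %s",
                          paste(miss, collapse = ", ")))
    key <- interaction(df$variety, df$treatment, df$replicate, drop = TRUE,
                       lex.order = TRUE)
    idx <- split(seq_len(nrow(df)), key)
    out <- lapply(idx, function(i) {
      tm <- df$time_us[i]
      bad <- which(diff(tm) <= 0)
      if (length(bad))
        stop(structure(
          class = c("ojip_validation_error", "error", "condition"),
          list(message = sprintf(
            "time column not strictly increasing at file row %d (replicate %s, %s/%s)",
            i[bad[1L] + 1L] + 1L,  # +1 for the header line
            df$replicate[i[1L]], df$variety[i[1L]], df$treatment[i[1L]]),
            call = NULL)))
      fluorescence_transient(tm, df$fluorescence[i],
                             variety = df$variety[i[1L]],
                             treatment = df$treatment[i[1L]],
                             replicate = df$replicate[i[1L]])
    })
    names(out) <- NULL
    return(out)
  }
  # wide_csv
  if (names(df)[1L] != "time_us")
    stop_format("wide_csv is missing column: time_us (must be first)")
  if (ncol(df) < 2L) stop_format("wide_csv has no trace columns")
  tm <- df$time_us
  out <- lapply(names(df)[-1L], function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop_format(sprintf(
        "wide_csv trace column '%s' is not named variety|treatment|replicate", nm))
    bad <- which(diff(tm) <= 0)
    if (length(bad))
      stop(structure(
        class = c("ojip_validation_error", "error", "condition"),
        list(message = sprintf(
          "time column not strictly increasing at file row %d (replicate %s)",
          bad[1L] + 2L, parts[3L]), call = NULL)))
    fluorescence_transient(tm, df[[nm]], variety = parts[1L],
                           treatment = parts[2L],
                           replicate = as.integer(parts[3L]))
  })
  out
}

#' Write OJIP transients to delimited text
#'
#' Inverse of [read_transients()]; the long dialect round-trips exactly.
#'
#' @param transients list of `fluor_transient` objects.
#' @param path output path.
#' @param dialect currently only `"long_csv"`.
#' @return `path`, invisibly.
#' @export
write_transients <- function(transients, path, dialect = "long_csv") {
  dialect <- match.arg(dialect, "long_csv")
  rows <- do.call(rbind, lapply(transients, function(x) {
    data.frame(variety = x$variety, treatment = x$treatment,
               replicate = x$replicate, time_us = x$times,
               fluorescence = x$fluorescence, stringsAsFactors = FALSE)
  }))
  rows$time_us <- sprintf("%.17g", rows$time_us)
  rows$fluorescence <- sprintf("%.17g", rows$fluorescence)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct/validate a tidy trait table
#'
#' The tidy "group table" is the substrate for all comparative statistics:
#' one row per (variety, treatment, replicate, trait) with a numeric value.
#' The key must be unique and every treatment label must be present for
#' every variety that appears (a balanced treatment layout; replicate
#' counts may differ).
#'
#' @param df data.frame with columns `variety,treatment,replicate,trait,value`.
#' @return The validated data.frame with class `c("group_table","data.frame")`.
#' @export
group_table <- function(df) {
  need <- c("variety", "treatment", "replicate", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format(sprintf("group table is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  df <- df[, need]
  df$variety <- as.character(df$variety)
  df$treatment <- as.character(df$treatment)
  df$replicate <- as.integer(df$replicate)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  if (nrow(df)) {
    key <- paste(df$variety, df$treatment, df$replicate, df$trait, sep = "\r")
    if (anyDuplicated(key))
      stop_format("duplicate (variety, treatment, replicate, trait) key")
    treatments <- unique(df$treatment)
    for (v in unique(df$variety)) {
      have <- unique(df$treatment[df$variety == v])
      missing_t <- setdiff(treatments, have)
      if (length(missing_t))
        stop_format(sprintf("variety '%s' lacks treatment(s): %s",
                            v, paste(missing_t, collapse = ", ")))
    }
  }
  class(df) <- c("group_table", "data.frame")
  df
}

#' Write a group table to CSV
#'
#' Values are written with 17 significant digits so that write-then-read is
#' the identity to full double precision.
#'
#' @param table a [group_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(table, path) {
  table <- group_table(table)
  out <- as.data.frame(table)
  out$value <- sprintf("%.17g", out$value)
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop(sprintf("cannot write '%s': %s",
                                            path, conditionMessage(e))))
  invisible(path)
}

#' Read a group table from CSV
#'
#' @param path path to a CSV written by [write_group_table()] (columns
#'   `variety,treatment,replicate,trait,value`).
#' @return A validated [group_table()].
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  group_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
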