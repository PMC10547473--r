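# Core trajectory container and the trace selection / interpolation rules
# applied to live-cell reporter time series before any metric is computed.

#' Construct a trajectory set
#'
#' A trajectory set is a long-format table of single-cell reporter time
#' series on a shared, uniformly spaced time grid.  One row is one (cell,
#' reporter, time point) observation.  Missing observations are encoded by
#' the logical `missing` column, never by sentinel values.
#'
#' @param df data.frame with columns `cell_id`, `reporter`, `time_min`,
#'   `value`, `missing`; optional columns `intensity` (mean raw
#'   fluorescence of the trace, used by QC), `condition` and `dose`.
#' @param background per-channel background intensity estimate (scalar),
#'   or `NA` when unknown.
#' @param schedule optional [treatment_schedule()] the traces refer to.
#' @return an object of class `trajectory_set` (a data.frame).
#' @export
trajectory_set <- function(df, background = NA_real_, schedule = NULL) {
  need <- c("cell_id", "reporter", "time_min", "value", "missing")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trajectory_set: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.logical(df$missing)) df$missing <- as.logical(df$missing)
  if (any(!df$missing & !is.finite(df$value))) {
    stop("trajectory_set: non-finite value at a point not flagged missing")
  }
  if (is.null(df$intensity)) df$intensity <- NA_real_
  if (is.null(df$condition)) df$condition <- NA_character_
  if (is.null(df$dose)) df$dose <- NA_real_
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  attr(df, "background") <- background
  attr(df, "schedule") <- schedule
  class(df) <- c("trajectory_set", "data.frame")
  df
}

#' Treatment schedule
#'
#' Ordered list of treatments: at `time` minutes, `stimulus` is set to
#' `dose`.  Times must be strictly increasing and nonnegative.
#'
#' @param time numeric vector of treatment times (minutes).
#' @param stimulus character vector of stimulus names.
#' @param dose numeric vector of doses in `[0, 1]` (fraction of the
#'   saturating concentration).
#' @return data.frame of class `treatment_schedule`.
#' @export
treatment_schedule <- function(time, stimulus, dose) {
  stopifnot(length(time) == length(stimulus), length(time) == length(dose))
  if (length(time) && (any(time < 0) || any(diff(time) <= 0))) {
    stop("treatment_schedule: times must be nonnegative and strictly increasing")
  }
  if (length(dose) && (any(dose < 0) || any(dose > 1))) {
    stop("treatment_schedule: doses must lie in [0, 1]")
  }
  structure(
    data.frame(time = time, stimulus = as.character(stimulus), dose = dose,
               stringsAsFactors = FALSE),
    class = c("treatment_schedule", "data.frame"))
}

#' Split a trajectory set into per-trace records
#'
#' @param set a [trajectory_set()].
#' @return named list of `cell_trace` objects, one per (cell, reporter)
#'   pair, each a list with fields `cell_id`, `reporter`, `time`, `value`,
#'   `missing`, `intensity`, `condition`, `dose`.
#' @export
split_traces <- function(set) {
  key <- paste(set$cell_id, set$reporter, sep = "\r")
  idx <- split(seq_len(nrow(set)), key)
  # preserve first-appearance order
  idx <- idx[unique(key)]
  lapply(idx, function(i) {
    i <- i[order(set$time_min[i])]
    structure(list(
      cell_id = set$cell_id[i[1L]],
      reporter = set$reporter[i[1L]],
      time = set$time_min[i],
      value = set$value[i],
      missing = set$missing[i],
      intensity = set$intensity[i[1L]],
      condition = set$condition[i[1L]],
      dose = set$dose[i[1L]]
    ), class = "cell_trace")
  })
}

#' Assemble a cell_trace directly
#'
#' Convenience constructor used in tests and for single-trace work.
#'
#' @param time time grid in minutes.
#' @param value trace values (C/N ratio, FRET ratio or intensity).
#' @param missing logical missing flags (default: none missing).
#' @param cell_id,reporter,condition,dose,intensity trace annotations.
#' @return `cell_trace` object.
#' @export
cell_trace <- function(time, value, missing = rep(FALSE, length(time)),
                       cell_id = "cell1", reporter = "reporter",
                       condition = NA_character_, dose = NA_real_,
                       intensity = NA_real_) {
  stopifnot(length(time) == length(value), length(time) == length(missing))
  o <- order(time)
  structure(list(cell_id = cell_id, reporter = reporter,
                 time = time[o], value = value[o], missing = missing[o],
                 intensity = intensity, condition = condition, dose = dose),
            class = "cell_trace")
}

#' Filter traces by intensity, length and gap rules
#'
#' Retains traces whose mean raw fluorescence exceeds
#' `intensity_factor` times the background (strict inequality), whose time
#' span is at least `min_hours` hours, and whose longest run of contiguous
#' missing points does not exceed `max_gap`.  The intensity rule uses the
#' trace's mean raw intensity; traces with no recorded intensity pass that
#' rule (there is nothing to compare).
#'
#' @param set a [trajectory_set()].
#' @param background background fluorescence (must be > 0).
#' @param min_hours minimum trace span, hours.
#' @param max_gap maximum allowed run of contiguous missing points.
#' @param intensity_factor multiple of background the trace mean intensity
#'   must strictly exceed.
#' @return list with elements `set` (the retained [trajectory_set()]) and
#'   `report` (a `qc_report`: per-trace pass/fail with reasons, plus counts).
#' @export
filter_traces <- function(set, background, min_hours = 8, max_gap = 3,
                          intensity_factor = 2) {
  if (!is.finite(background) || background <= 0) {
    stop("filter_traces: background must be a positive number")
  }
  traces <- split_traces(set)
  rows <- lapply(traces, function(tr) {
    reasons <- character(0)
    if (is.finite(tr$intensity) &&
        !(tr$intensity > intensity_factor * background)) {
      reasons <- c(reasons, "intensity")
    }
    span_hr <- (max(tr$time) - min(tr$time)) / 60
    if (span_hr < min_hours - 1e-9) reasons <- c(reasons, "length")
    if (max_run(tr$missing) > max_gap) reasons <- c(reasons, "gap")
    data.frame(cell_id = tr$cell_id, reporter = tr$reporter,
               pass = length(reasons) == 0L,
               reason = if (length(reasons)) paste(reasons, collapse = ",") else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  counts <- c(
    intensity = sum(grepl("intensity", report$reason)),
    length = sum(grepl("length", report$reason)),
    gap = sum(grepl("gap", report$reason))
  )
  keep_key <- paste(report$cell_id, report$reporter, sep = "\r")[report$pass]
  row_key <- paste(set$cell_id, set$reporter, sep = "\r")
  kept <- set[row_key %in% keep_key, , drop = FALSE]
  kept <- trajectory_set(kept, background = attr(set, "background"),
                         schedule = attr(set, "schedule"))
  report <- structure(list(traces = report, counts = counts,
                           n_pass = sum(report$pass),
                           n_fail = sum(!report$pass)),
                      class = "qc_report")
  list(set = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Trace QC report:", x$n_pass, "passed,", x$n_fail, "failed\n")
  cat("  failures by reason: intensity =", x$counts[["intensity"]],
      ", length =", x$counts[["length"]], ", gap =", x$counts[["gap"]], "\n")
  invisible(x)
}

#' Linearly interpolate interior gaps of a trace
#'
#' Interior missing points are replaced by linear interpolation between the
#' flanking observed values.  Leading and trailing missing points cannot be
#' interpolated and are trimmed; the trace start/end times move inward
#' accordingly.  Observed values are never altered.
#'
#' @param trace a `cell_trace`.
#' @return the interpolated `cell_trace` with all `missing` flags `FALSE`.
#' @export
interpolate_gaps <- function(trace) {
  stopifnot(inherits(trace, "cell_trace"))
  obs <- !trace$missing
  if (!any(obs)) stop("interpolate_gaps: all points are missing")
  first <- which(obs)[1L]
  last <- tail(which(obs), 1L)
  keep <- first:last
  tt <- trace$time[keep]
  vv <- trace$value[keep]
  mm <- trace$missing[keep]
  if (any(mm)) {
    fit <- approx(x = tt[!mm], y = vv[!mm], xout = tt[mm], method = "linear")
    vv[mm] <- fit$y
  }
  out <- trace
  out$time <- tt
  out$value <- vv
  out$missing <- rep(FALSE, length(tt))
  out
}

#' Interpolate every trace in a set
#'
#' Applies [interpolate_gaps()] per trace and reassembles the set.  Traces
#' whose leading/trailing points are trimmed keep their own (shortened)
#' grid.
#'
#' @param set a [trajectory_set()].
#' @return a [trajectory_set()] with no missing points.
#' @export
interpolate_set <- function(set) {
  traces <- lapply(split_traces(set), interpolate_gaps)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, reporter = tr$reporter,
               time_min = tr$time, value = tr$value, missing = tr$missing,
               intensity = tr$intensity, condition = tr$condition,
               dose = tr$dose, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  trajectory_set(df, background = attr(set, "background"),
                 schedule = attr(set, "schedule"))
}
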