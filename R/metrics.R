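# Per-cell response metrics: initial response (delta_i), steady-state
# response (delta_ss), AMPKAR2 FRET linearization, and relative
# translation activity (RTA).

window_mean <- function(trace, from, to, closed_right = TRUE) {
  inw <- if (closed_right) trace$time >= from & trace$time <= to
         else trace$time >= from & trace$time < to
  ok <- inw & !trace$missing & is.finite(trace$value)
  if (sum(ok) < 2L) return(NA_real_)
  mean(trace$value[ok])
}

check_coverage <- function(trace, t_treat, baseline_window, t_end) {
  if (min(trace$time) > t_treat - baseline_window + 1e-9) {
    stop("trace coverage insufficient on the baseline side: starts at ",
         min(trace$time), " min, needs ", t_treat - baseline_window)
  }
  if (max(trace$time) < t_end - 1e-9) {
    stop("trace coverage insufficient on the response side: ends at ",
         max(trace$time), " min, needs ", t_end)
  }
}

#' Initial response of a trace to a treatment (delta_i)
#'
#' Signed change in reporter level from the pre-treatment baseline to the
#' peak response shortly after treatment: the extremum of a 3-point
#' moving average within the response window (default 30-60 min after
#' treatment), signed by the largest absolute deviation from the
#' baseline mean (default: the 30 min immediately preceding treatment).
#' Stimulators of mTORC1 give positive delta_i for the TFEB reporter C/N
#' ratio; inhibitors give negative values.
#'
#' @param trace a `cell_trace`.
#' @param t_treat treatment time, minutes.
#' @param baseline_window length of the pre-treatment baseline window,
#'   minutes.
#' @param response_window c(start, end) of the response window relative
#'   to `t_treat`, minutes.
#' @return signed delta_i in trace units; `NA` if either window has
#'   fewer than 2 observed points.
#' @export
delta_i <- function(trace, t_treat, baseline_window = 30,
                    response_window = c(30, 60)) {
  stopifnot(inherits(trace, "cell_trace"))
  check_coverage(trace, t_treat, baseline_window,
                 t_treat + response_window[2L])
  base <- window_mean(trace, t_treat - baseline_window, t_treat,
                      closed_right = FALSE)
  if (!is.finite(base)) return(NA_real_)
  v <- trace$value
  v[trace$missing] <- NA_real_
  sm <- moving_avg3(v)
  sel <- trace$time >= t_treat + response_window[1L] &
    trace$time <= t_treat + response_window[2L] & is.finite(sm)
  if (sum(sel) < 2L) return(NA_real_)
  dev <- sm[sel] - base
  dev[which.max(abs(dev))]
}

#' Steady-state response of a trace to a treatment (delta_ss)
#'
#' Mean reporter level over a late window (default 3-4 hr after
#' treatment) minus the pre-treatment baseline mean.
#'
#' @inheritParams delta_i
#' @param ss_window c(start, end) of the steady-state window relative to
#'   `t_treat`, minutes.
#' @return signed delta_ss in trace units.
#' @export
delta_ss <- function(trace, t_treat, ss_window = c(180, 240),
                     baseline_window = 30) {
  stopifnot(inherits(trace, "cell_trace"))
  check_coverage(trace, t_treat, baseline_window, t_treat + ss_window[2L])
  base <- window_mean(trace, t_treat - baseline_window, t_treat,
                      closed_right = FALSE)
  late <- window_mean(trace, t_treat + ss_window[1L], t_treat + ss_window[2L])
  if (!is.finite(base) || !is.finite(late)) return(NA_real_)
  late - base
}

#' AMPKAR2 phosphorylation status from the FRET ratio
#'
#' Applies the printed affine linearization of the AMPKAR2 FRET ratio to
#' a phosphorylation-status scale: `2.74 * ratio - 0.59`.  Missing values
#' propagate.
#'
#' @param fret_ratio numeric vector of FRET ratio values.
#' @return numeric vector of phosphorylation-status values.
#' @export
ampkar_phos <- function(fret_ratio) {
  if (any(is.infinite(fret_ratio))) {
    stop("ampkar_phos: non-finite FRET ratio")
  }
  2.74 * fret_ratio - 0.59
}

#' Relative translation activity (RTA) of a translation reporter trace
#'
#' The translation reporter accumulates fluorescence after stabilizer
#' (TMP) addition; its intensity-gain rate is fitted before and after a
#' stimulus and RTA is the ratio of the post-stimulus to pre-stimulus
#' slope.  Slopes are fitted robustly (Theil-Sen by default).
#'
#' @param trace a `cell_trace` of reporter intensity.
#' @param t_tmp time of stabilizer addition, minutes.
#' @param t_stim time of the stimulus, minutes (must exceed `t_tmp`).
#' @param fit_method `"theil_sen"` or `"lm"`.
#' @param slope_floor pre-stimulus slopes at or below this floor make RTA
#'   undefined (`NA` with attribute `reason`).
#' @return RTA ratio (dimensionless), or flagged `NA` when undefined.
#' @export
relative_translation_activity <- function(trace, t_tmp, t_stim,
                                          fit_method = "theil_sen",
                                          slope_floor = 1e-8) {
  stopifnot(inherits(trace, "cell_trace"))
  if (t_tmp >= t_stim) stop("relative_translation_activity: t_tmp must precede t_stim")
  ok <- !trace$missing & is.finite(trace$value)
  pre <- ok & trace$time >= t_tmp & trace$time < t_stim
  post <- ok & trace$time >= t_stim
  if (sum(pre) < 4L || sum(post) < 4L) {
    stop("relative_translation_activity: need >= 4 points in each segment (have ",
         sum(pre), " pre, ", sum(post), " post)")
  }
  fit <- function(sel) {
    if (identical(fit_method, "theil_sen")) {
      theil_sen(trace$time[sel], trace$value[sel])$slope
    } else {
      unname(stats::coef(stats::lm(trace$value[sel] ~ trace$time[sel]))[2L])
    }
  }
  s_pre <- fit(pre)
  s_post <- fit(post)
  if (!is.finite(s_pre) || s_pre <= slope_floor) {
    out <- NA_real_
    attr(out, "reason") <- "pre-stimulus slope nonpositive or below floor"
    return(out)
  }
  s_post / s_pre
}

#' Per-cell response metrics for a whole trajectory set
#'
#' Applies [delta_i()] and [delta_ss()] to every trace.
#'
#' @param set a [trajectory_set()] (interpolated or with missing flags).
#' @param t_treat treatment time, minutes.
#' @param treatment name recorded in the output.
#' @param ... passed to [delta_i()] / [delta_ss()].
#' @return data.frame: `cell_id`, `reporter`, `treatment`, `delta_i`,
#'   `delta_ss`, `condition`, `dose`.
#' @export
response_metrics <- function(set, t_treat, treatment = "treatment", ...) {
  traces <- split_traces(set)
  rows <- lapply(traces, function(tr) {
    di <- tryCatch(delta_i(tr, t_treat, ...), error = function(e) NA_real_)
    ds <- tryCatch(delta_ss(tr, t_treat), error = function(e) NA_real_)
    data.frame(cell_id = tr$cell_id, reporter = tr$reporter,
               treatment = treatment, delta_i = di, delta_ss = ds,
               condition = tr$condition, dose = tr$dose,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
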