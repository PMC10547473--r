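# Volatility (per-cell coefficient of variation) and reporter coupling
# (lagged cross-correlation with a scrambled-pair null).

#' Coefficient of variation of one trace in a post-perturbation window
#'
#' CV = sample standard deviation / mean of the trace values inside a
#' window after the final perturbation (default 2-6 hr), subsampled at
#' every `stride`-th retained point to suppress point-to-point
#' measurement noise.
#'
#' @param trace a `cell_trace`.
#' @param t_perturb time of the final perturbation, minutes.
#' @param window c(start, end) of the window in hours after `t_perturb`.
#' @param stride subsampling stride (2 = every other point).
#' @param phase stride phase: 0 starts at the first retained point.
#' @param min_points minimum strided points required.
#' @return CV (dimensionless); `NA` with attribute `reason` if the window
#'   mean is nonpositive; error if too few points.
#' @export
trace_cv <- function(trace, t_perturb, window = c(2, 6), stride = 2,
                     phase = 0, min_points = 5) {
  stopifnot(inherits(trace, "cell_trace"))
  sel <- trace$time >= t_perturb + window[1L] * 60 &
    trace$time <= t_perturb + window[2L] * 60 &
    !trace$missing & is.finite(trace$value)
  v <- trace$value[sel]
  idx <- seq_along(v)
  v <- v[(idx - 1L) %% stride == phase %% stride]
  if (length(v) < min_points) {
    stop("trace_cv: fewer than ", min_points, " points in the window after striding")
  }
  m <- mean(v)
  if (m <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "window mean nonpositive"
    return(out)
  }
  sd(v) / m
}

#' Cohort volatility summary by condition
#'
#' Per-cell CVs grouped by a condition label, summarized by the median
#' and interquartile range per group.
#'
#' @param set a [trajectory_set()].
#' @param t_perturb final-perturbation time, minutes.
#' @param group_col grouping column (default `"condition"`); `"dose"`
#'   groups by dose.
#' @param ... passed to [trace_cv()].
#' @return list with `cells` (per-cell CV data.frame) and `summary`
#'   (per-group median CV, IQR and n); groups with fewer than 2 cells are
#'   omitted with a warning.
#' @export
cohort_cv <- function(set, t_perturb, group_col = "condition", ...) {
  traces <- split_traces(set)
  cells <- do.call(rbind, lapply(traces, function(tr) {
    cv <- tryCatch(as.numeric(trace_cv(tr, t_perturb, ...)),
                   error = function(e) NA_real_)
    data.frame(cell_id = tr$cell_id, reporter = tr$reporter,
               condition = tr$condition, dose = tr$dose, cv = cv,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  g <- cells[[if (group_col %in% names(cells)) group_col else "condition"]]
  groups <- split(cells$cv, g)
  small <- names(groups)[vapply(groups, function(v) sum(is.finite(v)) < 2L, TRUE)]
  if (length(small)) {
    warning("cohort_cv: omitting group(s) with < 2 cells: ",
            paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  summ <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]][is.finite(groups[[nm]])]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = nm, n = length(v), median_cv = q[2L],
               iqr_lo = q[1L], iqr_hi = q[3L], stringsAsFactors = FALSE)
  }))
  list(cells = cells, summary = summ)
}

#' Lagged Pearson cross-correlation of two series on a shared grid
#'
#' Correlation of the overlapping segments at every integer lag in
#' `[-max_lag, max_lag]`; at positive lag `k`, `y` is taken `k` steps
#' after `x` (so if `y` is a delayed copy of `x`, the optimal lag is
#' positive).  The optimal lag is the argmax of the correlation; ties go
#' to the smallest `|lag|`, then to the negative lag.  Lags whose overlap
#' is shorter than `min_overlap` or has zero variance are undefined (NA)
#' and excluded from the argmax.
#'
#' @param x,y numeric series of equal length (shared time grid).
#' @param max_lag maximum lag searched, steps.
#' @param min_overlap minimum overlap length per lag.
#' @param detrend remove a robust (Theil-Sen) linear trend from each
#'   series before correlating; off by default, matching the analysis
#'   being reproduced.
#' @return list with `lags`, `cor` (per-lag correlations), `best_lag`,
#'   `best_cor`.
#' @export
cross_correlate_pair <- function(x, y, max_lag, min_overlap = 10,
                                 detrend = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (detrend) {
    tt <- seq_len(n)
    for (nm in c("x", "y")) {
      v <- get(nm)
      ok <- is.finite(v)
      if (sum(ok) >= 3L && length(unique(tt[ok])) >= 2L) {
        fit <- theil_sen(tt[ok], v[ok])
        assign(nm, v - (fit$intercept + fit$slope * tt))
      }
    }
  }
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) { xi <- seq_len(n - k); yi <- xi + k }
    else { yi <- seq_len(n + k); xi <- yi - k }
    if (length(xi) < min_overlap) return(NA_real_)
    xs <- x[xi]; ys <- y[yi]
    ok <- is.finite(xs) & is.finite(ys)
    if (sum(ok) < min_overlap) return(NA_real_)
    if (sd(xs[ok]) == 0 || sd(ys[ok]) == 0) return(NA_real_)
    cor(xs[ok], ys[ok])
  }, numeric(1))
  if (all(is.na(cc))) {
    return(list(lags = lags, cor = cc, best_lag = NA_integer_,
                best_cor = NA_real_))
  }
  best <- max(cc, na.rm = TRUE)
  cand <- lags[!is.na(cc) & cc >= best - 1e-12]
  cand <- cand[order(abs(cand), cand)]
  best_lag <- cand[1L]
  list(lags = lags, cor = cc, best_lag = best_lag,
       best_cor = cc[match(best_lag, lags)])
}

trace_matrix <- function(set) {
  traces <- split_traces(set)
  ids <- vapply(traces, function(tr) tr$cell_id, "")
  vals <- lapply(traces, function(tr) {
    v <- tr$value
    v[tr$missing] <- NA_real_
    v
  })
  n <- max(vapply(vals, length, 1L))
  m <- vapply(vals, function(v) c(v, rep(NA_real_, n - length(v))), numeric(n))
  colnames(m) <- ids
  m
}

#' Reporter-coupling analysis across a cohort of cells
#'
#' For every cell present in both sets, finds the optimal lag between its
#' two reporter signals by cross-correlation; reports the median optimal
#' lag across cells and the distribution of per-cell correlations
#' recomputed at that median lag, alongside a scrambled-pair null
#' distribution (signals of randomly paired distinct cells).
#'
#' @param setA,setB [trajectory_set()] objects holding one reporter each,
#'   with matching `cell_id`s.
#' @param max_lag maximum lag searched, steps (default 20 steps, i.e.
#'   about +/- 2 hr at 6-min sampling).
#' @param n_null number of scrambled pairs for the null.
#' @param seed seed for the scrambled pairing.
#' @param min_overlap minimum overlap per lag.
#' @return object of class `coupling_result`: per-cell optimal lags and
#'   peak correlations, `median_lag` (steps), `cor_at_median` (per-cell
#'   correlations at the median lag), and `null` (scrambled-pair
#'   correlation sample at the median lag).
#' @export
coupling_analysis <- function(setA, setB, max_lag = 20, n_null = 1000,
                              seed = 1L, min_overlap = 10) {
  mA <- trace_matrix(setA)
  mB <- trace_matrix(setB)
  only_a <- setdiff(colnames(mA), colnames(mB))
  only_b <- setdiff(colnames(mB), colnames(mA))
  if (length(only_a) || length(only_b)) {
    stop("coupling_analysis: unmatched cell ids: ",
         paste(head(c(only_a, only_b), 10L), collapse = ", "))
  }
  ids <- colnames(mA)
  mB <- mB[, ids, drop = FALSE]
  per <- lapply(ids, function(id)
    cross_correlate_pair(mA[, id], mB[, id], max_lag, min_overlap))
  lags <- vapply(per, function(p) as.numeric(p$best_lag), numeric(1))
  peaks <- vapply(per, function(p) p$best_cor, numeric(1))
  med <- median(lags, na.rm = TRUE)
  # the searched lags are integers; a half-integer median (even cohort) is
  # rounded toward zero
  median_lag <- as.integer(sign(med) * floor(abs(med) + 1e-9))
  cor_at <- vapply(ids, function(id) {
    cc <- cross_correlate_pair(mA[, id], mB[, id], abs(median_lag) + 0L,
                               min_overlap)
    cc$cor[match(median_lag, cc$lags)]
  }, numeric(1))
  null <- if (n_null > 0 && length(ids) >= 2L) {
    scrambled_null(setA, setB, n_pairs = n_null, seed = seed,
                   lag = median_lag, min_overlap = min_overlap)
  } else numeric(0)
  structure(list(cells = data.frame(cell_id = ids, best_lag = lags,
                                    best_cor = peaks,
                                    cor_at_median = unname(cor_at),
                                    stringsAsFactors = FALSE),
                 median_lag = median_lag,
                 max_lag = max_lag,
                 null = null),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("Coupling analysis of", nrow(x$cells), "cells\n")
  cat("  median optimal lag:", x$median_lag, "steps\n")
  cat("  median correlation at median lag:",
      round(median(x$cells$cor_at_median, na.rm = TRUE), 3), "\n")
  cat("  scrambled null: n =", length(x$null), ", median =",
      round(median(x$null, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Scrambled-pair null correlation sample
#'
#' Correlations, at a fixed lag, between the reporter signals of randomly
#' paired *distinct* cells: the no-cell-level-coupling reference
#' distribution.  Pairs are sampled with replacement; a warning is issued
#' if `n_pairs` exceeds the number of distinct ordered pairings.
#'
#' @param setA,setB [trajectory_set()] objects with common cell ids.
#' @param n_pairs number of scrambled pairs to draw.
#' @param seed RNG seed (same seed, same sample).
#' @param lag lag (steps) at which correlations are computed.
#' @param min_overlap minimum overlap per pair.
#' @return numeric vector of `n_pairs` correlations.
#' @export
scrambled_null <- function(setA, setB, n_pairs = 1000, seed = 1L, lag = 0,
                           min_overlap = 10) {
  mA <- trace_matrix(setA)
  mB <- trace_matrix(setB)
  ids <- intersect(colnames(mA), colnames(mB))
  if (length(ids) < 2L) stop("scrambled_null: need >= 2 common cells")
  if (n_pairs > length(ids) * (length(ids) - 1L)) {
    warning("scrambled_null: n_pairs exceeds distinct pairings; sampling with replacement")
  }
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  i <- sample.int(length(ids), n_pairs, replace = TRUE)
  j <- sample.int(length(ids) - 1L, n_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # j != i, uniform over the rest
  vapply(seq_len(n_pairs), function(k) {
    cc <- cross_correlate_pair(mA[, ids[i[k]]], mB[, ids[j[k]]],
                               abs(lag), min_overlap)
    cc$cor[match(lag, cc$lags)]
  }, numeric(1))
}
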