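# Analog vs digital dose-response classification.  A digital (switch-like)
# response shows bimodal per-cell metric distributions at intermediate
# doses; an analog (graded) response shifts a unimodal distribution.  The
# paper-level distinction is visual; here it is formalized as: bimodal iff
# the dip test rejects unimodality (p < 0.05) AND a two-component Gaussian
# mixture beats one component by a BIC margin > 10.  Both thresholds are
# conventions, configurable and always reported.

# EM fit of a k-component univariate Gaussian mixture (k = 1 or 2).
gmm_fit <- function(x, k, max_iter = 300, tol = 1e-8) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x)
    s2 <- mean((x - mu)^2)
    ll <- sum(dnorm(x, mu, sqrt(s2), log = TRUE))
    return(list(loglik = ll, n_par = 2L, means = mu, sds = sqrt(s2),
                weights = 1))
  }
  # deterministic init: split at the median
  lo <- x <= median(x)
  mu <- c(mean(x[lo]), mean(x[!lo]))
  s <- c(sd(x[lo]), sd(x[!lo]))
  s[!is.finite(s) | s < 1e-8] <- sd(x) / 2 + 1e-8
  w <- c(mean(lo), 1 - mean(lo))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * dnorm(x, mu[1L], s[1L])
    d2 <- w[2L] * dnorm(x, mu[2L], s[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s <- sqrt(c(sum(g * (x - mu[1L])^2) / sum(g),
                sum((1 - g) * (x - mu[2L])^2) / sum(1 - g)))
    s <- pmax(s, 1e-6 * sd(x))
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(loglik = ll, n_par = 5L, means = mu, sds = s, weights = w)
}

gmm_bic <- function(fit, n) -2 * fit$loglik + fit$n_par * log(n)

#' Classify a per-cell metric sample as unimodal or bimodal
#'
#' Combines the dip test (Monte Carlo p-value) with a one-vs-two
#' component Gaussian-mixture BIC comparison: the sample is called
#' bimodal iff the dip test rejects unimodality at `p_threshold` AND the
#' two-component mixture is preferred by a BIC margin greater than
#' `bic_margin`.  Both scores are always reported.  Constant samples are
#' unimodal by convention and flagged degenerate.
#'
#' @param values numeric sample of a per-cell metric (n >= 50).
#' @param seed RNG seed for the dip null simulation.
#' @param p_threshold dip-test significance threshold.
#' @param bic_margin required BIC improvement of the 2-component model.
#' @param n_boot Monte Carlo null size for the dip test.
#' @return list with `call` (`"unimodal"` or `"bimodal"`), `dip`,
#'   `dip_p`, `bic1`, `bic2`, `bic_margin` (bic1 - bic2), `degenerate`.
#' @export
classify_modality <- function(values, seed = 1L, p_threshold = 0.05,
                              bic_margin = 10, n_boot = 200) {
  values <- values[is.finite(values)]
  if (length(values) < 50L) {
    stop("classify_modality: need at least 50 values")
  }
  if (var(values) < .Machine$double.eps) {
    return(list(call = "unimodal", dip = 0, dip_p = 1,
                bic1 = NA_real_, bic2 = NA_real_, bic_margin = NA_real_,
                degenerate = TRUE))
  }
  dt <- dip_test(values, n_boot = n_boot, seed = seed)
  f1 <- gmm_fit(values, 1L)
  f2 <- gmm_fit(values, 2L)
  n <- length(values)
  b1 <- gmm_bic(f1, n)
  b2 <- gmm_bic(f2, n)
  margin <- b1 - b2
  call <- if (dt$p.value < p_threshold && margin > bic_margin) "bimodal"
          else "unimodal"
  list(call = call, dip = dt$statistic, dip_p = dt$p.value,
       bic1 = b1, bic2 = b2, bic_margin = margin, degenerate = FALSE)
}

#' Dose-response modality report
#'
#' Classifies the per-cell metric distribution at each dose and calls the
#' overall dose-response "analog" (all doses unimodal with a monotone
#' mean trend), "digital" (bimodality at any dose), or "indeterminate"
#' (unimodal but non-monotone trend).  The trend is the Theil-Sen slope
#' of the per-dose means against dose; monotonicity requires every
#' consecutive change in the mean to agree in sign with the slope (zero
#' changes allowed).
#'
#' @param doses ordered numeric dose levels (>= 3).
#' @param values_by_dose list of numeric vectors, one per dose.
#' @param seed RNG seed for the per-dose dip tests.
#' @param ... passed to [classify_modality()].
#' @return object of class `modality_report`: per-dose table (n, mean,
#'   dip, dip p, BIC margin, call), `overall` call, `trend_slope`.
#' @export
dose_response_summary <- function(doses, values_by_dose, seed = 1L, ...) {
  if (length(doses) < 3L) {
    stop("dose_response_summary: need at least 3 dose levels")
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("dose_response_summary: dose levels must be strictly increasing")
  }
  stopifnot(length(values_by_dose) == length(doses))
  per <- lapply(seq_along(doses), function(i)
    classify_modality(values_by_dose[[i]], seed = seed + i, ...))
  means <- vapply(values_by_dose, function(v) mean(v[is.finite(v)]), numeric(1))
  ns <- vapply(values_by_dose, function(v) sum(is.finite(v)), integer(1))
  tab <- data.frame(
    dose = doses, n = ns, mean = means,
    dip = vapply(per, `[[`, numeric(1), "dip"),
    dip_p = vapply(per, `[[`, numeric(1), "dip_p"),
    bic_margin = vapply(per, `[[`, numeric(1), "bic_margin"),
    call = vapply(per, `[[`, character(1), "call"),
    stringsAsFactors = FALSE)
  slope <- theil_sen(doses, means)$slope
  dm <- diff(means)
  monotone <- all(dm * sign(slope) >= -1e-12) && sign(slope) != 0
  overall <- if (any(tab$call == "bimodal")) "digital"
             else if (monotone) "analog"
             else "indeterminate"
  structure(list(table = tab, overall = overall, trend_slope = slope),
            class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  cat("Dose-response modality:", x$overall,
      "(trend slope", signif(x$trend_slope, 3), ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
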