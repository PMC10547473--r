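# Partial least-squares regression (single response, NIPALS with
# deflation) with cross-validated component selection.  Implemented here
# directly: the variance-explained screening is the analysis of interest
# and no PLS implementation is assumed available.

# Fit PLS1 on preprocessed (centered/scaled) X and centered y.
# Returns loadings for up to ncomp components (fewer if X is exhausted).
pls1_fit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  Xd <- X; yd <- y
  a_eff <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < 1e-12) break
    w <- w / wn
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-12) break
    pl <- crossprod(Xd, tt) / t2
    qq <- sum(yd * tt) / t2
    Xd <- Xd - tt %*% t(pl)
    yd <- yd - qq * tt
    W[, a] <- w; P[, a] <- pl; qv[a] <- qq
    a_eff <- a
  }
  list(W = W[, seq_len(a_eff), drop = FALSE],
       P = P[, seq_len(a_eff), drop = FALSE],
       q = qv[seq_len(a_eff)], ncomp = a_eff)
}

# Regression coefficients of the a-component PLS1 model (on the
# preprocessed scale).
pls1_coef <- function(fit, a) {
  a <- min(a, fit$ncomp)
  if (a == 0L) return(matrix(0, nrow(fit$W), 1L))
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  q <- fit$q[seq_len(a)]
  W %*% solve(crossprod(P, W), q)
}

# Column-wise preprocessing learned on training data: optional natural
# log, then z-scoring.  Returns the transform and its application.
make_preproc <- function(X, log_transform) {
  if (log_transform) X <- log(pmax(X, 1e-12))
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv, log = log_transform)
}

apply_preproc <- function(X, pp) {
  if (pp$log) X <- log(pmax(X, 1e-12))
  sweep(sweep(X, 2L, pp$mu), 2L, pp$sd, "/")
}

#' PLSR percent variance explained of an output column
#'
#' Fits PLS1 models of an output (e.g. OPP protein-synthesis labeling)
#' on a predictor matrix, selects the number of components (dF) as the
#' smallest count within one standard error of the maximal
#' cross-validated R^2, and reports percent variance explained both
#' cross-validated and in-sample.  At the population-average level the
#' cells are first collapsed to per-condition means and evaluation is
#' leave-one-condition-out.  Intensities are natural-log transformed
#' before z-scoring by default (standard for immunofluorescence
#' intensities; toggleable).
#'
#' @param X numeric matrix or data.frame of predictors (one row per
#'   cell).
#' @param y numeric output vector (one value per cell).
#' @param level `"single-cell"` or `"population-average"`.
#' @param conditions condition labels per cell (required for the
#'   population-average level).
#' @param n_folds folds for single-cell cross-validation.
#' @param seed seed for the fold assignment.
#' @param log_transform log-transform intensities before z-scoring.
#' @param max_comp maximum components searched (default: number of
#'   predictors).
#' @return object of class `plsr_report`: `level`, `n` (rows modeled),
#'   `dF`, `r2_cv` and `r2_insample` (percent), `predictors`,
#'   `log_transform`, `n_folds`.
#' @export
plsr_variance_explained <- function(X, y, level = c("single-cell",
                                                    "population-average"),
                                    conditions = NULL, n_folds = 10,
                                    seed = 1L, log_transform = TRUE,
                                    max_comp = NULL) {
  level <- match.arg(level)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  keep <- complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  pred_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)))

  if (level == "population-average") {
    if (is.null(conditions)) {
      stop("plsr_variance_explained: population-average level needs conditions")
    }
    conditions <- conditions[keep]
    Xa <- apply(X, 2L, function(col) tapply(col, conditions, mean))
    ya <- as.numeric(tapply(y, conditions, mean))
    X <- as.matrix(Xa)
    y <- ya
    n_folds <- nrow(X)  # leave-one-condition-out
  }
  n <- nrow(X)
  if (n < 4L) stop("plsr_variance_explained: too few rows")
  if (n < n_folds) n_folds <- n
  if (n_folds < 2L) stop("plsr_variance_explained: need at least 2 folds")
  max_comp <- min(max_comp %||% ncol(X), ncol(X), n - 2L)

  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  folds <- rep_len(seq_len(n_folds), n)[sample.int(n)]

  press <- matrix(0, n_folds, max_comp)
  tssf <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    ppx <- make_preproc(X[tr, , drop = FALSE], log_transform)
    ppy <- make_preproc(matrix(y[tr], ncol = 1L), log_transform)
    Xtr <- apply_preproc(X[tr, , drop = FALSE], ppx)
    ytr <- as.numeric(apply_preproc(matrix(y[tr], ncol = 1L), ppy))
    Xte <- apply_preproc(X[!tr, , drop = FALSE], ppx)
    yte <- as.numeric(apply_preproc(matrix(y[!tr], ncol = 1L), ppy))
    fit <- pls1_fit(Xtr, ytr, max_comp)
    for (a in seq_len(max_comp)) {
      b <- pls1_coef(fit, a)
      press[f, a] <- sum((yte - Xte %*% b)^2)
    }
    tssf[f] <- sum(yte^2)
  }
  r2cv <- 1 - colSums(press) / sum(tssf)
  r2cv_fold <- 1 - sweep(press, 1L, tssf, "/")
  best <- which.max(r2cv)
  se <- sd(r2cv_fold[, best]) / sqrt(n_folds)
  dF <- min(which(r2cv >= r2cv[best] - se))

  pp_all_x <- make_preproc(X, log_transform)
  pp_all_y <- make_preproc(matrix(y, ncol = 1L), log_transform)
  Xz <- apply_preproc(X, pp_all_x)
  yz <- as.numeric(apply_preproc(matrix(y, ncol = 1L), pp_all_y))
  fit_all <- pls1_fit(Xz, yz, max_comp)
  b <- pls1_coef(fit_all, dF)
  r2_in <- 1 - sum((yz - Xz %*% b)^2) / sum(yz^2)

  structure(list(level = level, n = n, dF = as.integer(min(dF, fit_all$ncomp)),
                 r2_cv = 100 * r2cv[dF], r2_insample = 100 * r2_in,
                 r2_cv_by_comp = 100 * r2cv,
                 predictors = pred_names, log_transform = log_transform,
                 n_folds = n_folds, seed = seed),
            class = "plsr_report")
}

#' @export
print.plsr_report <- function(x, ...) {
  cat(sprintf("PLSR (%s): dF = %d, R2(cv) = %.1f%%, R2(in-sample) = %.1f%% [n = %d, %d predictors]\n",
              x$level, x$dF, x$r2_cv, x$r2_insample, x$n,
              length(x$predictors)))
  invisible(x)
}
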