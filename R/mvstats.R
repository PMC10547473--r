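# Stain-table normalization, PLSR subset screening, Theil-Sen fitting and
# the Welch t-test used throughout.

#' Add phospho/total ratio columns to a stain table
#'
#' Scales each phospho stain by its matching total abundance stain,
#' adding a `<stain>_norm` column per pair.  The TFEB C/N column is
#' already a ratio and passes through unchanged.  Cells with zero or
#' missing totals get a missing ratio but are retained for the other
#' columns.
#'
#' @param table a `stain_table` data.frame.
#' @param pairs named character vector mapping phospho column -> total
#'   column; default: the built-in panel pairing (4E-BP1, the two S6
#'   sites, AKT, GSK3beta).
#' @return the table with ratio columns appended.
#' @export
normalize_stains <- function(table, pairs = NULL) {
  if (is.null(pairs)) {
    panel <- stain_panel()
    has_tot <- !is.na(panel$total)
    pairs <- setNames(panel$total[has_tot], panel$stain[has_tot])
  }
  for (ph in names(pairs)) {
    tot <- pairs[[ph]]
    if (!ph %in% names(table) || !tot %in% names(table)) {
      stop("normalize_stains: missing column for pair ", ph, " / ", tot)
    }
    denom <- table[[tot]]
    bad <- !is.finite(denom) | denom == 0
    r <- table[[ph]] / denom
    r[bad] <- NA_real_
    table[[paste0(ph, "_norm")]] <- r
  }
  table
}

#' Measured predictor columns of a stain table
#'
#' The stain columns usable as PLSR predictors: everything except cell
#' ids, condition flags, the OPP output and derived `_norm` ratios.
#'
#' @param table a `stain_table`.
#' @return character vector of column names.
#' @export
stain_predictor_columns <- function(table) {
  setdiff(names(table),
          c("cell_id", "glucose", "glutamine", "insulin", "aa", "OPP",
            grep("_norm$", names(table), value = TRUE)))
}

#' Screen predictor subsets by PLSR variance explained
#'
#' Runs [plsr_variance_explained()] for each named predictor subset at
#' the requested level(s), plus (optionally) every single-predictor
#' model.  Default subsets: `all_stains` (every measured column) and
#' `norm_mtorc1` (the phospho/total-normalized direct mTORC1 targets
#' plus TFEB C/N); ratio columns are created on the fly when needed.
#'
#' @param table a `stain_table` with condition flag columns `glucose`,
#'   `glutamine`, `insulin`, `aa` and an `OPP` column.
#' @param subsets named list of predictor column vectors; `NULL` for the
#'   defaults.
#' @param levels character vector of levels to evaluate.
#' @param singles also fit every single-predictor model (single-cell
#'   level).
#' @param seed fold-assignment seed.
#' @param ... passed to [plsr_variance_explained()].
#' @return data.frame with one row per (subset, level): `subset`,
#'   `level`, `n`, `dF`, `r2_cv`, `r2_insample`.
#' @export
subset_screen <- function(table, subsets = NULL,
                          levels = c("population-average", "single-cell"),
                          singles = FALSE, seed = 1L, ...) {
  if (is.null(subsets)) {
    meas <- stain_predictor_columns(table)
    subsets <- list(
      all_stains = meas,
      norm_mtorc1 = c("p4EBP1_norm", "pS6_235_236_norm",
                      "pS6_240_244_norm", "TFEB_CN"))
  }
  need_norm <- unique(unlist(subsets))
  need_norm <- need_norm[grepl("_norm$", need_norm) & !need_norm %in% names(table)]
  if (length(need_norm)) table <- normalize_stains(table)
  if (singles) {
    for (colnm in stain_predictor_columns(table)) {
      subsets[[paste0("single:", colnm)]] <- colnm
    }
  }
  unknown <- setdiff(unique(unlist(subsets)), names(table))
  if (length(unknown)) {
    stop("subset_screen: unknown column(s): ", paste(unknown, collapse = ", "))
  }
  cond <- interaction(table$glucose, table$glutamine, table$insulin,
                      table$aa, drop = TRUE)
  rows <- list()
  for (nm in names(subsets)) {
    for (lv in levels) {
      rep <- plsr_variance_explained(
        table[, subsets[[nm]], drop = FALSE], table$OPP, level = lv,
        conditions = cond, seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = nm, level = lv, n = rep$n, dF = rep$dF,
        r2_cv = rep$r2_cv, r2_insample = rep$r2_insample,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Theil-Sen robust line fit
#'
#' Slope = median of all pairwise slopes over point pairs with distinct
#' x; intercept = median of `y - slope * x`.  Insensitive to outliers
#' (up to ~29% contamination) and robust to heteroskedastic noise.
#'
#' @param x,y numeric vectors of equal length; at least 2 distinct x
#'   values.
#' @return object of class `line_fit`: `slope`, `intercept`, `method`.
#' @export
theil_sen <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L) {
    stop("theil_sen: need at least 2 distinct x values")
  }
  n <- length(x)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  low <- lower.tri(dx) & dx != 0
  slope <- median(dy[low] / dx[low])
  intercept <- median(y - slope * x)
  structure(list(slope = slope, intercept = intercept, method = "theil_sen"),
            class = "line_fit")
}

#' Welch two-sample t-test (unequal variances)
#'
#' Two-sided t-test with the Satterthwaite degrees-of-freedom
#' approximation; the convention used for every group comparison in the
#' package (significance at p < 0.05).
#'
#' @param a,b numeric samples (each n >= 2; not both of zero variance).
#' @return list with `statistic` (t), `parameter` (df), `p.value`.
#' @export
welch_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_test: each sample needs n >= 2")
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop("welch_test: both samples have zero variance")
  na <- length(a); nb <- length(b)
  sa <- va / na; sb <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  list(statistic = t, parameter = df, p.value = 2 * pt(-abs(t), df))
}
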