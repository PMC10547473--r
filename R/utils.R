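# Internal helpers shared across modules.

# Run downstream code under a fixed RNG seed, restoring the caller's RNG
# state on exit.  Returns a function that performs the restore; callers do
# `restore <- local_seed(seed); on.exit(restore(), add = TRUE)`.
local_seed <- function(seed) {
  if (is.null(seed)) return(function() NULL)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

# Hill function: saturating response of `x` with half-maximum `ec50` and
# exponent `h`; returns values in [0, 1).
hill <- function(x, ec50, h) {
  x <- pmax(x, 0)
  xn <- x^h
  xn / (xn + ec50^h)
}

# Length of the longest run of TRUE in a logical vector (0 if none).
max_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

# Centered 3-point moving average that ignores NA neighbours.
moving_avg3 <- function(v) {
  n <- length(v)
  if (n == 0L) return(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - 1L):min(n, i + 1L)
    vv <- v[idx]
    out[i] <- if (all(is.na(vv))) NA_real_ else mean(vv, na.rm = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
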