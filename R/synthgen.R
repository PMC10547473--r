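# Seeded generators for reporter trajectories, multiplexed stain tables and
# two-channel reporter images with known ground truth.
#
# The generative model mirrors the rheostat picture of cellular mTORC1
# activity: a cell's latent activity is the product of a saturating
# amino-acid ("Rag") term and a saturating growth-factor ("Rheb") term,
# both with nonzero floors, perturbed by a zero-mean mean-reverting
# (Ornstein-Uhlenbeck-like) fluctuation process.  Reporters are lagged
# saturating (Hill) readouts of the latent activity plus measurement
# noise.  All numeric parameter defaults are generator conventions chosen
# to be realistic for this kind of data, not measured quantities; see the
# methods vignette.

#' Reporter readout specification
#'
#' @param ec50 half-maximal latent activity of the readout (latent units).
#' @param hill_exp Hill exponent of the readout.
#' @param out_min output value at zero activity (trace units).
#' @param out_range output dynamic range (trace units).
#' @param lag_min readout lag in minutes.
#' @param noise_sd measurement noise standard deviation (trace units).
#' @param intensity_mean mean raw fluorescence of a trace (arbitrary
#'   units), used by the QC intensity rule.
#' @return list of class `reporter_spec`.
#' @export
reporter_spec <- function(ec50 = 0.15, hill_exp = 1.5, out_min = 0.2,
                          out_range = 1.0, lag_min = 0, noise_sd = 0.03,
                          intensity_mean = 500) {
  stopifnot(ec50 > 0, hill_exp > 0, out_range >= 0, noise_sd >= 0)
  structure(list(ec50 = ec50, hill_exp = hill_exp, out_min = out_min,
                 out_range = out_range, lag_min = lag_min,
                 noise_sd = noise_sd, intensity_mean = intensity_mean),
            class = "reporter_spec")
}

#' Simulation configuration
#'
#' @param n_cells number of cells (>= 1).
#' @param duration total simulated time, minutes (> 0).
#' @param sample_interval sampling interval, minutes (> 0; live-cell data
#'   of this kind are acquired every 6-7 min).
#' @param treatment_schedule a [treatment_schedule()]; stimulus names on
#'   the amino-acid axis are `"aa"`, on the growth-factor axis
#'   `"insulin"` (alias `"gf"`).
#' @param latent_params list with elements `baseline_aa`, `baseline_gf`
#'   (doses in `[0,1]` before the first treatment), `reversion_halftime`
#'   (minutes; fluctuations revert to the mean with this half-time),
#'   `noise_sd` (stationary s.d. of the latent fluctuation), `floor`
#'   (basal occupancy of the Rag and Rheb terms), `k_aa`, `k_gf`
#'   (half-saturation doses of the two input axes).
#' @param reporter_params named list of [reporter_spec()] objects, one per
#'   reporter.
#' @param missing_rate per-point probability of a missing observation.
#' @param max_gap longest run of contiguous missing points the generator
#'   will emit (longer random runs are truncated).
#' @param seed integer seed; the same configuration and seed give
#'   bit-identical output.
#' @param condition optional condition label attached to every trace.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells, duration, sample_interval = 6,
                       treatment_schedule = NULL,
                       latent_params = list(),
                       reporter_params = list(TFEB_TR = reporter_spec()),
                       missing_rate = 0.02, max_gap = 3, seed = 1L,
                       condition = NULL) {
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("sim_config: n_cells must be >= 1")
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("sim_config: duration must be positive")
  }
  if (!is.numeric(sample_interval) || sample_interval <= 0) {
    stop("sim_config: sample_interval must be positive")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("sim_config: missing_rate must lie in [0, 1]")
  }
  if (is.null(treatment_schedule)) {
    treatment_schedule <- treatment_schedule(numeric(0), character(0), numeric(0))
  }
  stopifnot(inherits(treatment_schedule, "treatment_schedule"))
  lp <- list(baseline_aa = 0, baseline_gf = 0, reversion_halftime = 60,
             noise_sd = 0.08, floor = 0.1, k_aa = 0.2, k_gf = 0.2)
  lp[names(latent_params)] <- latent_params
  if (lp$baseline_aa < 0 || lp$baseline_aa > 1 ||
      lp$baseline_gf < 0 || lp$baseline_gf > 1) {
    stop("sim_config: baseline doses must lie in [0, 1]")
  }
  stopifnot(length(reporter_params) >= 1,
            all(vapply(reporter_params, inherits, TRUE, "reporter_spec")))
  if (is.null(names(reporter_params)) || any(names(reporter_params) == "")) {
    stop("sim_config: reporter_params must be a named list")
  }
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 sample_interval = sample_interval,
                 treatment_schedule = treatment_schedule,
                 latent_params = lp, reporter_params = reporter_params,
                 missing_rate = missing_rate, max_gap = as.integer(max_gap),
                 seed = as.integer(seed), condition = condition),
            class = "sim_config")
}

# Map a stimulus name to the input axis it drives.
stimulus_axis <- function(name) {
  nm <- tolower(name)
  if (nm %in% c("aa", "amino_acids", "amino acids", "eaa")) return("aa")
  if (nm %in% c("insulin", "gf", "growth_factor", "growth factor")) return("gf")
  if (nm %in% c("vehicle", "none")) return(NA_character_)
  stop("unknown stimulus name: ", name,
       " (use 'aa' or 'insulin'/'gf', or 'vehicle')")
}

# Piecewise-constant dose of one input axis over the time grid.
dose_series <- function(times, schedule, axis, baseline) {
  d <- rep(baseline, length(times))
  if (nrow(schedule) == 0L) return(d)
  for (i in seq_len(nrow(schedule))) {
    ax <- stimulus_axis(schedule$stimulus[i])
    if (is.na(ax) || ax != axis) next
    d[times >= schedule$time[i]] <- schedule$dose[i]
  }
  d
}

# Deterministic AND-gate mean activity from the two dose series.
latent_mean_series <- function(times, config) {
  lp <- config$latent_params
  aa <- dose_series(times, config$treatment_schedule, "aa", lp$baseline_aa)
  gf <- dose_series(times, config$treatment_schedule, "gf", lp$baseline_gf)
  rag <- lp$floor + (1 - lp$floor) * aa / (aa + lp$k_aa + (aa + lp$k_aa == 0))
  rheb <- lp$floor + (1 - lp$floor) * gf / (gf + lp$k_gf + (gf + lp$k_gf == 0))
  rag * rheb
}

# One cell's zero-mean OU fluctuation sampled on the grid (exact
# discretization; stationary start).
ou_fluctuation <- function(n_steps, dt, halftime, sd_st) {
  if (sd_st == 0) return(numeric(n_steps))
  theta <- log(2) / halftime
  a <- exp(-theta * dt)
  innov_sd <- sd_st * sqrt(1 - a^2)
  eta <- numeric(n_steps)
  eta[1L] <- rnorm(1L, 0, sd_st)
  if (n_steps > 1L) {
    eps <- rnorm(n_steps - 1L, 0, innov_sd)
    for (t in 2:n_steps) eta[t] <- a * eta[t - 1L] + eps[t - 1L]
  }
  eta
}

# Shift a series by `lag` samples (positive lag delays it), padding with
# the edge value.
shift_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0 || n == 0L) return(x)
  if (lag > 0) c(rep(x[1L], min(lag, n)), head(x, max(0L, n - lag)))
  else c(tail(x, max(0L, n + lag)), rep(x[n], min(-lag, n)))
}

# Truncate runs of TRUE longer than max_gap, keeping the first max_gap
# flags of each run.
cap_gap_runs <- function(flag, max_gap) {
  r <- rle(flag)
  pos <- cumsum(c(1L, head(r$lengths, -1L)))
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > max_gap) {
      idx <- (pos[k] + max_gap):(pos[k] + r$lengths[k] - 1L)
      flag[idx] <- FALSE
    }
  }
  flag
}

default_condition_label <- function(config, times) {
  if (!is.null(config$condition)) return(config$condition)
  sch <- config$treatment_schedule
  if (nrow(sch) == 0L) return("untreated")
  paste0(sch$stimulus, "=", sch$dose, collapse = "+")
}

#' Simulate single-cell reporter trajectories
#'
#' Draws one latent activity series per cell (AND-gate mean plus
#' mean-reverting fluctuation) and one trace per cell per configured
#' reporter: a lagged Hill readout of the latent activity plus independent
#' measurement noise, with missing points injected at `missing_rate`
#' (contiguous runs capped at `max_gap`).
#'
#' @param config a [sim_config()].
#' @return list with elements `traces` (a [trajectory_set()]) and `truth`
#'   (latent activity matrix, time grid, true per-reporter lags in samples,
#'   and the deterministic mean-activity series).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  restore <- local_seed(config$seed)
  on.exit(restore(), add = TRUE)

  times <- seq(0, config$duration, by = config$sample_interval)
  nt <- length(times)
  nc <- config$n_cells
  m <- latent_mean_series(times, config)
  lp <- config$latent_params
  reporters <- config$reporter_params
  cond <- default_condition_label(config, times)
  sch <- config$treatment_schedule
  aa_rows <- which(vapply(sch$stimulus, function(s)
    identical(stimulus_axis(s), "aa"), TRUE))
  dose_lab <- if (length(aa_rows)) sch$dose[max(aa_rows)] else
    if (nrow(sch)) sch$dose[nrow(sch)] else lp$baseline_aa

  latent <- matrix(0, nc, nt)
  lag_steps <- vapply(reporters, function(rp)
    as.integer(round(rp$lag_min / config$sample_interval)), 1L)

  blocks <- vector("list", nc * length(reporters))
  bi <- 1L
  for (ci in seq_len(nc)) {
    eta <- ou_fluctuation(nt, config$sample_interval,
                          lp$reversion_halftime, lp$noise_sd)
    lat <- pmax(m + eta, 0)
    latent[ci, ] <- lat
    for (ri in seq_along(reporters)) {
      rp <- reporters[[ri]]
      lat_in <- shift_series(lat, lag_steps[ri])
      val <- rp$out_min + rp$out_range * hill(lat_in, rp$ec50, rp$hill_exp)
      if (rp$noise_sd > 0) val <- val + rnorm(nt, 0, rp$noise_sd)
      miss <- if (config$missing_rate > 0) {
        cap_gap_runs(runif(nt) < config$missing_rate, config$max_gap)
      } else rep(FALSE, nt)
      intens <- rp$intensity_mean * exp(rnorm(1L, 0, 0.2))
      v <- val
      v[miss] <- NA_real_
      blocks[[bi]] <- data.frame(
        cell_id = sprintf("cell_%04d", ci),
        reporter = names(reporters)[ri],
        time_min = times, value = v, missing = miss,
        intensity = intens, condition = cond, dose = dose_lab,
        stringsAsFactors = FALSE)
      bi <- bi + 1L
    }
  }
  df <- do.call(rbind, blocks)
  rownames(df) <- NULL
  truth <- structure(list(time = times, latent = latent,
                          latent_mean = m, lags = lag_steps,
                          config = config),
                     class = "ground_truth")
  list(traces = trajectory_set(df, schedule = config$treatment_schedule),
       truth = truth)
}

#' Simulate two reporters coupled through one latent activity
#'
#' Both reporters read out the same per-cell latent series; the second is
#' delayed by `lag_steps` samples.  Measurement noise is independent
#' between the two channels.  Used as the ground-truth fixture for the
#' reporter-coupling (cross-correlation) analysis.
#'
#' @param config a [sim_config()]; its first one or two `reporter_params`
#'   entries define the two channels (a single entry is reused for both).
#' @param lag_steps integer delay of the second reporter, in samples; must
#'   not exceed half the trace length in magnitude.
#' @return list with `traces` (a [trajectory_set()] holding reporters
#'   `"repA"` and `"repB"`) and `truth` (latent matrix and true lags).
#' @export
simulate_coupled_reporters <- function(config, lag_steps) {
  stopifnot(inherits(config, "sim_config"))
  times <- seq(0, config$duration, by = config$sample_interval)
  if (abs(lag_steps) > length(times) / 2) {
    stop("simulate_coupled_reporters: lag_steps exceeds half the trace length")
  }
  rp <- config$reporter_params
  specA <- rp[[1L]]
  specB <- if (length(rp) >= 2L) rp[[2L]] else rp[[1L]]
  specA$lag_min <- 0
  specB$lag_min <- lag_steps * config$sample_interval
  cfg2 <- config
  cfg2$reporter_params <- list(repA = specA, repB = specB)
  out <- simulate_trajectories(cfg2)
  out$truth$lags <- c(repA = 0L, repB = as.integer(lag_steps))
  out
}

# The measured stain panel: 16 columns per cell.  ec50/hill values encode
# the convention that substrates differ in sensitivity to mTORC1 activity
# (4E-BP1 sensitive, S6 sites insensitive and steep); `driver` names the
# latent input of each phospho stain.
stain_panel <- function() {
  data.frame(
    stain = c("p4EBP1", "pS6_235_236", "pS6_240_244", "pS6K_389",
              "pULK1_757", "TFEB_CN", "pAKT_473", "pGSK3B_9",
              "pACC_79", "pRb_249_252"),
    total = c("t4EBP1", "tS6", "tS6", NA, NA, NA, "tAKT", "tGSK3B", NA, NA),
    driver = c("mtorc1", "mtorc1", "mtorc1", "mtorc1", "mtorc1", "mtorc1",
               "insulin", "insulin", "starvation", "mtorc1"),
    ec50 = c(0.15, 0.55, 0.50, 0.45, 0.25, 0.30, NA, NA, 0.50, 0.50),
    hexp = c(1.5, 3.0, 3.0, 2.5, 1.5, 1.5, NA, NA, 2.0, 1.5),
    stringsAsFactors = FALSE)
}

stain_total_means <- function() {
  c(t4EBP1 = 900, tS6 = 1500, tAKT = 1100, tGSK3B = 1000, tTFEB = 800)
}

# Columns used to build the OPP signal (log scale) and their weights.
opp_weights <- function() {
  c(p4EBP1 = 0.25, pS6_235_236 = 0.10, pS6_240_244 = 0.10,
    pS6K_389 = 0.15, pULK1_757 = 0.30, TFEB_CN = 0.25)
}

#' Simulate a multiplexed immunofluorescence stain table
#'
#' Generates per-cell stain intensities for a 16-column panel under a
#' factorial design of four present/absent stimuli (glucose, glutamine,
#' insulin, essential amino acids).  Each condition sets a latent mTORC1
#' activity through the AND-gate model; phospho stains are total abundance
#' times a substrate-specific Hill response of the latent activity with
#' multiplicative noise.  The OPP-like protein-synthesis column is built,
#' on the log scale, as an exact linear blend of the observed log stain
#' responses plus independent noise scaled so that the explainable
#' variance fraction of log OPP equals `target_r2`.
#'
#' @param config a [sim_config()] (`n_cells` is the total cell count,
#'   split evenly across conditions; `seed` drives all randomness).
#' @param n_conditions number of factorial conditions to use (2..16; the
#'   first rows of the glucose x glutamine x insulin x amino-acid design).
#' @param target_r2 explainable-variance fraction of the OPP column, in
#'   `[0, 1]`.
#' @return list with `table` (a `stain_table` data.frame: `cell_id`, four
#'   condition flags, 15 stain columns and `OPP`) and `truth` (latent
#'   activities, blend weights and `target_r2`).
#' @export
simulate_stain_table <- function(config, n_conditions = 16, target_r2 = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(target_r2) || target_r2 < 0 || target_r2 > 1) {
    stop("simulate_stain_table: target_r2 must lie in [0, 1]")
  }
  if (n_conditions < 2 || n_conditions > 16) {
    stop("simulate_stain_table: n_conditions must be in 2..16")
  }
  restore <- local_seed(config$seed)
  on.exit(restore(), add = TRUE)

  design <- expand.grid(glucose = 0:1, glutamine = 0:1,
                        insulin = 0:1, aa = 0:1)
  design <- design[seq_len(n_conditions), , drop = FALSE]
  n_total <- config$n_cells
  per <- rep(n_total %/% n_conditions, n_conditions)
  if (n_total %% n_conditions) {
    per[seq_len(n_total %% n_conditions)] <- per[1L] + 1L
  }
  lp <- config$latent_params
  flags <- design[rep(seq_len(n_conditions), per), , drop = FALSE]
  rownames(flags) <- NULL
  n <- nrow(flags)

  rag <- lp$floor + (1 - lp$floor) * flags$aa
  rheb <- lp$floor + (1 - lp$floor) * flags$insulin
  energy <- 0.4 + 0.6 * (flags$glucose + flags$glutamine) / 2
  m <- rag * rheb * energy
  latent <- pmax(m + rnorm(n, 0, lp$noise_sd), 0.02)

  panel <- stain_panel()
  tot_mu <- stain_total_means()
  tab <- data.frame(cell_id = sprintf("cell_%06d", seq_len(n)), flags,
                    stringsAsFactors = FALSE)
  totals <- lapply(names(tot_mu), function(nm)
    tot_mu[[nm]] * exp(rnorm(n, 0, 0.25)))
  names(totals) <- names(tot_mu)

  for (k in seq_len(nrow(panel))) {
    st <- panel$stain[k]
    drv <- panel$driver[k]
    frac <- switch(drv,
      mtorc1 = 0.05 + 0.95 * hill(latent, panel$ec50[k], panel$hexp[k]),
      insulin = 0.05 + 0.95 * (0.15 + 0.85 * flags$insulin),
      starvation = 0.05 + 0.95 * hill(1 - latent, panel$ec50[k], panel$hexp[k]))
    if (st == "TFEB_CN") {
      tab[[st]] <- (0.3 + 1.2 * hill(latent, panel$ec50[k], panel$hexp[k])) *
        exp(rnorm(n, 0, 0.10))
    } else {
      tot <- if (!is.na(panel$total[k])) totals[[panel$total[k]]] else
        1000 * exp(rnorm(n, 0, 0.25))
      tab[[st]] <- tot * frac * exp(rnorm(n, 0, 0.10))
    }
  }
  for (nm in names(totals)) tab[[nm]] <- totals[[nm]]

  w <- opp_weights()
  s <- rowSums(vapply(names(w), function(nm) w[[nm]] * log(tab[[nm]]),
                      numeric(n)))
  s_z <- (s - mean(s)) / sd(s)
  sig_sd <- 0.35
  opp_log <- if (target_r2 == 0) {
    log(800) + rnorm(n, 0, sig_sd)
  } else if (target_r2 == 1) {
    log(800) + sig_sd * s_z
  } else {
    noise_sd <- sig_sd * sqrt((1 - target_r2) / target_r2)
    log(800) + sig_sd * s_z + rnorm(n, 0, noise_sd)
  }
  tab$OPP <- exp(opp_log)
  class(tab) <- c("stain_table", "data.frame")
  truth <- structure(list(latent = latent, target_r2 = target_r2,
                          weights = w, design = design,
                          latent_mean = m),
                     class = "ground_truth")
  list(table = tab, truth = truth)
}

#' Simulate a two-channel reporter image field
#'
#' Places `n_cells` non-overlapping round nuclei on a jittered grid.
#' Channel 1 is a nuclear marker (bright discs on a dim background);
#' channel 2 is the translocation reporter with the requested nuclear and
#' cytoplasmic intensities (cytoplasm is an annulus of width `cyto_width`
#' around each nucleus).  Gaussian read noise is added to both channels.
#'
#' @param n_cells number of cells to place.
#' @param nucleus_radius nuclear radius in pixels (>= 3).
#' @param intensities length-2 numeric: nuclear and cytoplasmic reporter
#'   intensity.
#' @param noise_sd Gaussian noise s.d. added per pixel.
#' @param seed integer seed.
#' @param cyto_width width of the cytoplasmic annulus, pixels.
#' @param field optional c(rows, cols) of the image; an error is raised if
#'   `n_cells` cannot be placed without overlap.
#' @return list with matrices `nuclear` and `reporter` and `truth`
#'   (ground-truth label matrix, centers, radius and true C/N ratio).
#' @export
simulate_images <- function(n_cells, nucleus_radius = 10,
                            intensities = c(nuclear = 100, cytoplasmic = 50),
                            noise_sd = 0, seed = 1L, cyto_width = 8,
                            field = NULL) {
  if (nucleus_radius < 3) stop("simulate_images: nucleus_radius must be >= 3")
  stopifnot(n_cells >= 1, length(intensities) == 2)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)

  spacing <- 2 * (nucleus_radius + cyto_width) + 5
  if (is.null(field)) {
    ncc <- ceiling(sqrt(n_cells))
    nrc <- ceiling(n_cells / ncc)
    field <- c(nrc * spacing, ncc * spacing)
  } else {
    nrc <- floor(field[1L] / spacing)
    ncc <- floor(field[2L] / spacing)
    if (nrc * ncc < n_cells) {
      stop("simulate_images: cannot place ", n_cells,
           " cells without overlap in a ", field[1L], "x", field[2L], " field")
    }
  }

  jit <- 2
  centers <- t(vapply(seq_len(n_cells), function(i) {
    gr <- (i - 1L) %/% ncc
    gc <- (i - 1L) %% ncc
    c(row = gr * spacing + spacing / 2 + runif(1, -jit, jit),
      col = gc * spacing + spacing / 2 + runif(1, -jit, jit))
  }, numeric(2)))

  nr <- field[1L]; nc <- field[2L]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  labels <- matrix(0L, nr, nc)
  nuclear <- matrix(5, nr, nc)
  reporter <- matrix(0, nr, nc)
  for (i in seq_len(n_cells)) {
    d2 <- (rows - centers[i, 1L])^2 + (cols - centers[i, 2L])^2
    nuc <- d2 <= nucleus_radius^2
    cyt <- d2 <= (nucleus_radius + cyto_width)^2 & !nuc
    labels[nuc] <- i
    nuclear[nuc] <- 100
    reporter[nuc] <- intensities[[1L]]
    reporter[cyt] <- intensities[[2L]]
  }
  if (noise_sd > 0) {
    nuclear <- nuclear + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    reporter <- reporter + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  truth <- structure(list(labels = labels, centers = centers,
                          nucleus_radius = nucleus_radius,
                          intensities = intensities,
                          cyto_width = cyto_width,
                          cn_true = intensities[[2L]] / intensities[[1L]]),
                     class = "ground_truth")
  list(nuclear = nuclear, reporter = reporter, truth = truth)
}
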