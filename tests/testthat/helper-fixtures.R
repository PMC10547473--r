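# Shared fixture builders.  Everything is generated in code; no files.

# A single trace with a clean step of `step` at t_treat on a 6-min grid.
step_trace <- function(step = 0.5, t_treat = 120, base = 1.0,
                       duration = 600, interval = 6, noise_sd = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = interval)
  v <- ifelse(tt < t_treat, base, base + step)
  if (noise_sd > 0) v <- v + rnorm(length(tt), 0, noise_sd)
  cell_trace(tt, v)
}

# Assemble a trajectory_set from a list of cell_trace objects.
set_from_traces <- function(traces, background = NA_real_) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, reporter = tr$reporter,
               time_min = tr$time, value = tr$value, missing = tr$missing,
               intensity = tr$intensity, condition = tr$condition,
               dose = tr$dose, stringsAsFactors = FALSE)
  }))
  trajectory_set(df, background = background)
}

# Binary image with discs at the given centers (matrix rows = y).
disc_image <- function(nr, nc, centers, radius, value = 100, bg = 0) {
  rr <- matrix(rep(seq_len(nr), nc), nr)
  cc <- matrix(rep(seq_len(nc), each = nr), nr)
  img <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    img[(rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2] <- value
  }
  img
}

# Generator configuration for the starved, fluctuation-rich regime used
# by the coupling and volatility fixtures (amino acids limiting, insulin
# present).
starved_config <- function(n_cells, duration = 720, noise_sd = 0.25,
                           latent_sd = 0.15, seed = 1L) {
  sim_config(n_cells = n_cells, duration = duration,
             latent_params = list(baseline_aa = 0.05, baseline_gf = 1,
                                  noise_sd = latent_sd),
             reporter_params = list(r = reporter_spec(noise_sd = noise_sd)),
             missing_rate = 0, seed = seed)
}

# Split a coupled-reporter simulation into the two per-reporter sets.
coupled_sets <- function(cp) {
  list(A = trajectory_set(cp$traces[cp$traces$reporter == "repA", ]),
       B = trajectory_set(cp$traces[cp$traces$reporter == "repB", ]))
}
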