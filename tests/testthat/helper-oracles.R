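# Independent oracles and shared fixtures for the test suite.

# All-pairs periodic contact detection: the O(n^2) reference against which
# the grid-based search is contracted.
brute_contacts <- function(x, y, radius, geometry, reach = 0) {
  n <- length(x)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- lateral_distance(x[i], x[j], geometry)
      d <- sqrt(dx^2 + (y[i] - y[j])^2)
      if (d < radius[i] + radius[j] + reach)
        out <- rbind(out, c(i, j))
    }
  }
  colnames(out) <- c("i", "j")
  out
}

# Random cell configuration inside a geometry.
random_state <- function(n, geometry, r_range = c(4, 7.5), mature_p = 0.5) {
  data.frame(
    id = seq_len(n),
    x = runif(n, 0, geometry$width),
    y = runif(n, 0, geometry$height),
    radius = runif(n, r_range[1], r_range[2]),
    mature = runif(n) < mature_p,
    label = FALSE, clone = 0L)
}

# A hand-placed toy state builder (columns of the snapshot schema).
toy_state <- function(x, y, radius = 5, mature = FALSE, label = FALSE,
                      clone = 0L, phase = NULL) {
  n <- length(x)
  df <- data.frame(
    id = seq_len(n), x = x, y = y,
    radius = rep_len(radius, n),
    mature = rep_len(mature, n),
    label = rep_len(label, n),
    clone = rep_len(clone, n))
  if (!is.null(phase)) df$phase <- rep_len(phase, n)
  df
}

# A small crypt configuration that fills quickly: used wherever the test
# needs full engine dynamics but not the full-size crypt.
small_config <- function(model = "niche", ...) {
  crypt_config(model,
               geometry = list(n_circumference = 6L, n_length = 10L),
               mechanics = if (model == "niche")
                 list(attr_over_eta = 0.5e-8, attr_distance = 0.5,
                      lateral_migration = TRUE)
               else list(attr_over_eta = 1.0e-8, attr_distance = 0,
                         lateral_migration = FALSE, stem_attached = TRUE),
               run = list(measurement_days = 1, max_hours = 400),
               ...)
}

# Cross-file cache for expensive calibrated runs (populated by whichever
# test file needs them first; test files run in one session).
.run_cache <- new.env(parent = emptyenv())

cached_runs <- function(key, config, seeds, ...) {
  if (!exists(key, envir = .run_cache)) {
    runs <- lapply(seeds, function(s) run_crypt(config, seed = s, ...))
    assign(key, runs, envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

niche296_runs <- function(n = 10) {
  cfg <- crypt_scenario("niche-run296")
  cached_runs("niche296", cfg, seeds = seq_len(n))
}

pedigree13_runs <- function(n = 3) {
  cfg <- crypt_scenario("pedigree-run13")
  cfg$run$measurement_days <- 1   # onset + one day is enough for reuse here
  cached_runs("pedigree13", cfg, seeds = seq_len(n))
}
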