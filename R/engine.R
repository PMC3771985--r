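#' Run one crypt simulation
#'
#' Initialises one row of 22 cells at the crypt base (stem cells for the
#' pedigree model, proliferative cells for the niche model, with
#' unsynchronised cycle clocks), then advances the simulation in fixed steps
#' of \code{mechanics$dt} seconds.  Each step applies, in order: cell-cycle
#' advance and growth, niche fate checks, divisions, one synchronous
#' mechanics step, and removal of cells whose centre has passed the orifice.
#' Hourly cell counts are recorded; steady state is declared when the 12-h
#' moving-average gradient of total cell number, having first been clearly
#' positive, falls back below the tolerance.  The run then continues for the
#' measurement window (default 3 simulated days) and stops.
#'
#' The run is fully reproducible from \code{(config, seed)}.
#'
#' @param config a [crypt_config()].
#' @param seed integer seed for this run's random stream.
#' @param li optional labelling-index experiment: a list with
#'   \code{mark_hour} (hours after steady-state onset at which all S-phase
#'   cells are labelled, default 0) and \code{chase} (hours from marking to
#'   the final snapshot, default 1).  The run stops at the end of the chase.
#' @param clones optional clonal-marking experiment: a list with \code{n}
#'   (clones to mark in the base row, default 4) and \code{mark_hour}
#'   (hours after onset, default 0); marks are heritable.
#' @param snapshot_hours integer vector of absolute simulation hours at
#'   which to keep full per-cell snapshots.
#' @return an object of class \code{crypt_run}: \code{series} (hourly
#'   data.frame with total/proliferative/mature/stem counts, births and
#'   exits), \code{onset} (steady-state onset hour, \code{NA} if never
#'   reached), \code{state} (final per-cell data.frame), \code{snapshots},
#'   \code{reached_steady_state}, plus the config and seed.
#' @export
#' @examples
#' \donttest{
#' cfg <- crypt_scenario("niche-run296")
#' run <- run_crypt(cfg, seed = 1)
#' summary(run)
#' }
run_crypt <- function(config, seed = 1L, li = NULL, clones = NULL,
                      snapshot_hours = numeric(0)) {
  validate_config(config)
  geo <- config_geometry(config)
  m <- config$mechanics; cy <- config$cycle; l <- config$lineage
  r <- config$run
  cfg <- list(
    width = geo$width, height = geo$height,
    n_circ = geo$n_circumference, n_len = geo$n_length,
    k = m$k_over_eta, attr = m$attr_over_eta * 1e6,
    attr_dist = m$attr_distance, delta_eq = m$delta_eq, dt = m$dt,
    active = m$active_migration, lateral = m$lateral_migration,
    stem_attached = m$stem_attached, drift = m$drift_over_eta * 1e6,
    stem_g1 = cy$stem$g1, stem_s = cy$stem$s, stem_g2 = cy$stem$g2,
    stem_m = cy$stem$m,
    ta_g1 = cy$ta$g1, ta_s = cy$ta$s, ta_g2 = cy$ta$g2, ta_m = cy$ta$m,
    r_min = cy$r_min, r_max = cy$r_max, mean_radius = geo$mean_radius,
    deterministic_cycle = l$deterministic_cycle,
    vertical_only = cy$vertical_division_only,
    model = if (config$model == "pedigree") 0L else 1L,
    n_gen = l$n_ta_generations, region = l$proliferation_region,
    only_new_mature = l$only_new_cells_mature,
    use_pdf = l$position_pdf, pdf_hw = l$pdf_half_width,
    max_hours = r$max_hours, measure_hours = r$measurement_days * 24,
    window = r$steady_state_window, ss_tol = r$steady_state_tol,
    li_enabled = !is.null(li),
    li_mark = if (is.null(li)) 0 else li$mark_hour %||% 0,
    li_chase = if (is.null(li)) 1 else li$chase %||% 1,
    clones_n = if (is.null(clones)) 0L else as.integer(clones$n %||% 4L),
    clones_mark = if (is.null(clones)) 0 else clones$mark_hour %||% 0)
  set.seed(as.integer(seed))
  raw <- run_crypt_cpp(cfg, as.numeric(snapshot_hours))
  out <- list(
    series = as.data.frame(raw$series),
    onset = if (is.na(raw$onset)) NA_real_ else raw$onset,
    state = decode_state(raw$state),
    snapshots = lapply(raw$snapshots, decode_state),
    reached_steady_state = raw$reached_steady_state,
    config = config, geometry = geo, seed = as.integer(seed))
  if (!out$reached_steady_state)
    warning("run did not reach steady state before max_hours = ",
            r$max_hours, " h")
  class(out) <- "crypt_run"
  out
}

decode_state <- function(s) {
  phases <- c("A", "S", "G2", "M", "G0")
  classes <- c("stem", "TA")
  data.frame(
    id = s$id, x = s$x, y = s$y, radius = s$radius,
    phase = phases[s$phase + 1L], clock = s$clock,
    class = classes[s$class + 1L], generation = s$generation,
    mature = s$phase == 4L,
    label = s$label == 1L, clone = s$clone)
}

#' Detect steady state in an hourly cell-count series
#'
#' The gradient of total cell number is measured with a moving-average
#' window: \code{g(t) = (N(t) - N(t - w)) / w} over \code{w} hours.  Steady
#' state is declared at the first time at which \code{|g| < tol}
#' \emph{after} the gradient has been clearly positive (\code{g > tol}) for
#' a sustained full window, so neither the flat transient before the first
#' row of cells completes its cycle nor brief division lulls in the small
#' founding population can trigger the detector.
#'
#' @param total hourly total cell counts.
#' @param hours sampling times; defaults to \code{0, 1, 2, ...}.
#' @param window window length in hours (default 12).
#' @param tol gradient tolerance in cells/hour (default 0.5).
#' @return the onset time, or \code{NA} if steady state was not reached.
#' @export
#' @examples
#' n <- c(rep(22, 10), seq(22, 700, by = 20), rep(700, 30))
#' detect_steady_state(n)
detect_steady_state <- function(total, hours = seq_along(total) - 1,
                                window = 12, tol = 0.5) {
  stopifnot(length(total) == length(hours))
  if (length(total) <= window) return(NA_real_)
  step <- diff(hours)
  if (length(step) && any(abs(step - step[1]) > 1e-9))
    stop("series must be sampled at fixed intervals")
  w <- as.integer(round(window / step[1]))
  if (w < 1 || length(total) <= w) return(NA_real_)
  seen_positive <- FALSE
  pos_run <- 0L
  for (i in (w + 1):length(total)) {
    g <- (total[i] - total[i - w]) / (hours[i] - hours[i - w])
    if (g > tol) {
      pos_run <- pos_run + 1L
      if (pos_run >= w) seen_positive <- TRUE
    } else if (!seen_positive) {
      pos_run <- 0L
    }
    if (seen_positive && abs(g) < tol) return(hours[i])
  }
  NA_real_
}

#' Run replicated crypt simulations
#'
#' Runs \code{replicates} independent simulations with seeds
#' \code{seed, seed + 1, ...} (one stream per replicate, so each replicate
#' is individually reproducible) and aggregates their performance measures.
#'
#' @inheritParams run_crypt
#' @param replicates number of replicate runs; defaults to
#'   \code{config$run$replicates}.
#' @param targets normalisation targets, see [crypt_targets()].
#' @return an object of class \code{crypt_sim} with the individual
#'   \code{runs}, the per-run \code{measures} data.frame, and the replicate
#'   seeds.
#' @export
simulate_crypt <- function(config, replicates = NULL, seed = 1L,
                           targets = crypt_targets()) {
  replicates <- replicates %||% config$run$replicates
  seeds <- as.integer(seed) + seq_len(replicates) - 1L
  runs <- lapply(seeds, function(s) run_crypt(config, seed = s))
  measures <- do.call(rbind, lapply(runs, function(r) {
    as.data.frame(performance_summary(r, targets = targets))
  }))
  measures$seed <- seeds
  structure(list(runs = runs, measures = measures, config = config,
                 seeds = seeds, targets = targets),
            class = "crypt_sim")
}

#' @export
print.crypt_run <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("Crypt run (%s model, seed %d): %d cells after %g h\n",
              x$config$model, x$seed, nrow(x$state),
              x$series$hour[n]))
  if (is.na(x$onset)) cat("  steady state: not reached\n")
  else cat(sprintf("  steady state onset: %g h\n", x$onset))
  invisible(x)
}

#' @export
summary.crypt_run <- function(object, ...) {
  ps <- performance_summary(object)
  cat(sprintf("Crypt run (%s model, seed %d)\n", object$config$model,
              object$seed))
  if (is.na(object$onset)) {
    cat("  steady state not reached; no measurement window\n")
    return(invisible(ps))
  }
  cat(sprintf("  steady state onset %g h; measures over the following %g h:\n",
              object$onset, ps$window_hours))
  cat(sprintf("  cells %.1f (proliferative %.1f, mature %.1f)\n",
              ps$n_cells, ps$proliferative, ps$n_cells - ps$proliferative))
  cat(sprintf("  production %.2f cells/h, mature proportion %.3f, mature order %.3f\n",
              ps$production_rate, ps$mature_proportion, ps$mature_order))
  invisible(ps)
}

#' @export
print.crypt_sim <- function(x, ...) {
  cat(sprintf("Replicated crypt simulation (%s model, %d replicates)\n",
              x$config$model, length(x$runs)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.crypt_sim <- function(object, ...) {
  m <- object$measures
  num <- c("n_cells", "proliferative", "production_rate",
           "mature_proportion", "mature_order")
  out <- data.frame(
    measure = num,
    mean = vapply(num, function(v) mean(m[[v]], na.rm = TRUE), 0),
    sd = vapply(num, function(v) sd(m[[v]], na.rm = TRUE), 0),
    normalised = NA_real_)
  tg <- object$targets
  tgv <- c(tg$n_cells, NA, tg$production_rate,
           1 - tg$proliferative / tg$n_cells, NA)
  out$normalised <- out$mean / tgv
  rownames(out) <- NULL
  out
}

#' Plot a crypt run
#'
#' Two panels: the hourly cell-count trajectories (total, proliferative,
#' mature) with the steady-state onset marked, and the final spatial state
#' with cells drawn as discs (proliferative dark, mature light; stem cells
#' outlined).
#'
#' @param x a \code{crypt_run}.
#' @param which \code{"both"}, \code{"series"} or \code{"state"}.
#' @param ... ignored.
#' @export
plot.crypt_run <- function(x, which = c("both", "series", "state"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "series")) {
    s <- x$series
    graphics::plot(s$hour, s$total, type = "l", lwd = 2,
                   xlab = "time (h)", ylab = "cells",
                   main = paste(x$config$model, "model"))
    graphics::lines(s$hour, s$proliferative, col = "steelblue")
    graphics::lines(s$hour, s$mature, col = "darkorange")
    if (!is.na(x$onset)) graphics::abline(v = x$onset, lty = 2)
    graphics::legend("topleft", bty = "n", lwd = c(2, 1, 1),
                     col = c("black", "steelblue", "darkorange"),
                     legend = c("total", "proliferative", "mature"))
  }
  if (which %in% c("both", "state")) plot_state(x$state, x$geometry)
  invisible(x)
}

#' Draw a per-cell snapshot
#'
#' @param state a per-cell data.frame as found in \code{crypt_run$state}.
#' @param geometry a [crypt_geometry()].
#' @param main plot title.
#' @export
plot_state <- function(state, geometry, main = "crypt snapshot") {
  cols <- ifelse(state$mature, "navajowhite",
                 ifelse(state$class == "stem", "navy", "indianred"))
  if (any(state$clone > 0))
    cols[state$clone > 0] <-
      grDevices::hcl.colors(max(state$clone), "Dark 3")[
        state$clone[state$clone > 0]]
  graphics::plot(NA, xlim = c(0, geometry$width),
                 ylim = c(0, geometry$height), asp = 1,
                 xlab = "circumference (um)", ylab = "crypt axis (um)",
                 main = main)
  graphics::symbols(state$x, state$y, circles = state$radius,
                    inches = FALSE, add = TRUE, bg = cols,
                    fg = ifelse(state$label, "black", "grey40"))
  invisible(state)
}

#' @export
plot.crypt_sim <- function(x, ...) {
  s0 <- x$runs[[1]]$series
  graphics::plot(NA, xlim = range(s0$hour), ylim = c(0, max(s0$total) * 1.2),
                 xlab = "time (h)", ylab = "total cells",
                 main = sprintf("%s model, %d replicates", x$config$model,
                                length(x$runs)))
  for (r in x$runs)
    graphics::lines(r$series$hour, r$series$total,
                    col = grDevices::adjustcolor("steelblue", 0.5))
  invisible(x)
}
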