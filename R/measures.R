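#' Normalisation targets for the performance measures
#'
#' The reference crypt of the descending colon maintains about 704 cells
#' (32 rows of 22), of which about 200 are proliferative.  The production
#' target follows from steady-state turnover: ~200 proliferative cells with
#' a mean transit-amplifying cycle of ~15.5 h replace themselves at about
#' 13 cells/hour; the value is configurable.  The mature-order acceptance
#' threshold defaults to 0.90.
#'
#' @param n_cells target total cell number.
#' @param proliferative target proliferative cell number.
#' @param production_rate target cell production rate (cells/hour).
#' @param mature_order minimum acceptable mature-cell order.
#' @return a named list of targets.
#' @export
crypt_targets <- function(n_cells = 704, proliferative = 200,
                          production_rate = 13, mature_order = 0.90) {
  list(n_cells = n_cells, proliferative = proliferative,
       production_rate = production_rate, mature_order = mature_order)
}

#' Order of a single cell
#'
#' The order of cell \code{i} is the fraction of its contact neighbours that
#' are mature; a cell with no neighbours has order 1 by convention.  The
#' order of the mature population is the mean over mature cells
#' ([mature_cell_order()]): near 1 for a perfectly segregated mature
#' compartment, and necessarily below 1 wherever proliferating and mature
#' cells touch.
#'
#' @param state per-cell data.frame with columns \code{x}, \code{y},
#'   \code{radius} and logical \code{mature}.
#' @param geometry a [crypt_geometry()].
#' @return numeric vector of per-cell order values in \code{[0, 1]}.
#' @export
cell_order <- function(state, geometry) {
  n <- nrow(state)
  pairs <- find_contacts(state$x, state$y, state$radius, geometry, reach = 0)
  nn <- integer(n)     # neighbours
  nm <- integer(n)     # mature neighbours
  if (nrow(pairs)) {
    i <- pairs[, 1]; j <- pairs[, 2]
    nn <- tabulate(i, n) + tabulate(j, n)
    nm <- tabulate(i[state$mature[j]], n) + tabulate(j[state$mature[i]], n)
  }
  ifelse(nn == 0, 1, nm / pmax(nn, 1L))
}

#' Mean order of the mature cell population
#'
#' @inheritParams cell_order
#' @return the arithmetic mean of [cell_order()] over mature cells, or
#'   \code{NA} if there are no mature cells.
#' @export
mature_cell_order <- function(state, geometry) {
  if (!any(state$mature)) return(NA_real_)
  mean(cell_order(state, geometry)[state$mature])
}

#' Performance measures of a run
#'
#' Time-averages the hourly series over the measurement window (from the
#' steady-state onset for \code{measurement_days}): total cell number,
#' proliferative cell number, production rate (cells leaving the crypt per
#' hour) and mature proportion; the mature-cell order is computed from the
#' final spatial state.  Normalised variants divide each measure by its
#' target.  Runs that never reached steady state are flagged
#' (\code{steady = FALSE}) and report \code{NA} measures.
#'
#' @param run a \code{crypt_run}.
#' @param targets a [crypt_targets()] list.
#' @return a one-row list (class \code{performance_measures}) with fields
#'   \code{n_cells}, \code{proliferative}, \code{production_rate},
#'   \code{mature_proportion}, \code{mature_order}, their \code{norm_*}
#'   counterparts, \code{window_hours} and \code{steady}.
#' @export
performance_summary <- function(run, targets = crypt_targets()) {
  stopifnot(inherits(run, "crypt_run"))
  if (is.na(run$onset)) {
    out <- list(n_cells = NA_real_, proliferative = NA_real_,
                production_rate = NA_real_, mature_proportion = NA_real_,
                mature_order = NA_real_, norm_n_cells = NA_real_,
                norm_production = NA_real_, norm_mature_proportion = NA_real_,
                window_hours = 0, steady = FALSE)
    class(out) <- "performance_measures"
    return(out)
  }
  s <- run$series
  win <- s$hour > run$onset &
    s$hour <= run$onset + run$config$run$measurement_days * 24
  s <- s[win, , drop = FALSE]
  out <- list(
    n_cells = mean(s$total),
    proliferative = mean(s$proliferative),
    production_rate = mean(s$exits),
    mature_proportion = mean(s$mature / s$total),
    mature_order = mature_cell_order(run$state, run$geometry),
    window_hours = nrow(s), steady = TRUE)
  out$norm_n_cells <- out$n_cells / targets$n_cells
  out$norm_production <- out$production_rate / targets$production_rate
  out$norm_mature_proportion <-
    out$mature_proportion / (1 - targets$proliferative / targets$n_cells)
  class(out) <- "performance_measures"
  out
}

#' @export
print.performance_measures <- function(x, ...) {
  if (!x$steady) {
    cat("performance measures unavailable: run never reached steady state\n")
    return(invisible(x))
  }
  cat(sprintf(
    "cells %.1f (norm %.3f) | proliferative %.1f | production %.2f/h (norm %.3f)\n",
    x$n_cells, x$norm_n_cells, x$proliferative, x$production_rate,
    x$norm_production))
  cat(sprintf("mature proportion %.3f (norm %.3f) | mature order %.3f\n",
              x$mature_proportion, x$norm_mature_proportion, x$mature_order))
  invisible(x)
}

#' @export
as.data.frame.performance_measures <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Labelling-index profile of a single snapshot
#'
#' Bins cells into the crypt's rows by their centre and reports the labelled
#' proportion per row.  Empty rows are \code{NA}, not 0.
#'
#' @param state per-cell data.frame with \code{y} and logical \code{label}.
#' @param geometry a [crypt_geometry()].
#' @return data.frame with \code{row} (0-based), \code{cells},
#'   \code{labelled} and \code{proportion}.
#' @export
li_profile <- function(state, geometry) {
  rows <- row_index(state$y, geometry)
  nl <- geometry$n_length
  cells <- tabulate(rows + 1L, nl)
  labelled <- tabulate(rows[state$label] + 1L, nl)
  data.frame(row = 0:(nl - 1L), cells = cells, labelled = labelled,
             proportion = ifelse(cells == 0, NA_real_, labelled / cells))
}

#' Simulate a labelling-index experiment
#'
#' Each replicate is grown to steady state; all S-phase cells are then
#' labelled, the label is inherited at division and never cleared, and after
#' a chase (default 1 h) the proportion of labelled cells at each crypt row
#' is recorded.  The replicate mean and standard deviation per row are
#' returned.
#'
#' @inheritParams simulate_crypt
#' @param mark_hour hours after steady-state onset at which to mark.
#' @param chase chase duration in hours.
#' @return an object of class \code{li_profile_set}: \code{profile}
#'   (data.frame with per-row \code{mean} and \code{sd}),
#'   \code{replicates} (matrix rows x replicates), and the config.
#' @export
simulate_li <- function(config, replicates = NULL, seed = 1L,
                        mark_hour = 0, chase = 1) {
  replicates <- replicates %||% config$run$replicates
  seeds <- as.integer(seed) + seq_len(replicates) - 1L
  geo <- config_geometry(config)
  mat <- sapply(seeds, function(s) {
    run <- run_crypt(config, seed = s,
                     li = list(mark_hour = mark_hour, chase = chase))
    li_profile(run$state, geo)$proportion
  })
  mat <- matrix(mat, nrow = geo$n_length)
  prof <- data.frame(
    row = 0:(geo$n_length - 1L),
    mean = rowMeans(mat, na.rm = TRUE),
    sd = apply(mat, 1, sd, na.rm = TRUE))
  structure(list(profile = prof, replicates = mat, config = config,
                 seeds = seeds, chase = chase),
            class = "li_profile_set")
}

#' @export
print.li_profile_set <- function(x, ...) {
  cat(sprintf("Labelling-index profile: %d replicates, %g h chase\n",
              ncol(x$replicates), x$chase))
  print(round(x$profile, 3))
  invisible(x)
}

#' @export
plot.li_profile_set <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$row, p$mean, type = "b", pch = 4, ylim = c(0, 1),
                 xlab = "crypt row (base = 0)", ylab = "labelled proportion",
                 main = sprintf("LI, %s model", x$config$model))
  ok <- !is.na(p$sd)
  graphics::arrows(p$row[ok], pmax(0, p$mean[ok] - p$sd[ok]),
                   p$row[ok], pmin(1, p$mean[ok] + p$sd[ok]),
                   length = 0.02, angle = 90, code = 3, col = "grey60")
  invisible(x)
}

#' Simulate clonal ribbon trajectories
#'
#' Marks \code{n_clones} distinct base-row cells at steady state; marks are
#' heritable, and labelled descendants are followed as they migrate up the
#' crypt.  The final state (and any requested snapshots) can be scored with
#' [ribbon_gap_statistic()].
#'
#' @inheritParams run_crypt
#' @param n_clones clones to mark (default 4).
#' @param mark_hour hours after steady-state onset at which to mark.
#' @return a \code{crypt_run} whose states carry \code{clone} labels.
#' @export
simulate_clones <- function(config, seed = 1L, n_clones = 4,
                            mark_hour = 0, snapshot_hours = numeric(0)) {
  run_crypt(config, seed = seed,
            clones = list(n = n_clones, mark_hour = mark_hour),
            snapshot_hours = snapshot_hours)
}

#' Gap count within clonal ribbons
#'
#' A clone's ribbon is the set of cells carrying its mark, organised in
#' lateral bands (columns one effective cell diameter wide).  A gap is an
#' unmarked cell vertically interposed between two marked cells of the same
#' clone within one column.  Contiguous ribbons score 0.
#'
#' @param state per-cell data.frame with \code{x}, \code{y}, \code{clone}.
#' @param geometry a [crypt_geometry()].
#' @return data.frame with one row per clone: \code{clone}, \code{cells},
#'   \code{gaps}.
#' @export
ribbon_gap_statistic <- function(state, geometry) {
  clones <- sort(unique(state$clone[state$clone > 0]))
  colw <- geometry$width / geometry$n_circumference
  col <- floor(wrap_lateral(state$x, geometry) / colw)
  out <- lapply(clones, function(cl) {
    gaps <- 0L
    for (cc in unique(col[state$clone == cl])) {
      idx <- which(col == cc)
      ys <- state$y[idx][order(state$y[idx])]
      isc <- (state$clone[idx] == cl)[order(state$y[idx])]
      marked <- which(isc)
      if (length(marked) >= 2)
        gaps <- gaps + sum(!isc[seq(min(marked), max(marked))])
    }
    data.frame(clone = cl, cells = sum(state$clone == cl), gaps = gaps)
  })
  if (!length(out))
    return(data.frame(clone = integer(0), cells = integer(0),
                      gaps = integer(0)))
  do.call(rbind, out)
}
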