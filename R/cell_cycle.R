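#' Smith-Martin cell-cycle parameters
#'
#' Default durations (hours) for the two proliferative cell classes.  Phase A
#' of the Smith-Martin model consists entirely of G1 and is left with constant
#' probability per unit time, giving an exponentially distributed duration
#' with the stated mean; S, G2 and M (together phase B) are deterministic.
#' Transit-amplifying (TA) cells: G1 7.0, S 6.2, G2 1.8, M 0.5.  Stem cells
#' cycle more slowly: G1 22.5, S 20.0, G2 6.0, M 1.5.
#'
#' @param class \code{"TA"} or \code{"stem"}.
#' @param g1,s,g2,m optional overrides (hours).
#' @return a list with elements \code{g1}, \code{s}, \code{g2}, \code{m}.
#' @export
cycle_params <- function(class = c("TA", "stem"),
                         g1 = NULL, s = NULL, g2 = NULL, m = NULL) {
  class <- match.arg(class)
  def <- if (class == "TA") list(g1 = 7.0, s = 6.2, g2 = 1.8, m = 0.5)
         else list(g1 = 22.5, s = 20.0, g2 = 6.0, m = 1.5)
  out <- modifyList(def, Filter(Negate(is.null),
                                list(g1 = g1, s = s, g2 = g2, m = m)))
  stopifnot(all(unlist(out) > 0))
  out
}

#' Sample stochastic phase-A (G1) durations
#'
#' Runs the engine's per-step exit rule in isolation: at each step of
#' \code{dt} seconds a cell leaves phase A with probability
#' \code{1 - exp(-dt_h / g1_mean)}, so the duration is (discretised)
#' exponential with mean \code{g1_mean} regardless of step size.  The
#' minimum-size gate is not applied here.
#'
#' @param n number of independent cells to simulate.
#' @param g1_mean mean G1 duration in hours.
#' @param dt step size in seconds (default 10).
#' @return numeric vector of \code{n} durations in hours.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_phase_a(1e4, 7))   # close to 7
sample_phase_a <- function(n, g1_mean, dt = 10) {
  stopifnot(n >= 1, g1_mean > 0, dt > 0)
  phase_a_durations_cpp(as.integer(n), g1_mean, dt)
}

#' Advance one cell through a cell-cycle step
#'
#' Reference single-cell implementation of the engine's cycle rule, useful
#' for unit-scale experiments.  Phase A exit is stochastic (or deterministic
#' at exactly \code{g1} for the adapted pedigree variant) and gated on the
#' minimum radius; S, G2 and M elapse deterministically; completing M sets
#' the division flag.  Mature (G0) cells are rejected: they never cycle.
#'
#' @param cell list with fields \code{phase} (one of \code{"A"}, \code{"S"},
#'   \code{"G2"}, \code{"M"}), \code{clock} (hours in current phase) and
#'   \code{radius} (um).
#' @param params a [cycle_params()] list.
#' @param dt step in hours; must be positive.
#' @param r_min minimum radius to leave phase A (um).  The default (4.5) sits
#'   below the typical birth radius, so the gate only guards against
#'   runaway-small lineages and the stochastic phase keeps its exponential
#'   mean-\code{g1} law for typical cells.
#' @param deterministic if \code{TRUE}, phase A lasts exactly \code{g1}.
#' @return the updated cell list, with logical field \code{divide}.
#' @export
advance_phase <- function(cell, params, dt, r_min = 4.5,
                          deterministic = FALSE) {
  stopifnot(dt > 0)
  if (identical(cell$phase, "G0"))
    stop("mature (G0) cells do not cycle")
  cell$divide <- FALSE
  if (cell$phase == "A") {
    if (deterministic) {
      cell$clock <- cell$clock + dt
      if (cell$clock >= params$g1 && cell$radius >= r_min) {
        cell$phase <- "S"; cell$clock <- 0
      }
    } else if (cell$radius >= r_min &&
               runif(1) < 1 - exp(-dt / params$g1)) {
      cell$phase <- "S"; cell$clock <- 0
    }
  } else if (cell$phase == "S") {
    cell$clock <- cell$clock + dt
    if (cell$clock >= params$s) {
      cell$clock <- cell$clock - params$s; cell$phase <- "G2"
    }
  } else if (cell$phase == "G2") {
    cell$clock <- cell$clock + dt
    if (cell$clock >= params$g2) {
      cell$clock <- cell$clock - params$g2; cell$phase <- "M"
    }
  } else if (cell$phase == "M") {
    cell$clock <- cell$clock + dt
    if (cell$clock >= params$m) cell$divide <- TRUE
  }
  cell
}

#' Grow a proliferative cell for one step
#'
#' Growth is linear in area during G1 (phase A) and G2 at a constant
#' class-wide rate \code{pi * mean_radius^2 / (g1 + g2)} per hour, so a cell
#' doubles its area over an average cycle.  The radius is clamped at
#' \code{r_max}; mature cells and cells in S or M do not grow.
#'
#' @inheritParams advance_phase
#' @param mean_radius nominal birth radius (um, default 5).
#' @param r_max maximum radius (um, default 7.5).
#' @return the updated cell list.
#' @export
grow_cell <- function(cell, params, dt, mean_radius = 5, r_max = 7.5) {
  if (!(cell$phase %in% c("A", "G2"))) return(cell)
  rate <- pi * mean_radius^2 / (params$g1 + params$g2)
  area <- pi * cell$radius^2 + rate * dt
  cell$radius <- min(sqrt(area / pi), r_max)
  cell
}

#' Divide a mother cell into two equal-area daughters
#'
#' Each daughter receives half the mother's area (radius divided by
#' \code{sqrt(2)}).  Daughters are placed symmetrically about the mother
#' centre along the division axis, separated so they just touch; the axis is
#' vertical when \code{orientation = "vertical"} and a uniformly random
#' direction otherwise.  Daughters start in phase A with a zero clock.
#' Lineage typing of the daughters is the business of the fate rules
#' ([pedigree_fate()], [niche_fate()]).
#'
#' @param cell list with fields \code{x}, \code{y}, \code{radius}.
#' @param orientation \code{"vertical"} or \code{"random"}.
#' @return list of two daughter cell lists.
#' @export
divide_cell <- function(cell, orientation = c("vertical", "random")) {
  orientation <- match.arg(orientation)
  rd <- cell$radius / sqrt(2)
  if (orientation == "vertical") {
    ax <- 0; ay <- 1
  } else {
    a <- runif(1, 0, 2 * pi); ax <- cos(a); ay <- sin(a)
  }
  mk <- function(s) list(x = cell$x + s * ax * rd, y = cell$y + s * ay * rd,
                         radius = rd, phase = "A", clock = 0)
  list(mk(1), mk(-1))
}
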