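#' Mechanics parameters
#'
#' Cells move in the overdamped limit: the drag against the basement membrane
#' balances the cell-cell contact forces, so each force enters as a velocity
#' contribution (force over the drag coefficient eta).  The contact force is
#' Hookean: repulsive with spring constant \code{k_over_eta} when the overlap
#' exceeds the equilibrium overlap \code{delta_eq}, and a constant attraction
#' \code{attr_over_eta} (cell-cell adhesion / filopodia) when the overlap is
#' below it, out to a gap of \code{attr_distance}.
#'
#' Defaults are the package's calibrated operating point: \code{k_over_eta}
#' = 0.05 /s and \code{dt} = 2 s, chosen so that (i) contact relaxation
#' (~1/(2k) = 10 s) is far faster than cell motion, keeping the tissue
#' quasi-static at physiological cell production rates, and (ii) the forward
#' Euler update is stable with ~6 contacts per cell (k * n * dt < 1).  See
#' the methods vignette for this calibration; the previously reported
#' estimate of the constant (1e-7 /s) and the 10-s step remain available
#' via the arguments.
#'
#' @param k_over_eta spring constant over drag, 1/s.
#' @param attr_over_eta attractive force over drag, m/s (as conventionally
#'   reported); converted internally to um/s.
#' @param attr_distance attraction reach beyond physical contact, um.
#' @param delta_eq equilibrium overlap, um.
#' @param dt integration step, seconds; must divide one hour exactly.
#' @param active_migration add a constant upward drift to non-anchored cells.
#' @param lateral_migration allow lateral (circumferential) movement.
#' @param stem_attached hard-anchor stem-cell centres to their base position
#'   (pedigree model).
#' @param drift_over_eta active-migration speed, m/s (used when
#'   \code{active_migration} is \code{TRUE}).
#' @return a list of class \code{mechanics_params}.
#' @export
mechanics_params <- function(k_over_eta = 0.05, attr_over_eta = 0,
                             attr_distance = 0, delta_eq = 0.5, dt = 2,
                             active_migration = FALSE,
                             lateral_migration = TRUE,
                             stem_attached = FALSE,
                             drift_over_eta = 0.5e-8) {
  stopifnot(k_over_eta >= 0, attr_over_eta >= 0, attr_distance >= 0,
            delta_eq >= 0, dt > 0)
  structure(list(k_over_eta = k_over_eta, attr_over_eta = attr_over_eta,
                 attr_distance = attr_distance, delta_eq = delta_eq, dt = dt,
                 active_migration = active_migration,
                 lateral_migration = lateral_migration,
                 stem_attached = stem_attached,
                 drift_over_eta = drift_over_eta),
            class = "mechanics_params")
}

#' Pairwise contact force (over drag) between two cells
#'
#' Returns the velocity contribution (um/s) exerted on cell i by cell j:
#' repulsion of magnitude \code{k_over_eta * (overlap - delta_eq)} along the
#' centre line when the overlap exceeds \code{delta_eq}; constant attraction
#' of magnitude \code{attr_over_eta} toward j when the overlap is below
#' \code{delta_eq} (including separated cells within \code{attr_distance}).
#' Cell j receives the exact opposite.  Coincident centres (a degenerate
#' input) get a uniformly random direction.
#'
#' @param ci,cj lists with fields \code{x}, \code{y}, \code{radius}.
#' @param params a [mechanics_params()].
#' @param geometry a [crypt_geometry()] (for the periodic lateral metric).
#' @return numeric length-2 vector (um/s) acting on \code{ci}.
#' @export
contact_force_over_eta <- function(ci, cj, params, geometry) {
  pair_force_cpp(ci$x, ci$y, cj$x, cj$y, ci$radius, cj$radius,
                 geometry$width, params$k_over_eta,
                 params$attr_over_eta * 1e6, params$attr_distance,
                 params$delta_eq)
}

#' One synchronous mechanics step over a configuration of cells
#'
#' Computes all pair forces from the same configuration, sums velocity
#' contributions per cell, applies the movement constraints in order (lateral
#' component zeroed unless \code{lateral_migration}; anchored cells held at
#' their vertical position; \code{y < 0} clipped to the base) and advances
#' every position by \code{velocity * dt}, wrapping laterally.  Aborts with a
#' diagnostic if any displacement exceeds the cell's radius (instability:
#' \code{dt} too large for the chosen stiffness).
#'
#' @param x,y,radius cell centres and radii (um).
#' @param params a [mechanics_params()].
#' @param geometry a [crypt_geometry()].
#' @param anchored logical vector; anchored cells do not move vertically and
#'   receive no active drift.
#' @return list with updated \code{x}, \code{y} and the
#'   \code{max_displacement} taken (um).
#' @export
mechanics_step <- function(x, y, radius, params, geometry,
                           anchored = rep(FALSE, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(radius),
            length(anchored) == length(x))
  mechanics_step_cpp(as.numeric(x), as.numeric(y), as.numeric(radius),
                     as.logical(anchored),
                     list(width = geometry$width, k = params$k_over_eta,
                          attr = params$attr_over_eta * 1e6,
                          attr_dist = params$attr_distance,
                          delta_eq = params$delta_eq, dt = params$dt,
                          active = params$active_migration,
                          lateral = params$lateral_migration,
                          drift = params$drift_over_eta * 1e6))
}
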