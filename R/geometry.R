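#' Crypt geometry: a laterally periodic rectangle (unrolled cylinder)
#'
#' The crypt wall is represented as a 2D rectangle with periodic left/right
#' borders; \code{y = 0} is the crypt base and \code{y = height} the orifice.
#' Dimensions are finely tuned so that the crypt holds exactly
#' \code{n_circumference * n_length} cells when cells of the mean radius are
#' perfectly arranged at the equilibrium overlap: the effective cell diameter
#' is \code{2 * mean_radius - delta_eq} and width/height are whole multiples
#' of it.
#'
#' @param n_circumference cells around the circumference (default 22).
#' @param n_length cells along the crypt axis (default 32).
#' @param mean_radius mean cell radius in um (default 5).
#' @param delta_eq equilibrium overlap between touching cells in um
#'   (default 0.5); must match the mechanics configuration.
#' @return an object of class \code{crypt_geometry} with fields
#'   \code{width}, \code{height} (um), the cell counts, and
#'   \code{capacity = n_circumference * n_length}.
#' @export
#' @examples
#' g <- crypt_geometry()
#' g$capacity   # 704
crypt_geometry <- function(n_circumference = 22L, n_length = 32L,
                           mean_radius = 5, delta_eq = 0.5) {
  stopifnot(n_circumference >= 1, n_length >= 1,
            mean_radius > 0, delta_eq >= 0, delta_eq < 2 * mean_radius)
  d_eff <- 2 * mean_radius - delta_eq
  structure(list(
    n_circumference = as.integer(n_circumference),
    n_length = as.integer(n_length),
    mean_radius = mean_radius,
    delta_eq = delta_eq,
    effective_diameter = d_eff,
    width = n_circumference * d_eff,
    height = n_length * d_eff,
    capacity = as.integer(n_circumference) * as.integer(n_length)
  ), class = "crypt_geometry")
}

#' @export
print.crypt_geometry <- function(x, ...) {
  cat(sprintf(
    "Crypt geometry: %d x %d cells, %.1f x %.1f um (effective diameter %.2f um),\n  capacity %d cells at perfect packing\n",
    x$n_circumference, x$n_length, x$width, x$height,
    x$effective_diameter, x$capacity))
  invisible(x)
}

#' Wrap a lateral coordinate onto the periodic circumference
#'
#' @param x lateral coordinate(s) in um; any real value.
#' @param geometry a [crypt_geometry()].
#' @return coordinates wrapped into \code{[0, width)}.
#' @export
wrap_lateral <- function(x, geometry) {
  w <- geometry$width
  x <- x %% w
  x[x == w] <- 0
  x
}

#' Minimal lateral distance on the periodic circumference
#'
#' @param x1,x2 lateral coordinates in um.
#' @inheritParams wrap_lateral
#' @return \code{min(|dx|, width - |dx|)} elementwise.
#' @export
lateral_distance <- function(x1, x2, geometry) {
  d <- abs(wrap_lateral(x1, geometry) - wrap_lateral(x2, geometry))
  pmin(d, geometry$width - d)
}

#' Integer row position of a cell
#'
#' The crypt is divided into \code{n_length} equal-height rows; a cell's row
#' is determined by its centre, with the top row absorbing any centre at or
#' above \code{height} (cells sit there only transiently before removal).
#'
#' @param y vertical coordinate(s) in um, \code{>= 0}.
#' @inheritParams wrap_lateral
#' @return 0-based integer row indices in \code{[0, n_length - 1]}.
#' @export
row_index <- function(y, geometry) {
  stopifnot(all(y >= 0))
  row <- floor(y / (geometry$height / geometry$n_length))
  pmin(as.integer(row), geometry$n_length - 1L)
}

#' Find contacting (or near-contacting) cell pairs
#'
#' Two cells are in contact when their centre distance, using the periodic
#' lateral metric, is less than the sum of their radii plus \code{reach}.
#' With \code{reach = 0} this is physical overlap; a positive reach models
#' filopodial attraction at a distance.  A uniform spatial bin grid is used
#' internally; the result is identical to the all-pairs comparison.
#'
#' @param x,y cell centre coordinates (um).
#' @param radius cell radii (um).
#' @inheritParams wrap_lateral
#' @param reach attraction reach in um (default 0).
#' @return an integer matrix with two columns \code{i}, \code{j}
#'   (\code{i < j}), one row per unordered pair in contact.
#' @export
find_contacts <- function(x, y, radius, geometry, reach = 0) {
  stopifnot(length(x) == length(y), length(x) == length(radius), reach >= 0)
  m <- contact_pairs_cpp(as.numeric(x), as.numeric(y), as.numeric(radius),
                         geometry$width, reach)
  colnames(m) <- c("i", "j")
  if (nrow(m) > 1) m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  m
}
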