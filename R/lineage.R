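#' Lineage (cell-fate) configuration
#'
#' Encodes how stemness and maturation are decided.  Under the
#' \emph{pedigree} model cells follow a preprogrammed hierarchy: immortal
#' stem cells divide asymmetrically into a stem cell and a first-generation
#' transit-amplifying (TA1) cell; TA cells divide symmetrically through
#' \code{n_ta_generations} generations, after which both daughters are
#' mature (G0).  Under the \emph{niche} model all divisions are symmetric
#' and fate is positional: the proliferative niche is the bottom
#' \code{proliferation_region} fraction of the crypt, and cells mature on
#' leaving it, either only at birth (\code{only_new_cells_mature = TRUE},
#' scheme A) or additionally whenever a G1 cell's centre crosses the
#' boundary (scheme B).  Maturation is irreversible.
#'
#' Two adapted variants are supported: a deterministic-cycle pedigree model
#' (zero cell-cycle variance, cells out of phase) and a position-PDF niche
#' model where the hard boundary is replaced by a monotone maturation
#' probability ramp of half-width \code{pdf_half_width} (fraction of crypt
#' height) centred on the boundary.
#'
#' @param model \code{"pedigree"} or \code{"niche"}.
#' @param n_ta_generations TA generations before maturity (pedigree,
#'   default 5).
#' @param proliferation_region niche height fraction in (0, 1] (default 0.3).
#' @param only_new_cells_mature niche scheme A (TRUE) or B (FALSE).
#' @param deterministic_cycle adapted pedigree: phase A lasts exactly G1.
#' @param position_pdf adapted niche: probabilistic maturation ramp.
#' @param pdf_half_width ramp half-width as a fraction of crypt height.
#' @return a list of class \code{lineage_config}.
#' @export
lineage_config <- function(model = c("pedigree", "niche"),
                           n_ta_generations = 5L,
                           proliferation_region = 0.3,
                           only_new_cells_mature = FALSE,
                           deterministic_cycle = FALSE,
                           position_pdf = FALSE,
                           pdf_half_width = 0.15) {
  model <- match.arg(model)
  stopifnot(n_ta_generations >= 1,
            proliferation_region > 0, proliferation_region <= 1,
            pdf_half_width > 0, pdf_half_width < 0.5)
  structure(list(model = model,
                 n_ta_generations = as.integer(n_ta_generations),
                 proliferation_region = proliferation_region,
                 only_new_cells_mature = only_new_cells_mature,
                 deterministic_cycle = deterministic_cycle,
                 position_pdf = position_pdf,
                 pdf_half_width = pdf_half_width),
            class = "lineage_config")
}

#' Pedigree fate of the two daughters at division
#'
#' Stem mothers divide asymmetrically into another stem cell and a TA1 cell;
#' TA mothers of generation \code{g < n_ta_generations} produce two TA cells
#' of generation \code{g + 1}; TA mothers of the final generation produce
#' two mature (G0) cells.  Mature cells never divide.
#'
#' @param class mother class, \code{"stem"} or \code{"TA"}.
#' @param generation mother TA generation (ignored for stem mothers).
#' @param n_ta_generations number of TA generations (default 5).
#' @return a list of two lists, each with \code{class} (\code{"stem"},
#'   \code{"TA"} or \code{"mature"}) and \code{generation}.
#' @export
pedigree_fate <- function(class, generation = 0L, n_ta_generations = 5L) {
  if (class == "mature")
    stop("mature cells never divide")
  if (class == "stem")
    return(list(list(class = "stem", generation = 0L),
                list(class = "TA", generation = 1L)))
  stopifnot(class == "TA", generation >= 1)
  if (generation < n_ta_generations) {
    d <- list(class = "TA", generation = as.integer(generation + 1L))
  } else {
    d <- list(class = "mature", generation = as.integer(generation))
  }
  list(d, d)
}

#' Niche fate of a cell given its vertical position
#'
#' The proliferative region is \code{[0, proliferation_region * height)}.
#' Scheme A (\code{only_new_cells_mature = TRUE}): only daughters born above
#' the boundary mature (\code{at_birth = TRUE}); cells that migrate out
#' while cycling continue their cycle.  Scheme B additionally matures any
#' cell still in G1 (phase A) whose centre lies above the boundary.
#' Maturation is irreversible: a mature cell stays mature.
#'
#' @param phase cell phase, one of \code{"A"}, \code{"S"}, \code{"G2"},
#'   \code{"M"}, \code{"G0"}.
#' @param y vertical position of the cell centre (um).
#' @param geometry a [crypt_geometry()].
#' @param cfg a [lineage_config()] with \code{model = "niche"}.
#' @param at_birth is this the birth-time check for a newborn daughter?
#' @return the updated phase (\code{"G0"} if the cell matures).
#' @export
niche_fate <- function(phase, y, geometry, cfg, at_birth = FALSE) {
  stopifnot(cfg$model == "niche")
  if (phase == "G0") return("G0")
  boundary <- cfg$proliferation_region * geometry$height
  if (at_birth && y > boundary) return("G0")
  if (!cfg$only_new_cells_mature && phase == "A" && y > boundary)
    return("G0")
  phase
}

#' Position-dependent maturation probability (adapted niche model)
#'
#' A linear ramp centred on the proliferation boundary: 0 deep in the niche,
#' 1 well above the boundary, and 0.5 at the boundary itself.  The ramp
#' half-width is \code{pdf_half_width * height}.
#'
#' @param y vertical position(s) of the cell centre (um).
#' @inheritParams niche_fate
#' @return maturation probabilities in \code{[0, 1]}.
#' @export
position_maturation_probability <- function(y, geometry, cfg) {
  b <- cfg$proliferation_region * geometry$height
  hw <- cfg$pdf_half_width * geometry$height
  p <- (y - (b - hw)) / (2 * hw)
  pmin(pmax(p, 0), 1)
}
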