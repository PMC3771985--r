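#' Free-parameter grids for the parametric study
#'
#' The full Cartesian product of the explored free-parameter values:
#' attractive force over eta {0, 0.5e-8, 1.0e-8} m/s, attraction reach
#' {0, 0.5, 1} um, active migration {TRUE, FALSE}, lateral migration
#' {TRUE, FALSE}, vertical division only {TRUE, FALSE}; the niche model
#' adds only-new-cells-mature {TRUE, FALSE} and proliferation region
#' {0.2, 0.3, 0.4, 0.5}.  This gives 72 pedigree and 576 niche parameter
#' sets.  Ordering is deterministic (lexicographic over the axes as listed,
#' first axis varying fastest); each row carries a run index.
#'
#' @param model \code{"pedigree"} or \code{"niche"}.
#' @return a data.frame, one row per parameter set, with a \code{run}
#'   index column.
#' @export
#' @examples
#' nrow(parameter_grid("pedigree"))   # 72
parameter_grid <- function(model = c("pedigree", "niche")) {
  model <- match.arg(model)
  axes <- list(
    attr_over_eta = c(0, 0.5e-8, 1.0e-8),
    attr_distance = c(0, 0.5, 1),
    active_migration = c(TRUE, FALSE),
    lateral_migration = c(TRUE, FALSE),
    vertical_division_only = c(TRUE, FALSE))
  if (model == "niche")
    axes <- c(axes, list(only_new_cells_mature = c(TRUE, FALSE),
                         proliferation_region = c(0.2, 0.3, 0.4, 0.5)))
  g <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE))
  g$model <- model
  g$run <- seq_len(nrow(g))
  g
}

#' Turn one grid row into a runnable configuration
#'
#' @param row one-row data.frame from [parameter_grid()].
#' @param base optional base [crypt_config()] supplying everything the grid
#'   does not vary.
#' @return a [crypt_config()].
#' @export
grid_config <- function(row, base = NULL) {
  stopifnot(nrow(row) == 1)
  model <- as.character(row$model)
  base <- base %||% crypt_config(model)
  mech <- list(attr_over_eta = row$attr_over_eta,
               attr_distance = row$attr_distance,
               active_migration = row$active_migration,
               lateral_migration = row$lateral_migration)
  lin <- list()
  if (model == "niche")
    lin <- list(only_new_cells_mature = row$only_new_cells_mature,
                proliferation_region = row$proliferation_region)
  crypt_config(model,
               geometry = base$geometry,
               mechanics = modifyList(base$mechanics, mech),
               cycle = modifyList(base$cycle,
                                  list(vertical_division_only =
                                         row$vertical_division_only)),
               lineage = modifyList(base$lineage, c(lin, list(model = NULL))),
               run = base$run)
}

#' Enumerate a grid into runnable configurations
#'
#' @param grid a [parameter_grid()] data.frame (or subset).
#' @param base optional base configuration.
#' @return a list of [crypt_config()] objects, in grid order.
#' @export
enumerate_grid <- function(grid, base = NULL) {
  if (!nrow(grid)) stop("empty parameter grid")
  lapply(seq_len(nrow(grid)), function(i) grid_config(grid[i, ], base))
}

#' Run a (subset of a) parameter sweep
#'
#' Runs replicated simulations for every row of the grid and collects
#' normalised performance means and variances.  Results are independent of
#' execution order; each parameter set uses the same replicate seeds.
#'
#' @param grid a [parameter_grid()] data.frame or subset thereof.
#' @param base optional base configuration.
#' @param replicates replicates per parameter set.
#' @param seed master seed.
#' @param targets a [crypt_targets()] list.
#' @return the grid with performance columns appended (one row per set).
#' @export
run_sweep <- function(grid, base = NULL, replicates = 3, seed = 1L,
                      targets = crypt_targets()) {
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sim <- simulate_crypt(grid_config(grid[i, ], base),
                          replicates = replicates, seed = seed,
                          targets = targets)
    m <- sim$measures
    data.frame(
      norm_n_cells = mean(m$norm_n_cells, na.rm = TRUE),
      norm_production = mean(m$norm_production, na.rm = TRUE),
      norm_mature_proportion = mean(m$norm_mature_proportion, na.rm = TRUE),
      mature_order = mean(m$mature_order, na.rm = TRUE),
      var_n_cells = var(m$n_cells, na.rm = TRUE),
      steady_runs = sum(m$steady))
  })
  cbind(grid, do.call(rbind, res))
}

#' Sequential gating specification
#'
#' An ordered list of interval gates on normalised measures, applied
#' sequentially as in the parametric study: first the cell-number gate
#' (normalised total within [0.99, 1.01]), then the production gate
#' (normalised rate up to 1.12), then the cell-maturity criteria.  Bounds
#' are configurable; the mature-order threshold defaults to 0.90.
#'
#' @param ... gates as \code{list(measure =, lower =, upper =)}; when empty
#'   the default gate sequence is returned.
#' @return a list of gates, class \code{gate_spec}.
#' @export
gate_spec <- function(...) {
  gates <- list(...)
  if (!length(gates)) {
    gates <- list(
      list(measure = "norm_n_cells", lower = 0.99, upper = 1.01),
      list(measure = "norm_production", lower = 0.85, upper = 1.12),
      list(measure = "mature_order", lower = 0.90, upper = Inf))
  }
  for (g in gates)
    stopifnot(is.character(g$measure), is.finite(g$lower) || g$lower == -Inf,
              g$upper >= g$lower)
  structure(gates, class = "gate_spec")
}

#' Sequentially gate sweep results and rank the survivors
#'
#' Applies each gate in order, dropping parameter sets outside the bounds.
#' Survivors are ranked by closeness of the normalised production rate to 1,
#' breaking ties by higher mature order.  If no set survives, an empty
#' result is returned with the binding gate recorded in attribute
#' \code{"binding_gate"}.
#'
#' @param results a data.frame from [run_sweep()] (or any table with the
#'   gated measure columns).
#' @param gates a [gate_spec()].
#' @return the surviving rows, ranked, with a \code{rank} column.
#' @export
gate_runs <- function(results, gates = gate_spec()) {
  kept <- results
  for (g in gates) {
    if (!g$measure %in% names(kept))
      stop("results lack gated measure: ", g$measure)
    ok <- kept[[g$measure]] >= g$lower & kept[[g$measure]] <= g$upper &
      !is.na(kept[[g$measure]])
    kept <- kept[ok, , drop = FALSE]
    if (!nrow(kept)) {
      attr(kept, "binding_gate") <- g$measure
      return(kept)
    }
  }
  ord <- order(abs(kept$norm_production - 1), -kept$mature_order)
  kept <- kept[ord, , drop = FALSE]
  kept$rank <- seq_len(nrow(kept))
  kept
}
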