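#' Full run configuration
#'
#' Assembles geometry, mechanics, cell-cycle, lineage and run-control
#' parameters into a validated configuration.  Component arguments may be
#' given as complete objects ([mechanics_params()], [lineage_config()]) or
#' as partial lists of overrides merged into the defaults.  Defaults encode
#' the fixed parameters of the crypt (22 x 32 cells, mean radius 5 um, TA
#' and stem Smith-Martin durations, 5 TA generations, stem attachment for
#' the pedigree model) together with the package's calibrated mechanics.
#'
#' @param model \code{"pedigree"} or \code{"niche"}.
#' @param geometry overrides for \code{n_circumference}, \code{n_length},
#'   \code{mean_radius}.
#' @param mechanics overrides for [mechanics_params()] fields.
#' @param cycle overrides: \code{stem}, \code{ta} (each a [cycle_params()]
#'   list), \code{r_min}, \code{r_max}, \code{vertical_division_only}.
#' @param lineage overrides for [lineage_config()] fields.
#' @param run overrides: \code{replicates} (default 30),
#'   \code{measurement_days} (default 3), \code{steady_state_window} (hours,
#'   default 12), \code{steady_state_tol} (cells/hour, default 0.5),
#'   \code{max_hours} safety cap (default 2000).
#' @return an object of class \code{crypt_config}.
#' @export
#' @examples
#' cfg <- crypt_config("niche", lineage = list(proliferation_region = 0.3))
crypt_config <- function(model = c("pedigree", "niche"),
                         geometry = list(), mechanics = list(),
                         cycle = list(), lineage = list(), run = list()) {
  model <- match.arg(model)
  geo_def <- list(n_circumference = 22L, n_length = 32L, mean_radius = 5)
  mech_def <- unclass(mechanics_params(
    stem_attached = identical(model, "pedigree")))
  cyc_def <- list(stem = cycle_params("stem"), ta = cycle_params("TA"),
                  r_min = 4.5, r_max = 7.5, vertical_division_only = TRUE)
  lin_def <- unclass(lineage_config(model))
  run_def <- list(replicates = 30L, measurement_days = 3,
                  steady_state_window = 12, steady_state_tol = 0.5,
                  max_hours = 2000)
  merge_strict <- function(def, ov, where) {
    ov <- unclass(ov)
    bad <- setdiff(names(ov), names(def))
    if (length(bad))
      stop("unknown ", where, " parameter(s): ", paste(bad, collapse = ", "))
    modifyList(def, ov)
  }
  cfg <- structure(list(
    model = model,
    geometry = merge_strict(geo_def, geometry, "geometry"),
    mechanics = merge_strict(mech_def, mechanics, "mechanics"),
    cycle = merge_strict(cyc_def, cycle, "cycle"),
    lineage = merge_strict(lin_def, lineage, "lineage"),
    run = merge_strict(run_def, run, "run")
  ), class = "crypt_config")
  cfg$lineage$model <- model
  validate_config(cfg)
}

#' Validate a crypt configuration
#'
#' Checks value ranges and cross-component consistency; returns the
#' configuration invisibly unchanged on success, or fails with a
#' field-level message.
#'
#' @param cfg a [crypt_config()].
#' @return the validated configuration (invisibly classed).
#' @export
validate_config <- function(cfg) {
  g <- cfg$geometry; m <- cfg$mechanics; cy <- cfg$cycle
  l <- cfg$lineage; r <- cfg$run
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(cfg$model %in% c("pedigree", "niche"), "model must be pedigree or niche")
  chk(g$n_circumference >= 1 && g$n_length >= 1, "geometry: cell counts >= 1")
  chk(g$mean_radius > 0, "geometry: mean_radius must be positive")
  chk(m$dt > 0 && abs(3600 / m$dt - round(3600 / m$dt)) < 1e-9,
      "mechanics: dt must be positive and divide one hour exactly")
  chk(m$k_over_eta >= 0 && m$attr_over_eta >= 0 && m$attr_distance >= 0 &&
        m$delta_eq >= 0, "mechanics: forces and distances must be >= 0")
  chk(all(unlist(cy$stem) > 0) && all(unlist(cy$ta) > 0),
      "cycle: all phase durations must be positive")
  chk(cy$r_min > 0 && cy$r_max > cy$r_min,
      "cycle: need 0 < r_min < r_max")
  chk(l$proliferation_region > 0 && l$proliferation_region <= 1,
      "lineage: proliferation_region must be in (0, 1]")
  chk(l$n_ta_generations >= 1, "lineage: n_ta_generations >= 1")
  chk(r$replicates >= 1, "run: replicates >= 1")
  chk(r$measurement_days > 0, "run: measurement_days must be positive")
  chk(r$steady_state_window > 0, "run: steady_state_window must be positive")
  invisible(cfg)
}

#' Geometry object implied by a configuration
#'
#' @param cfg a [crypt_config()].
#' @return the [crypt_geometry()] (using the mechanics equilibrium overlap).
#' @export
config_geometry <- function(cfg) {
  crypt_geometry(cfg$geometry$n_circumference, cfg$geometry$n_length,
                 cfg$geometry$mean_radius, cfg$mechanics$delta_eq)
}

#' Shipped calibrated scenarios
#'
#' Named parameter sets selected by the parametric study, plus the two
#' adapted variants:
#' \describe{
#'   \item{pedigree-run13}{attractive force over eta 1.0e-8 m/s, reach 0 um,
#'     no active migration, no lateral migration, vertical division only,
#'     stem cells attached.}
#'   \item{niche-run296}{attractive force over eta 0.5e-8 m/s, reach 0.5 um,
#'     no active migration, lateral migration on, vertical division only,
#'     only-new-cells-mature off, proliferation region 0.3.}
#'   \item{pedigree-adapted}{run 13 with a deterministic (zero-variance),
#'     unsynchronised cell cycle.}
#'   \item{niche-adapted}{run 296 with position-PDF maturation.}
#' }
#'
#' @param name scenario name.
#' @return a [crypt_config()].
#' @export
#' @examples
#' cfg <- crypt_scenario("niche-run296")
crypt_scenario <- function(name = c("pedigree-run13", "niche-run296",
                                    "pedigree-adapted", "niche-adapted")) {
  name <- match.arg(name)
  ped_mech <- list(attr_over_eta = 1.0e-8, attr_distance = 0,
                   active_migration = FALSE, lateral_migration = FALSE,
                   stem_attached = TRUE)
  nic_mech <- list(attr_over_eta = 0.5e-8, attr_distance = 0.5,
                   active_migration = FALSE, lateral_migration = TRUE,
                   stem_attached = FALSE)
  switch(name,
    "pedigree-run13" = crypt_config("pedigree", mechanics = ped_mech),
    "pedigree-adapted" = crypt_config("pedigree", mechanics = ped_mech,
                                      lineage = list(deterministic_cycle = TRUE)),
    "niche-run296" = crypt_config("niche", mechanics = nic_mech,
                                  lineage = list(proliferation_region = 0.3,
                                                 only_new_cells_mature = FALSE)),
    "niche-adapted" = crypt_config("niche", mechanics = nic_mech,
                                   lineage = list(proliferation_region = 0.3,
                                                  only_new_cells_mature = FALSE,
                                                  position_pdf = TRUE)))
}

#' @export
print.crypt_config <- function(x, ...) {
  cat("Crypt run configuration (", x$model, " model)\n", sep = "")
  g <- config_geometry(x)
  cat(sprintf("  geometry:  %d x %d cells, %.1f x %.1f um\n",
              g$n_circumference, g$n_length, g$width, g$height))
  m <- x$mechanics
  cat(sprintf(
    "  mechanics: k/eta %.3g /s, attraction %.3g m/s (reach %.2g um), dt %g s\n",
    m$k_over_eta, m$attr_over_eta, m$attr_distance, m$dt))
  cat(sprintf(
    "             active %s, lateral %s, stems attached %s, vertical division %s\n",
    m$active_migration, m$lateral_migration, m$stem_attached,
    x$cycle$vertical_division_only))
  l <- x$lineage
  if (x$model == "pedigree") {
    cat(sprintf("  lineage:   %d TA generations%s\n", l$n_ta_generations,
                if (l$deterministic_cycle) ", deterministic cycle" else ""))
  } else {
    cat(sprintf("  lineage:   region %.2f, only-new-mature %s%s\n",
                l$proliferation_region, l$only_new_cells_mature,
                if (l$position_pdf) ", position-PDF maturation" else ""))
  }
  invisible(x)
}

#' Save / load a configuration as YAML
#'
#' Configurations round-trip exactly: \code{load_config(save_config(cfg))}
#' reproduces \code{cfg}.  Unknown keys in a file are an error (a guard
#' against silent typos); missing keys take the documented defaults, which
#' are echoed via [validate_config()].
#'
#' @param cfg a [crypt_config()].
#' @param path file path.
#' @return \code{save_config}: the path, invisibly. \code{load_config}: a
#'   validated [crypt_config()].
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("model", "geometry", "mechanics", "cycle", "lineage", "run")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown top-level key(s) in config: ", paste(bad, collapse = ", "))
  model <- raw$model %||% "pedigree"
  crypt_config(model,
               geometry = raw$geometry %||% list(),
               mechanics = raw$mechanics %||% list(),
               cycle = raw$cycle %||% list(),
               lineage = raw$lineage %||% list(),
               run = raw$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Stable hash of a configuration (for provenance headers)
#'
#' @param cfg a [crypt_config()].
#' @return an md5 string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}
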