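#' Relative sensitivity of a function at a normal operating point
#'
#' The relative sensitivity function (RSF) is the dimensionless normalised
#' derivative \code{(p/f) df/dp} evaluated at the normal operating point
#' (NOP).  For stochastic simulators an analytic derivative is unavailable,
#' so it is estimated by a central finite difference of the normalised
#' response:
#' \deqn{S = \frac{f(p_0(1+\delta)) - f(p_0(1-\delta))}{f(p_0)\,2\delta}.}
#' Positive \code{S} means the measure increases with the parameter.
#'
#' @param f function of one numeric parameter returning a scalar measure
#'   (typically the mean of replicate simulations).
#' @param p0 normal operating point; must be positive.
#' @param delta relative perturbation in (0, 0.5] (default 0.1).
#' @return a list with \code{sensitivity}, the three function values
#'   (\code{f0}, \code{f_plus}, \code{f_minus}) and the inputs.  The
#'   sensitivity is \code{NA} when \code{f(p0) = 0} (undefined).
#' @export
#' @examples
#' relative_sensitivity(function(p) 3 * p, 2)$sensitivity    # 1
#' relative_sensitivity(function(p) p^2, 2)$sensitivity      # 2
relative_sensitivity <- function(f, p0, delta = 0.1) {
  stopifnot(p0 > 0, delta > 0, delta <= 0.5)
  f0 <- f(p0)
  fp <- f(p0 * (1 + delta))
  fm <- f(p0 * (1 - delta))
  s <- if (is.na(f0) || f0 == 0) NA_real_ else (fp - fm) / (f0 * 2 * delta)
  list(sensitivity = s, f0 = f0, f_plus = fp, f_minus = fm,
       p0 = p0, delta = delta)
}

#' Empirical sensitivity of crypt performance to cell-cycle G1 duration
#'
#' Estimates the relative sensitivity of the four performance measures to a
#' G1 duration, at the configuration's operating point, by running
#' replicated simulations at \code{p0} and \code{p0 (1 +/- delta)}.  The
#' same replicate seeds are used at every evaluation point (common random
#' numbers), which substantially reduces the Monte-Carlo variance of the
#' paired difference.
#'
#' @param config a [crypt_config()]; the NOP is its current G1 value.
#' @param parameter which G1 to perturb: \code{"stem_g1"} or \code{"ta_g1"}
#'   for the pedigree model; \code{"g1"} (the single proliferative class)
#'   for the niche model, equivalent to \code{"ta_g1"}.
#' @param delta relative perturbation (default 0.1).
#' @param replicates simulation replicates per evaluation point.
#' @param seed master seed; replicate r uses \code{seed + r - 1} at every
#'   evaluation point.
#' @param targets normalisation targets (passed through to the measures).
#' @return a data.frame of class \code{sensitivity_result}: one row per
#'   measure with the NOP, the sensitivity estimate, its standard error
#'   over replicate pairings, and the replicate count.
#' @export
cycle_sensitivity <- function(config, parameter = c("ta_g1", "stem_g1", "g1"),
                              delta = 0.1, replicates = 5, seed = 1L,
                              targets = crypt_targets()) {
  parameter <- match.arg(parameter)
  field <- if (parameter == "stem_g1") "stem" else "ta"
  if (parameter == "stem_g1" && config$model != "pedigree")
    stop("stem_g1 applies to the pedigree model only")
  p0 <- config$cycle[[field]]$g1
  with_g1 <- function(value) {
    cfg <- config
    cfg$cycle[[field]]$g1 <- value
    cfg
  }
  eval_point <- function(value) {
    sim <- simulate_crypt(with_g1(value), replicates = replicates,
                          seed = seed, targets = targets)
    sim$measures
  }
  m0 <- eval_point(p0)
  mp <- eval_point(p0 * (1 + delta))
  mm <- eval_point(p0 * (1 - delta))
  meas <- c("n_cells", "production_rate", "mature_proportion", "mature_order")
  out <- do.call(rbind, lapply(meas, function(v) {
    f0 <- mean(m0[[v]], na.rm = TRUE)
    si <- (mp[[v]] - mm[[v]]) / (f0 * 2 * delta)   # per-replicate pairing
    data.frame(model = config$model, parameter = parameter, measure = v,
               nop = p0, sensitivity = if (f0 == 0) NA_real_ else mean(si, na.rm = TRUE),
               se = sd(si, na.rm = TRUE) / sqrt(sum(!is.na(si))),
               replicates = replicates, delta = delta)
  }))
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Relative sensitivity (%s model, %s, NOP %g h, delta %.0f%%, %d replicates)\n",
              x$model[1], x$parameter[1], x$nop[1], 100 * x$delta[1],
              x$replicates[1]))
  df <- data.frame(measure = x$measure,
                   sensitivity = round(x$sensitivity, 3),
                   se = round(x$se, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
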