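#' Write a table as CSV with a machine-readable provenance header
#'
#' Prepends commented header lines (\code{# key: value}) carrying the
#' package version, the configuration hash and the seed, so that every
#' output file can be traced to the exact run that produced it.
#'
#' @param df a data.frame.
#' @param path output file.
#' @param config optional [crypt_config()] used for the run.
#' @param seed optional seed used for the run.
#' @param extra optional named list of further header fields.
#' @return the path, invisibly.
#' @export
write_crypt_csv <- function(df, path, config = NULL, seed = NULL,
                            extra = list()) {
  hdr <- c(version = as.character(utils::packageVersion("cryptsim")))
  if (!is.null(config)) hdr <- c(hdr, config_hash = config_hash(config))
  if (!is.null(seed)) hdr <- c(hdr, seed = as.character(seed))
  hdr <- c(hdr, unlist(extra))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed CSV
#'
#' @param path file written by [write_crypt_csv()].
#' @return the data.frame, with the header fields attached as attribute
#'   \code{"provenance"} (a named character vector).
#' @export
read_crypt_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  prov <- character(0)
  if (length(hdr)) {
    kv <- sub("^# ", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: ?", "", kv)
    prov <- setNames(vals, keys)
  }
  df <- read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                              collapse = "\n"))
  attr(df, "provenance") <- prov
  df
}

#' Write the per-cell snapshot of a run
#'
#' One row per cell: id, position, radius, phase, class, generation and
#' labels, with the provenance header.
#'
#' @param run a \code{crypt_run}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_snapshot_csv <- function(run, path) {
  write_crypt_csv(run$state, path, config = run$config, seed = run$seed,
                  extra = list(onset = run$onset))
}

#' Write the hourly time series of a run
#'
#' @inheritParams write_snapshot_csv
#' @return the path, invisibly.
#' @export
write_series_csv <- function(run, path) {
  write_crypt_csv(run$series, path, config = run$config, seed = run$seed,
                  extra = list(onset = run$onset))
}
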