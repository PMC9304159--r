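# Run configuration and report rendering shared by the analysis scripts.

#' Resolved run configuration
#'
#' Collects the knobs every analysis run shares — temperature, pressure,
#' assembly scheme, frequency scale, seed, output directory — with the
#' constants-table version and package version, so every report can embed
#' the full configuration it was produced under. All randomness in a run
#' flows from the single `seed`.
#'
#' @param temperature K (default 298.15; the experimental comparison uses
#'   278.15).
#' @param pressure atm.
#' @param scheme energy assembly scheme (see [assemble()]).
#' @param scale frequency scaling factor (reporting only; thermochemistry
#'   stays unscaled).
#' @param seed integer seed.
#' @param out_dir output directory for reports.
#' @return a list of class `oxo_config`.
#' @export
run_config <- function(temperature = 298.15, pressure = 1,
                       scheme = "E+ZPE+solv+disp", scale = 1.0, seed = 1L,
                       out_dir = "results") {
  if (temperature <= 0) stop("invalid config: temperature must be positive")
  if (pressure <= 0) stop("invalid config: pressure must be positive")
  if (!scheme %in% .schemes) {
    stop("invalid config: unknown scheme '", scheme, "'")
  }
  structure(
    list(temperature = temperature, pressure = pressure, scheme = scheme,
         scale = scale, seed = as.integer(seed), out_dir = out_dir,
         constants = oxo_constants$version,
         package_version = as.character(utils::packageVersion("oxoscope"))),
    class = "oxo_config"
  )
}

#' Write a tab-separated report with an embedded configuration header
#'
#' Column names should carry units (e.g. `dG_kcal_mol`); the header block
#' records the resolved configuration and package version.
#'
#' @param df data frame to write.
#' @param path output path (directories are created).
#' @param config an [run_config()].
#' @return invisibly, `path`.
#' @export
write_report <- function(df, path, config = run_config()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf(
    "# oxoscope %s | constants %s | T %g K | P %g atm | scheme %s | scale %g | seed %d",
    config$package_version, config$constants, config$temperature,
    config$pressure, config$scheme, config$scale, config$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
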