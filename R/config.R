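# YAML analysis configuration: composition, selections, cutoffs and
# temperatures in one human-readable file.

config_defaults <- function() {
  list(
    composition = "Avanti",
    resolution = "AA",
    temperatures = c(277, 285, 296, 310, 320),
    cutoffs = list(
      cluster_aa = 0.35, cluster_cg = 0.65,
      enrichment = 0.9, protein_shell = 0.65, interdigitation = 0.35
    ),
    thickness_grid = c(15, 15),
    msd = list(restart_interval = 1, fit_window = c(10, 30)),
    permeation = list(exclusion_threshold = 0.01, buffer = 0)
  )
}

#' Read an analysis configuration
#'
#' Loads a YAML config and fills unset fields with the package defaults
#' (Avanti composition, the printed cutoffs of 0.35/0.65 nm for clustering,
#' 0.9 nm for neighbour enrichment, 0.65 nm for the protein shell, the
#' 15 x 15 thickness grid, the 10-30 ns MSD fit window and the 1-per-100-ns
#' permeation exclusion).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Write the default configuration as an editable template
#'
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path) {
  yaml::write_yaml(config_defaults(), path)
  invisible(path)
}

#' Write a tibble as TSV with a parameter-recording header comment
#'
#' @param x A data frame.
#' @param path Output path.
#' @param params Named list echoed into `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, params = list()) {
  hdr <- c(
    sprintf("# plext %s", as.character(utils::packageVersion("plext"))),
    vapply(
      names(params),
      function(n) sprintf("# %s: %s", n, paste(format(params[[n]]), collapse = " ")),
      character(1)
    )
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
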