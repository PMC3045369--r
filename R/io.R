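# Plain-text readers/writers for the pipeline's external interfaces.
# All tables are TSV; lines starting with '#' are treated as comments so that
# pipeline outputs (which carry a config-hash header) round-trip.

read_tc_tsv <- function(path, what) {
  if (!file.exists(path)) tc_format_error(sprintf("%s file not found: %s", what, path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Read a probe map
#'
#' A probe map is a TSV with columns `probe_id`, `chrom`, `start` (1-based),
#' `length` (bases) and `n_matches` (number of perfect genomic matches), plus
#' an optional logical `is_pm` column. Probe maps are assumed to be
#' pre-filtered to perfect-match probes; when `is_pm` is present, mismatch
#' probes are honoured downstream by [filter_unique_pm()].
#'
#' @param path Path to the TSV file.
#' @return A tibble of probe records.
#' @export
read_probe_map <- function(path) {
  probes <- read_tc_tsv(path, "probe map")
  check_columns(probes, c("probe_id", "chrom", "start", "length", "n_matches"),
                "probe map")
  validate_probes(probes)
  probes
}

validate_probes <- function(probes) {
  check_columns(probes, c("probe_id", "chrom", "start", "length", "n_matches"),
                "probe table")
  if (anyNA(probes$n_matches)) {
    tc_format_error("probe map has missing n_matches values")
  }
  if (any(probes$start < 1) || any(probes$length < 1) || any(probes$n_matches < 1)) {
    tc_format_error("probe map violates start >= 1, length >= 1, n_matches >= 1")
  }
  invisible(probes)
}

#' Read a probe-by-sample intensity table
#'
#' Rows are probes (`probe_id` column), remaining columns are samples named as
#' in the sample sheet. Values are fluorescence intensities on the raw or
#' normalized positive scale.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `probe_id` plus one numeric column per sample.
#' @export
read_intensities <- function(path) {
  x <- read_tc_tsv(path, "intensity")
  check_columns(x, "probe_id", "intensity table")
  x
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `condition` (one of `control`, `treatment`)
#' and `block` (the randomized-block label pairing one control with one
#' treatment sample).
#'
#' @param path Path to the TSV file.
#' @return A tibble of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  s <- read_tc_tsv(path, "sample sheet")
  check_samples(s)
  s
}

#' Read a simulation ground-truth table
#'
#' @param path Path to the TSV written by [write_fixtures()].
#' @return A tibble with per-gene true class, event type, fold and affected
#'   exons.
#' @export
read_truth <- function(path) {
  read_tc_tsv(path, "truth")
}

# Writer used by write_results(): prepends a comment header naming the config
# hash that produced the table, then the TSV body.
write_tc_tsv <- function(df, path, config_hash = NULL) {
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config_hash: %s", config_hash), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
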