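# End-to-end orchestration: build the probe map, normalize, ratio, test,
# estimate FDR, label events; deterministic given inputs and config.

#' Run the full differential-processing pipeline
#'
#' Executes probe-map construction, normalization, ratio generation (with
#' diagnostics), the hierarchical test cascade, optional empirical FDR
#' estimation over a threshold grid, and tentative event classification of
#' detected DPGs.
#'
#' @param probes Probe map tibble ([read_probe_map()]).
#' @param exons Exon annotation table ([read_annotation()]).
#' @param intensities Raw probe-by-sample intensity tibble
#'   ([read_intensities()]).
#' @param samples Sample sheet tibble ([read_sample_sheet()]).
#' @param normalization Passed to [normalize_intensities()].
#' @param pairing,orientation,seed Passed to [compute_ratios()].
#' @param alpha_t,alpha_f,alpha_w Cascade thresholds for the primary calls
#'   (defaults: the strictest DPG row, 1e-4 / 0.05 / 0.05).
#' @param min_probes_per_exon Passed to [make_cdf()].
#' @param fdr Run [estimate_fdr()] over `presets`? (default `FALSE`; needs
#'   block pairing).
#' @param presets Threshold grid for the FDR report.
#' @param events Label DPGs with [classify_events()]? (default `TRUE`).
#' @param delta Deviating-exon threshold for event labelling (log2 units).
#' @return A `tilecall_result` list: `cdf`, `normalized`, `ratios`,
#'   `diagnostics` (qc summaries, exon correlations/SDs, KS normality),
#'   `exon_results`, `calls`, `genes`, `events`, `fdr` and a `manifest`
#'   recording the package version, the full config, its hash and per-stage
#'   counts.
#' @export
run_pipeline <- function(probes, exons, intensities, samples,
                         normalization = "quantile",
                         pairing = "block",
                         orientation = "control/treatment",
                         alpha_t = 1e-4, alpha_f = 0.05, alpha_w = 0.05,
                         min_probes_per_exon = 2,
                         fdr = FALSE, presets = threshold_presets(),
                         events = TRUE, delta = 0.5,
                         seed = NULL) {
  config <- list(
    normalization = normalization, pairing = pairing,
    orientation = orientation, alpha_t = alpha_t, alpha_f = alpha_f,
    alpha_w = alpha_w, min_probes_per_exon = min_probes_per_exon,
    fdr = fdr, presets = if (fdr) as.data.frame(presets) else NULL,
    events = events, delta = delta, seed = seed
  )
  config_hash <- hash(config)

  cdf <- make_cdf(probes, exons, min_probes_per_exon = min_probes_per_exon)
  normalized <- normalize_intensities(intensities, method = normalization)
  qc_before <- qc_intensity_stats(intensities)
  qc_after <- qc_intensity_stats(normalized)
  ratios <- compute_ratios(normalized, samples, pairing = pairing,
                           orientation = orientation, seed = seed)
  diagnostics <- list(
    qc_before = qc_before,
    qc_after = qc_after,
    exon_correlation = exon_correlation(normalized, samples, cdf),
    exon_sd = exon_sd(normalized, samples, ratios, cdf),
    ks = ks_normality(ratios)
  )
  exon_results <- exon_tests(ratios, cdf)
  components <- transcript_tests(ratios, cdf, exon_results = exon_results)
  calls <- classify_transcripts(components, alpha_t = alpha_t,
                                alpha_f = alpha_f, alpha_w = alpha_w)
  genes <- summarize_genes(calls)
  event_calls <- if (events) {
    classify_events(calls, exon_results, alpha_t = alpha_t, delta = delta)
  } else NULL
  fdr_report <- if (fdr) {
    estimate_fdr(normalized, samples, cdf, presets = presets)
  } else NULL

  pv <- cdf_provenance(cdf)
  manifest <- list(
    package = "tilecall",
    version = as.character(utils::packageVersion("tilecall")),
    config = config,
    config_hash = config_hash,
    counts = list(
      probes_in = pv$n_probes_in, probes_kept = pv$n_probes_kept,
      transcripts_tested = nrow(calls),
      genes_tested = nrow(genes),
      calls = as.list(table(calls$status)),
      dpg_events = if (!is.null(event_calls)) as.list(table(event_calls$event)) else NULL
    )
  )
  structure(list(
    cdf = cdf, normalized = normalized, ratios = ratios,
    diagnostics = diagnostics, exon_results = exon_results, calls = calls,
    genes = genes, events = event_calls, fdr = fdr_report,
    manifest = manifest
  ), class = "tilecall_result")
}

#' @export
print.tilecall_result <- function(x, ...) {
  cm <- x$manifest$counts
  cat("<tilecall_result>\n")
  cat(sprintf("  probes: %s kept of %s\n", cm$probes_kept, cm$probes_in))
  cat(sprintf("  transcripts tested: %d (%d genes)\n",
              cm$transcripts_tested, cm$genes_tested))
  cat(sprintf("  calls: %s\n",
              paste(sprintf("%s=%s", names(cm$calls), unlist(cm$calls)),
                    collapse = " ")))
  cat(sprintf("  config hash: %s\n", x$manifest$config_hash))
  invisible(x)
}

#' Write all pipeline result tables to a directory
#'
#' Every table is TSV with a leading comment line naming the config hash that
#' produced it; the manifest is written as YAML.
#'
#' @param result A `tilecall_result`.
#' @param dir Output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!inherits(result, "tilecall_result")) tc_data_error("not a tilecall_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- result$manifest$config_hash
  paths <- c()
  put <- function(df, name) {
    p <- file.path(dir, name)
    write_tc_tsv(as_tibble(df), p, config_hash = h)
    paths[name] <<- p
  }
  put(as_tibble(result$cdf), "cdf.tsv")
  put(result$ratios, "ratios.tsv")
  put(result$diagnostics$qc_before, "qc_before.tsv")
  put(result$diagnostics$qc_after, "qc_after.tsv")
  put(result$diagnostics$exon_correlation, "exon_correlation.tsv")
  put(result$diagnostics$exon_sd, "exon_sd.tsv")
  put(result$diagnostics$ks, "ks_normality.tsv")
  put(select(result$exon_results, -"ss"), "exon_tests.tsv")
  put(as_tibble(result$calls), "transcript_calls.tsv")
  put(result$genes, "gene_summary.tsv")
  if (!is.null(result$events)) put(result$events, "dpg_events.tsv")
  if (!is.null(result$fdr)) {
    fdr_flat <- as_tibble(result$fdr) |>
      mutate(null_counts = vapply(.data$null_counts, paste, character(1),
                                  collapse = ",")) |>
      select("preset", "target_class", "alpha_t", "alpha_f", "alpha_w",
             "n_called", "mean_null", "fdr_percent", "null_counts")
    put(fdr_flat, "fdr_report.tsv")
  }
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(result$manifest, manifest_path)
  paths["manifest.yaml"] <- manifest_path
  invisible(paths)
}

#' Run the pipeline from a YAML config file
#'
#' The config names the four input files (`probe_map`, `annotation`,
#' `intensities`, `samples`), an output directory (`out_dir`) and any of the
#' [run_pipeline()] parameters, with `preset` selecting a named row of
#' [threshold_presets()] for the primary thresholds.
#'
#' @param config_path Path to the YAML file.
#' @return The `tilecall_result`, invisibly, after writing outputs.
#' @export
run_pipeline_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  for (f in c("probe_map", "annotation", "intensities", "samples", "out_dir")) {
    if (is.null(cfg[[f]])) tc_format_error(sprintf("config missing field '%s'", f))
  }
  alphas <- resolve_preset(cfg$preset, cfg$alpha_t, cfg$alpha_f, cfg$alpha_w)
  result <- run_pipeline(
    probes = read_probe_map(cfg$probe_map),
    exons = read_annotation(cfg$annotation),
    intensities = read_intensities(cfg$intensities),
    samples = read_sample_sheet(cfg$samples),
    normalization = cfg$normalization %||% "quantile",
    pairing = cfg$pairing %||% "block",
    orientation = cfg$orientation %||% "control/treatment",
    alpha_t = unname(alphas["alpha_t"]), alpha_f = unname(alphas["alpha_f"]),
    alpha_w = unname(alphas["alpha_w"]),
    min_probes_per_exon = cfg$min_probes_per_exon %||% 2,
    fdr = isTRUE(cfg$fdr), events = !isFALSE(cfg$events),
    delta = cfg$delta %||% 0.5,
    seed = cfg$seed
  )
  write_results(result, cfg$out_dir)
  invisible(result)
}

resolve_preset <- function(preset, alpha_t, alpha_f, alpha_w) {
  if (!is.null(preset)) {
    grid <- threshold_presets()
    row <- grid[grid$preset == preset, ]
    if (nrow(row) != 1) tc_format_error(sprintf("unknown preset '%s'", preset))
    c(alpha_t = row$alpha_t, alpha_f = row$alpha_f, alpha_w = row$alpha_w)
  } else {
    c(alpha_t = alpha_t %||% 1e-4, alpha_f = alpha_f %||% 0.05,
      alpha_w = alpha_w %||% 0.05)
  }
}
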