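# Across-array normalization of the raw probe-by-sample intensity table.
#
# Within-probe condition ratios, not normalization, are this pipeline's
# affinity-cancellation device; normalization only has to remove array-level
# offsets so that ratios compare like with like. Quantile normalization (the
# default) forces every sample onto the common distribution of mean order
# statistics; `median-scale` is a lighter alternative; `none` passes through
# data normalized upstream (e.g. with a variance-stabilizing method).

#' Normalize a probe-by-sample intensity table
#'
#' @param intensities Tibble with `probe_id` plus one positive numeric column
#'   per sample, on the raw intensity scale.
#' @param method `"quantile"` (columns share the across-sample mean order
#'   statistics; ties receive the mean of their candidate quantile values),
#'   `"median-scale"` (each column rescaled so its median equals the grand
#'   median) or `"none"`.
#' @param floor_percentile Optional background floor: this per-column
#'   percentile (e.g. `0.01`) is subtracted before normalization and values
#'   are clamped at 1 fluorescence unit to stay positive. `NULL` (default)
#'   disables it.
#' @return A tibble of the same shape on the positive intensity scale.
#' @details The grand median used by `median-scale` is the lower (type-1)
#'   sample median of the pooled values, so the target is always an observed
#'   intensity.
#' @export
normalize_intensities <- function(intensities,
                                  method = c("quantile", "median-scale", "none"),
                                  floor_percentile = NULL) {
  method <- match.arg(method)
  m <- intensity_matrix(intensities)
  if (ncol(m) < 2) tc_data_error("normalization needs at least 2 samples")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    tc_data_error(sprintf(
      "non-finite intensity for probe '%s' in sample '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    tc_data_error(sprintf(
      "negative intensity for probe '%s' in sample '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  if (!is.null(floor_percentile)) {
    floors <- apply(m, 2, quantile, probs = floor_percentile, names = FALSE)
    m <- pmax(sweep(m, 2, floors, "-"), 1)
  }
  out <- switch(method,
    quantile = limma::normalizeQuantiles(m, ties = TRUE),
    `median-scale` = {
      grand <- quantile(m, 0.5, type = 1, names = FALSE)
      meds <- apply(m, 2, quantile, probs = 0.5, type = 1, names = FALSE)
      if (any(meds == 0)) tc_data_error("median-scale: a column has median 0")
      sweep(m, 2, grand / meds, "*")
    },
    none = m
  )
  res <- as_tibble(out)
  res$probe_id <- intensities$probe_id
  res[c("probe_id", colnames(out))]
}

#' Per-sample five-number summaries of log2 intensities
#'
#' Quality-control companion to before/after-normalization box plots: the
#' across-array spread of the summaries should shrink after normalization.
#'
#' @param intensities Tibble with `probe_id` plus sample columns.
#' @return A `tilecall_qc` tibble with one row per sample and columns `min`,
#'   `q1`, `median`, `q3`, `max` of log2 intensity.
#' @export
qc_intensity_stats <- function(intensities) {
  m <- intensity_matrix(intensities)
  if (nrow(m) == 0) tc_data_error("empty intensity table")
  out <- lapply(colnames(m), function(s) {
    fn <- fivenum(log2(m[, s]))
    tibble(sample_id = s, min = fn[1], q1 = fn[2], median = fn[3],
           q3 = fn[4], max = fn[5])
  })
  out <- bind_rows(out)
  class(out) <- c("tilecall_qc", class(out))
  out
}
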