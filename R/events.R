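# Tentative mechanistic labelling of DPGs.
#
# A differentially processed transcript shows a subset of exons whose ratios
# deviate from the rest. Where that subset sits along the transcript (5'->3'
# by exon_index, which already accounts for strand) suggests a mechanism:
# a 3'-terminal run points to alternative polyadenylation (a poly(A)-site
# shift changes only the distal exons), a 5'-terminal run to alternative
# transcription initiation, an internal run to alternative splicing. The
# labelling is a heuristic formalization of by-eye profile reading and is
# flagged as tentative in all outputs; non-contiguous or unresolvable
# patterns are AMBIGUOUS.

#' Find the deviating exons of one transcript
#'
#' An exon deviates iff its one-sample t-test p-value is below `alpha_t` and
#' its mean log2 ratio lies more than `delta` from the baseline level. The
#' baseline is the median of the means of the *non-significant* exons (those
#' are the unshifted reference; using the median of all exons instead would
#' misplace the baseline whenever the affected run covers most of the
#' transcript). When every exon rejects, the baseline falls back to the
#' median of all exon means, and if every exon then also clears `delta`, the
#' minority-side group relative to that median is taken as deviating (the
#' smaller group; at equal sizes the group farther from zero; a full tie is
#' unresolvable and yields an empty set).
#'
#' @param exon_results Exon-level results of a single transcript
#'   ([exon_tests()] rows), ordered by `exon_index`.
#' @param alpha_t Exon t-test threshold (default 1e-4).
#' @param delta Minimum distance from the median exon mean, in log2 units
#'   (default 0.5; separates isoform-ratio shifts from noise at the
#'   fold-change scale the pipeline targets).
#' @return An integer vector of deviating `exon_index` values (possibly
#'   empty).
#' @export
find_deviating_exons <- function(exon_results, alpha_t = 1e-4, delta = 0.5) {
  check_columns(exon_results, c("exon_index", "mean_log2_ratio", "p_value"),
                "exon results")
  sig <- exon_results$p_value < alpha_t
  if (!any(sig)) return(integer(0))
  if (any(!sig)) {
    baseline <- median(exon_results$mean_log2_ratio[!sig])
    dev <- sig & abs(exon_results$mean_log2_ratio - baseline) > delta
    return(sort(exon_results$exon_index[dev]))
  }
  med <- median(exon_results$mean_log2_ratio)
  dev <- abs(exon_results$mean_log2_ratio - med) > delta
  if (all(dev) && length(dev) > 1) {
    above <- exon_results$mean_log2_ratio > med
    n_above <- sum(above)
    n_below <- sum(!above)
    if (n_above == n_below) {
      d_above <- max(abs(exon_results$mean_log2_ratio[above]))
      d_below <- max(abs(exon_results$mean_log2_ratio[!above]))
      if (d_above == d_below) return(integer(0))
      dev <- if (d_above > d_below) above else !above
    } else {
      dev <- if (n_above < n_below) above else !above
    }
  }
  sort(exon_results$exon_index[dev])
}

#' Classify a deviating-exon pattern into an event type
#'
#' @param deviating Integer vector of deviating exon indices (1..`n_exons`,
#'   5'->3').
#' @param n_exons Total number of (retained) exons in the transcript.
#' @return One of `"APA"` (contiguous run containing the 3'-terminal exon),
#'   `"ALT_INIT"` (contiguous run containing the 5'-terminal exon),
#'   `"ALT_SPLICE"` (contiguous internal run) or `"AMBIGUOUS"` (empty,
#'   non-contiguous, or the whole transcript).
#' @export
classify_event <- function(deviating, n_exons) {
  deviating <- sort(unique(as.integer(deviating)))
  if (length(deviating) == 0 || length(deviating) == n_exons) return("AMBIGUOUS")
  if (any(deviating < 1 | deviating > n_exons)) {
    tc_data_error("deviating exon index outside 1..n_exons")
  }
  contiguous <- all(diff(deviating) == 1)
  if (!contiguous) return("AMBIGUOUS")
  if (n_exons %in% deviating) return("APA")
  if (1 %in% deviating) return("ALT_INIT")
  "ALT_SPLICE"
}

#' Label detected DPGs with tentative event types
#'
#' Runs [find_deviating_exons()] and [classify_event()] over every DPG
#' transcript in a calls table.
#'
#' @param calls A `tilecall_calls` tibble.
#' @param exon_results The matching [exon_tests()] output.
#' @param alpha_t,delta Passed to [find_deviating_exons()].
#' @return A tibble `gene_id`, `transcript_id`, `event`, `deviating_exons`
#'   (comma-separated indices), `direction` (sign of the deviating exons'
#'   mean log2 ratio; 0 when ambiguous).
#' @export
classify_events <- function(calls, exon_results, alpha_t = 1e-4, delta = 0.5) {
  dpg <- as_tibble(calls) |> filter(.data$status == "DPG")
  if (nrow(dpg) == 0) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  event = character(), deviating_exons = character(),
                  direction = integer()))
  }
  ex_split <- split(as_tibble(exon_results), exon_results$transcript_id)
  rows <- lapply(seq_len(nrow(dpg)), function(i) {
    tx <- dpg$transcript_id[i]
    ex <- ex_split[[tx]]
    dev <- find_deviating_exons(ex, alpha_t = alpha_t, delta = delta)
    # classify on the dense rank of the retained exons: map-filtered exons
    # leave gaps in exon_index, and contiguity/terminality can only be judged
    # among the exons actually measured
    retained <- sort(ex$exon_index)
    event <- classify_event(match(dev, retained), length(retained))
    direction <- if (length(dev) == 0) 0L else {
      as.integer(sign(mean(ex$mean_log2_ratio[ex$exon_index %in% dev])))
    }
    tibble(
      gene_id = dpg$gene_id[i], transcript_id = tx, event = event,
      deviating_exons = paste(dev, collapse = ","), direction = direction
    )
  })
  bind_rows(rows)
}
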