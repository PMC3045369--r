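# The hierarchical test cascade.
#
# For each annotated transcript isoform, working on pooled log2 ratios
# (probes of an exon x ratio columns, treated as one i.i.d. sample):
#   gate 1: one-sample two-tailed t-test per exon (H0: mean log2 ratio = 0);
#           a transcript with no exon below alpha_t is not a target (NC);
#   gate 2: one-way ANOVA with exons as levels; unequal exon means below
#           alpha_f mean differential processing (DPG);
#   gate 3: otherwise (equal exon means, or a single exon), a one-sample
#           t-test over the whole transcript below alpha_w means a uniform
#           expression shift (DEG); otherwise NC.
# No multiplicity correction is applied across exons: error control is
# delegated to the empirical FDR from balanced ratio combinations.

#' One-sample two-tailed t-test against mean zero
#'
#' @param x Numeric vector of log2 ratios (n >= 2).
#' @return A one-row tibble `n`, `mean`, `t_stat`, `p_value`, `degenerate`.
#'   Zero variance yields `p = 1` when the mean is exactly 0, otherwise the
#'   `p -> 0` limit with `degenerate = TRUE`.
#' @export
one_sample_t <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) tc_data_error("one_sample_t needs at least 2 values")
  mom <- grouped_moments(x, rep("g", length(x)))
  res <- t_from_moments(mom$n, mom$mean, mom$ss)
  tibble(n = mom$n, mean = mom$mean, res)
}

#' One-way fixed-effects ANOVA
#'
#' F = MS_between / MS_within with df (k - 1, N - k). Groups with fewer than
#' 2 values are excluded with a warning; with fewer than 2 usable groups the
#' test is undefined. Degenerate inputs: all values identical gives `p = 1`
#' (flagged); zero within-group variance with distinct group means gives the
#' `F -> Inf`, `p -> 0` limit (flagged).
#'
#' @param value Numeric vector.
#' @param group Group labels, same length as `value`.
#' @return A one-row tibble `k`, `n`, `f_stat`, `p_value`, `degenerate`.
#' @export
oneway_anova <- function(value, group) {
  mom <- grouped_moments(value, group)
  small <- mom$n < 2
  if (any(small)) {
    warn(sprintf("excluding %d group(s) with < 2 values from ANOVA", sum(small)))
    mom <- mom[!small, , drop = FALSE]
  }
  if (nrow(mom) < 2) tc_data_error("ANOVA needs at least 2 groups with >= 2 values")
  res <- anova_by_key(rep("g", nrow(mom)), mom$n, mom$mean, mom$ss)
  select(res, -"key")
}

# Vectorized one-way ANOVA over many transcripts at once, from per-exon
# moments (n, mean, ss) keyed by transcript. Two-pass between-group SS so
# exactly equal group means give an exact zero.
anova_by_key <- function(key, n, mean, ss) {
  key <- as.character(key)
  N <- rowsum(n, key)
  k <- rowsum(rep(1, length(n)), key)
  grand <- rowsum(n * mean, key) / N
  ssb <- rowsum(n * (mean - grand[key, 1L])^2, key)
  ssw <- rowsum(ss, key)
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  f <- ifelse(msw > 0, msb / msw, ifelse(ssb == 0, NA_real_, Inf))
  p <- ifelse(msw > 0, pf(msb / msw, df1, df2, lower.tail = FALSE),
              ifelse(ssb == 0, 1, 0))
  tibble(
    key = rownames(N),
    k = as.vector(k),
    n = as.vector(N),
    f_stat = as.vector(f),
    p_value = as.vector(p),
    degenerate = as.vector(msw == 0)
  )
}

#' Per-exon one-sample t-tests over a ratio table
#'
#' Pools, for every exon in the map, the log2 ratios of its probes across all
#' ratio columns into one sample and tests H0: mean = 0.
#'
#' @param ratios A log2-ratio tibble from [compute_ratios()].
#' @param cdf A `tilecall_cdf` probe-to-exon map.
#' @return A tibble `gene_id`, `transcript_id`, `exon_index`, `n_ratios`,
#'   `mean_log2_ratio`, `t_stat`, `p_value`, `degenerate`.
#' @export
exon_tests <- function(ratios, cdf) {
  long <- as_tibble(cdf) |>
    inner_join(ratios_long(ratios), by = "probe_id",
               relationship = "many-to-many")
  key <- paste(long$transcript_id, long$exon_index, sep = "\r")
  mom <- grouped_moments(long$log2_ratio, key)
  parts <- strsplit(mom$key, "\r", fixed = TRUE)
  res <- t_from_moments(mom$n, mom$mean, mom$ss)
  gene_of <- long |> distinct(.data$transcript_id, .data$gene_id)
  tibble(
    transcript_id = vapply(parts, `[[`, character(1), 1),
    exon_index = as.integer(vapply(parts, `[[`, character(1), 2)),
    n_ratios = mom$n,
    mean_log2_ratio = mom$mean,
    ss = mom$ss,
    t_stat = res$t_stat,
    p_value = res$p_value,
    degenerate = res$degenerate
  ) |>
    left_join(gene_of, by = "transcript_id") |>
    select("gene_id", "transcript_id", "exon_index", "n_ratios",
           "mean_log2_ratio", "ss", "t_stat", "p_value", "degenerate") |>
    arrange(.data$transcript_id, .data$exon_index)
}

#' Per-transcript test components
#'
#' Aggregates exon-level results into, per transcript: the minimum exon
#' p-value (gate 1), the one-way ANOVA of exon means (gate 2, multi-exon
#' only) and the whole-transcript one-sample t-test (gate 3, pooled over all
#' retained exons). The whole-transcript moments are combined exactly from
#' the exon moments (pooled SS = within-exon SS + between-exon SS).
#'
#' @inheritParams exon_tests
#' @param exon_results Optional precomputed output of [exon_tests()].
#' @return A tibble with one row per transcript: `gene_id`, `transcript_id`,
#'   `n_exons`, `n_ratios`, `min_exon_p`, `anova_f`, `anova_p` (NA for
#'   single-exon transcripts), `whole_t`, `whole_p`,
#'   `whole_mean_log2_ratio`.
#' @export
transcript_tests <- function(ratios, cdf, exon_results = NULL) {
  ex <- exon_results %||% exon_tests(ratios, cdf)

  per_tx <- ex |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(
      n_exons = n(),
      min_exon_p = min(.data$p_value),
      grand = sum(.data$n_ratios * .data$mean_log2_ratio) / sum(.data$n_ratios),
      ssw = sum(.data$ss),
      ssb = sum(.data$n_ratios * (.data$mean_log2_ratio - grand)^2),
      n_ratios = sum(.data$n_ratios),   # last: masks the per-exon column
      .groups = "drop"
    ) |>
    arrange(.data$transcript_id)

  # gate 2: ANOVA across exons, multi-exon transcripts only
  anova_res <- tibble(f_stat = rep(NA_real_, nrow(per_tx)),
                      p_value = NA_real_, degenerate = FALSE)
  multi_tx <- per_tx$transcript_id[per_tx$n_exons > 1]
  if (length(multi_tx) > 0) {
    sel <- ex$transcript_id %in% multi_tx
    av <- anova_by_key(ex$transcript_id[sel], ex$n_ratios[sel],
                       ex$mean_log2_ratio[sel], ex$ss[sel])
    idx <- match(av$key, per_tx$transcript_id)
    anova_res$f_stat[idx] <- av$f_stat
    anova_res$p_value[idx] <- av$p_value
    anova_res$degenerate[idx] <- av$degenerate
  }

  # gate 3: whole-transcript t from exactly pooled moments
  whole <- t_from_moments(per_tx$n_ratios, per_tx$grand,
                          per_tx$ssw + per_tx$ssb)

  per_tx |>
    transmute(
      .data$gene_id, .data$transcript_id, .data$n_exons, .data$n_ratios,
      .data$min_exon_p,
      anova_f = anova_res$f_stat,
      anova_p = anova_res$p_value,
      anova_degenerate = anova_res$degenerate,
      whole_t = whole$t_stat,
      whole_p = whole$p_value,
      whole_mean_log2_ratio = per_tx$grand
    )
}

#' Classify transcripts as DPG, DEG or NC
#'
#' Applies the decision tree to precomputed test components: (1) no exon
#' below `alpha_t` is NC; (2) multi-exon with ANOVA p below `alpha_f` is DPG;
#' (3) otherwise (equal exon means, or single-exon) a whole-transcript p
#' below `alpha_w` is DEG; (4) otherwise NC.
#'
#' @param components Output of [transcript_tests()].
#' @param alpha_t Exon-level t-test threshold (default 1e-4).
#' @param alpha_f ANOVA threshold (default 0.05).
#' @param alpha_w Whole-transcript t-test threshold (default 0.05).
#' @return A `tilecall_calls` tibble: the components plus a `status` column
#'   (`DPG`, `DEG` or `NC`), with thresholds recorded as attributes.
#' @export
classify_transcripts <- function(components, alpha_t = 1e-4, alpha_f = 0.05,
                                 alpha_w = 0.05) {
  check_columns(components, c("n_exons", "min_exon_p", "anova_p", "whole_p"),
                "transcript components")
  candidate <- components$min_exon_p < alpha_t
  multi <- components$n_exons > 1
  dpg <- candidate & multi & !is.na(components$anova_p) &
    components$anova_p < alpha_f
  deg <- candidate & !dpg & components$whole_p < alpha_w
  out <- components
  out$status <- ifelse(dpg, "DPG", ifelse(deg, "DEG", "NC"))
  attr(out, "thresholds") <- c(alpha_t = alpha_t, alpha_f = alpha_f,
                               alpha_w = alpha_w)
  class(out) <- c("tilecall_calls", class(out))
  out
}

#' Run the full cascade on a ratio table
#'
#' Convenience wrapper: [transcript_tests()] followed by
#' [classify_transcripts()].
#'
#' @inheritParams exon_tests
#' @inheritParams classify_transcripts
#' @return A `tilecall_calls` tibble (see [classify_transcripts()]).
#' @export
call_transcripts <- function(ratios, cdf, alpha_t = 1e-4, alpha_f = 0.05,
                             alpha_w = 0.05) {
  classify_transcripts(transcript_tests(ratios, cdf),
                       alpha_t = alpha_t, alpha_f = alpha_f, alpha_w = alpha_w)
}

#' Summarize transcript calls per gene
#'
#' A gene is DPG if any isoform is DPG, else DEG if any isoform is DEG, else
#' NC; isoform detail is retained in list form.
#'
#' @param calls A `tilecall_calls` tibble.
#' @return A tibble `gene_id`, `status`, `n_isoforms`, `isoform_statuses`.
#' @export
summarize_genes <- function(calls) {
  check_columns(calls, c("gene_id", "transcript_id", "status"), "calls")
  as_tibble(calls) |>
    group_by(.data$gene_id) |>
    summarise(
      status = if (any(.data$status == "DPG")) "DPG"
               else if (any(.data$status == "DEG")) "DEG" else "NC",
      n_isoforms = n(),
      isoform_statuses = paste(.data$status, collapse = ","),
      .groups = "drop"
    )
}

#' @export
print.tilecall_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  counts <- table(factor(x$status, levels = c("DPG", "DEG", "NC")))
  cat(sprintf(
    "<tilecall_calls> %d transcripts at (alpha_t=%g, alpha_f=%g, alpha_w=%g): %d DPG, %d DEG, %d NC\n",
    nrow(x), th["alpha_t"], th["alpha_f"], th["alpha_w"],
    counts["DPG"], counts["DEG"], counts["NC"]
  ))
  NextMethod()
}
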