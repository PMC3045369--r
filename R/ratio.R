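# Within-block condition ratios: the affinity-cancellation step.
#
# A probe's fluorescence is (roughly) background + affinity x abundance x
# block x noise, with the affinity term shared between the two samples of a
# block. Dividing the control by the treatment intensity probe-wise therefore
# cancels the probe-specific affinity (and the block effect), leaving a
# quantity whose log2 is centred on the log2 abundance ratio. All downstream
# tests operate on these log2 ratios.

#' Compute per-probe log2 condition ratios
#'
#' @param normalized Tibble with `probe_id` plus one positive column per
#'   sample (output of [normalize_intensities()]).
#' @param samples Sample sheet tibble (`sample_id`, `condition`, `block`).
#' @param pairing `"block"` (default): one ratio per block, pairing the
#'   block's control and treatment samples — the randomized-block design.
#'   `"random-independent"`: for a completely randomized design, a seeded
#'   random perfect matching of control to treatment replicates is drawn and
#'   one ratio per matched pair is produced; the matching is recorded in the
#'   `pairing` attribute.
#' @param orientation `"control/treatment"` (default) or
#'   `"treatment/control"`: which condition is the numerator. Downstream
#'   tests are two-tailed and invariant to this choice.
#' @param seed Integer seed, required for `pairing = "random-independent"`.
#' @return A tibble with `probe_id` plus one log2-ratio column per block (or
#'   matched pair), with attributes `orientation` and `pairing`.
#' @export
compute_ratios <- function(normalized, samples,
                           pairing = c("block", "random-independent"),
                           orientation = c("control/treatment",
                                           "treatment/control"),
                           seed = NULL) {
  pairing <- match.arg(pairing)
  orientation <- match.arg(orientation)
  check_samples(samples)
  m <- intensity_matrix(normalized, samples)
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)
    tc_data_error(sprintf(
      "non-positive intensity for probe '%s' in sample '%s'; ratios need positive values",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }

  ctrl <- samples[samples$condition == "control", ]
  trt <- samples[samples$condition == "treatment", ]
  if (pairing == "block") {
    pairs <- inner_join(
      ctrl |> select(block = "block", control_sample = "sample_id"),
      trt |> select(block = "block", treatment_sample = "sample_id"),
      by = "block"
    )
    counts <- table(c(ctrl$block, trt$block))
    if (nrow(pairs) != length(unique(samples$block)) ||
        nrow(pairs) != nrow(ctrl) || nrow(pairs) != nrow(trt) ||
        any(counts != 2)) {
      tc_data_error("block pairing requires exactly one control and one treatment sample per block")
    }
    pairs <- arrange(pairs, .data$block)
    col_names <- as.character(pairs$block)
  } else {
    if (is.null(seed)) tc_data_error("random-independent pairing requires a seed")
    if (nrow(ctrl) != nrow(trt)) {
      tc_data_error("random-independent pairing requires equal replicate counts")
    }
    perm <- withr::with_seed(seed, sample.int(nrow(trt)))
    pairs <- tibble(
      block = paste0("pair", seq_len(nrow(ctrl))),
      control_sample = sort(ctrl$sample_id),
      treatment_sample = sort(trt$sample_id)[perm]
    )
    col_names <- pairs$block
  }

  num <- m[, pairs$control_sample, drop = FALSE]
  den <- m[, pairs$treatment_sample, drop = FALSE]
  lr <- log2(num) - log2(den)
  if (orientation == "treatment/control") lr <- -lr
  colnames(lr) <- col_names

  out <- as_tibble(lr)
  out$probe_id <- normalized$probe_id
  out <- out[c("probe_id", col_names)]
  attr(out, "orientation") <- orientation
  attr(out, "pairing") <- pairs
  out
}

# Long form of a ratio table: probe_id, ratio_column, log2_ratio.
ratios_long <- function(ratios) {
  check_columns(ratios, "probe_id", "ratio table")
  pivot_longer(ratios, -"probe_id", names_to = "ratio_column",
               values_to = "log2_ratio")
}

#' Per-exon correlation between condition probe profiles
#'
#' For each exon with at least `min_probes` probes, the Pearson correlation
#' between the control and treatment probe profiles (each profile being the
#' per-probe mean log2 intensity across that condition's replicates). High
#' correlations are the footprint of shared probe affinity and the empirical
#' justification for ratioing it away.
#'
#' @inheritParams compute_ratios
#' @param cdf A `tilecall_cdf` probe-to-exon map.
#' @param min_probes Minimum probes per exon (default 3).
#' @return A tibble `transcript_id`, `exon_index`, `n_probes`, `r`; exons
#'   with a zero-variance profile get `r = NA`. The five-number summary of
#'   `r` across exons is attached as attribute `fivenum`.
#' @export
exon_correlation <- function(normalized, samples, cdf, min_probes = 3) {
  check_samples(samples)
  m <- intensity_matrix(normalized, samples)
  lm2 <- log2(pmax(m, .Machine$double.xmin))
  prof <- vapply(.conditions, function(cond) {
    cols <- samples$sample_id[samples$condition == cond]
    rowMeans(lm2[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  prof_tbl <- tibble(
    probe_id = rownames(m),
    control = prof[, "control"],
    treatment = prof[, "treatment"]
  )
  out <- as_tibble(cdf) |>
    inner_join(prof_tbl, by = "probe_id") |>
    group_by(.data$transcript_id, .data$exon_index) |>
    filter(n() >= min_probes) |>
    summarise(
      n_probes = n(),
      r = {
        sc <- sd(.data$control)
        st <- sd(.data$treatment)
        if (is.na(sc) || is.na(st) || sc == 0 || st == 0) NA_real_
        else stats::cor(.data$control, .data$treatment)
      },
      .groups = "drop"
    )
  attr(out, "fivenum") <- fivenum(out$r, na.rm = TRUE)
  out
}

#' Per-exon spread of intensities versus ratios
#'
#' For each exon: the standard deviation across probes of (i) the per-condition
#' mean log2 intensity and (ii) the per-probe mean log2 ratio across blocks.
#' When probe affinity dominates the noise, the ratio SD sits well below the
#' intensity SDs — the variance reduction the ratio step buys.
#'
#' @inheritParams exon_correlation
#' @param ratios A log2-ratio tibble from [compute_ratios()].
#' @return A tibble `transcript_id`, `exon_index`, `n_probes`,
#'   `sd_intensity_control`, `sd_intensity_treatment`, `sd_ratio`, with the
#'   across-exon medians attached as attribute `medians`.
#' @export
exon_sd <- function(normalized, samples, ratios, cdf, min_probes = 3) {
  check_samples(samples)
  m <- intensity_matrix(normalized, samples)
  lm2 <- log2(pmax(m, .Machine$double.xmin))
  rl <- intensity_matrix(ratios)  # ratio table has the same shape contract
  per_probe <- tibble(
    probe_id = rownames(m),
    int_control = rowMeans(lm2[, samples$sample_id[samples$condition == "control"],
                               drop = FALSE]),
    int_treatment = rowMeans(lm2[, samples$sample_id[samples$condition == "treatment"],
                                 drop = FALSE]),
    mean_ratio = rowMeans(rl)[match(rownames(m), rownames(rl))]
  )
  out <- as_tibble(cdf) |>
    inner_join(per_probe, by = "probe_id") |>
    group_by(.data$transcript_id, .data$exon_index) |>
    filter(n() >= min_probes) |>
    summarise(
      n_probes = n(),
      sd_intensity_control = sd(.data$int_control),
      sd_intensity_treatment = sd(.data$int_treatment),
      sd_ratio = sd(.data$mean_ratio),
      .groups = "drop"
    )
  attr(out, "medians") <- c(
    sd_intensity_control = median(out$sd_intensity_control),
    sd_intensity_treatment = median(out$sd_intensity_treatment),
    sd_ratio = median(out$sd_ratio)
  )
  out
}

#' One-sample Kolmogorov-Smirnov normality check of pooled log2 ratios
#'
#' Tests the pooled log2 ratios against a normal distribution with the
#' sample's own mean and SD. Reported for QC only — approximate normality
#' justifies the t/F machinery downstream, but the pipeline never gates on
#' this p-value. Because the reference parameters are estimated from the same
#' sample, the plain KS p-value is conservative (a Lilliefors-type caveat).
#'
#' @param ratios A log2-ratio tibble from [compute_ratios()].
#' @return A one-row tibble `n`, `mean`, `sd`, `statistic`, `p_value`;
#'   degenerate (constant) input yields `NA` statistics.
#' @export
ks_normality <- function(ratios) {
  x <- as.vector(intensity_matrix(ratios))
  x <- x[is.finite(x)]
  if (length(x) < 30) tc_data_error("KS normality check needs at least 30 ratios")
  if (sd(x) == 0) {
    inform("constant ratios: KS normality check undefined")
    return(tibble(n = length(x), mean = mean(x), sd = 0,
                  statistic = NA_real_, p_value = NA_real_))
  }
  kt <- suppressWarnings(ks.test(x, "pnorm", mean = mean(x), sd = sd(x)))
  tibble(n = length(x), mean = mean(x), sd = sd(x),
         statistic = unname(kt$statistic), p_value = kt$p.value)
}
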