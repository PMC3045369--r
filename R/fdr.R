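# Empirical FDR from balanced combinations of forward and reversed ratios.
#
# With three blocks there are only three ratio columns, too few to mix equal
# numbers of forward (control/treatment) and reversed (treatment/control)
# ratios. A fourth pseudo-replicate per condition — the per-probe geometric
# mean of that condition's three columns — makes four ratio columns, and the
# choose(4, 2) = 6 sign patterns with exactly two columns reversed form the
# balanced null: genuine condition effects cancel in every pattern, so genes
# called significant under them are false discoveries. The FDR at a
# threshold pair is the mean null call count over all 6 patterns divided by
# the observed call count.

#' Geometric-mean pseudo-replicate
#'
#' Per-probe geometric mean of a condition's replicate columns. On the log2
#' scale this is exactly the arithmetic mean of the replicate log2 columns.
#'
#' @param x Numeric matrix or data frame of positive replicate columns
#'   (probes x replicates).
#' @return A numeric vector, one value per probe.
#' @export
make_pseudo_replicate <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) < 2) {
    tc_data_error("pseudo-replicate needs >= 2 numeric replicate columns")
  }
  if (any(m <= 0)) tc_data_error("pseudo-replicate needs positive intensities")
  2^rowMeans(log2(m))
}

#' Enumerate balanced sign combinations
#'
#' All sign vectors over `n_pairs` ratio columns with exactly half the
#' entries reversed, in deterministic (combn) order. With 4 columns these are
#' the 6 patterns of two forward and two reversed ratios, forming 3
#' complementary (fully inverted) pairs.
#'
#' @param n_pairs Even number of ratio columns (default 4).
#' @return An integer matrix with one row per combination, entries +1
#'   (forward) or -1 (reversed).
#' @export
enumerate_balanced <- function(n_pairs = 4) {
  if (n_pairs %% 2 != 0 || n_pairs < 2) {
    tc_data_error("balanced combinations need an even number of ratio columns")
  }
  picks <- utils::combn(n_pairs, n_pairs / 2)
  flips <- matrix(1L, nrow = ncol(picks), ncol = n_pairs)
  for (i in seq_len(ncol(picks))) flips[i, picks[, i]] <- -1L
  flips
}

# Builds the 4-column ratio set: blocks 1..n plus a pseudo-block pairing the
# two conditions' geometric-mean pseudo-replicates index-wise.
augmented_ratios <- function(normalized, samples, orientation = "control/treatment") {
  check_samples(samples)
  m <- intensity_matrix(normalized, samples)
  aug <- normalized[c("probe_id", samples$sample_id)]
  meta <- samples
  for (cond in .conditions) {
    cols <- samples$sample_id[samples$condition == cond]
    if (length(cols) < 2) tc_data_error("pseudo-replicate needs >= 2 replicates per condition")
    nm <- paste0("pseudo_", cond)
    aug[[nm]] <- make_pseudo_replicate(m[, cols, drop = FALSE])
    meta <- bind_rows(meta, tibble(sample_id = nm, condition = cond,
                                   block = "zz_pseudo"))
  }
  compute_ratios(aug, meta, pairing = "block", orientation = orientation)
}

# Applies a sign pattern to a ratio table (flipping a column's orientation =
# negating its log2 ratios).
flip_ratios <- function(ratios, flips) {
  cols <- setdiff(names(ratios), "probe_id")
  if (length(flips) != length(cols)) {
    tc_data_error("flip vector length must equal the number of ratio columns")
  }
  for (i in seq_along(cols)) {
    ratios[[cols[i]]] <- ratios[[cols[i]]] * flips[i]
  }
  ratios
}

#' Threshold presets for the cascade
#'
#' The named grid of (alpha_t, alpha_f, alpha_w) triples at which calls and
#' FDR are reported: five DPG rows with the exon-level threshold tightening
#' from 0.05 to 1e-4 (ANOVA at 0.05 except one row at 0.01, whole-transcript
#' test fixed at 0.05), and five DEG rows tightening the t thresholds from
#' 0.05 to 1e-5 with ANOVA fixed at 0.05. For DEG rows the varying value is
#' applied to both the exon-level and the whole-transcript t-test. The
#' strictest rows are named `strict-dpg` and `strict-deg`.
#'
#' @return A tibble `preset`, `target_class`, `alpha_t`, `alpha_f`,
#'   `alpha_w`.
#' @export
threshold_presets <- function() {
  dpg_t <- c(0.05, 0.01, 0.01, 0.001, 0.0001)
  dpg_f <- c(0.05, 0.05, 0.01, 0.05, 0.05)
  deg_t <- c(0.05, 0.01, 0.001, 0.0001, 0.00001)
  bind_rows(
    tibble(
      preset = c(paste0("dpg-t", dpg_t[-5], "-f", dpg_f[-5]), "strict-dpg"),
      target_class = "DPG",
      alpha_t = dpg_t, alpha_f = dpg_f, alpha_w = 0.05
    ),
    tibble(
      preset = c(paste0("deg-t", deg_t[-5]), "strict-deg"),
      target_class = "DEG",
      alpha_t = deg_t, alpha_f = 0.05, alpha_w = deg_t
    )
  )
}

#' Estimate the empirical FDR over a threshold grid
#'
#' For every preset: (1) the observed call count from the real block-paired
#' ratio columns; (2) six null call counts from the balanced sign patterns
#' applied to the 4-column ratio set (3 blocks + geometric-mean
#' pseudo-block); (3) FDR = mean null count / observed count.
#'
#' @param normalized Normalized intensity tibble.
#' @param samples Sample sheet tibble (3 or more blocks).
#' @param cdf A `tilecall_cdf` probe-to-exon map.
#' @param presets Threshold grid, defaults to [threshold_presets()].
#' @param orientation Numerator convention passed to [compute_ratios()];
#'   all counts are two-tailed and invariant to it.
#' @param observed_from `"three-ratio"` (default): observed counts come from
#'   the real per-block ratio columns, mirroring the asymmetry of the
#'   original protocol (nulls have 4 columns and so slightly different
#'   degrees of freedom). `"four-ratio"`: observed counts come from the
#'   unflipped 4-column set, for df-consistency with the nulls.
#' @return A `tilecall_fdr` tibble: one row per preset with `n_called`,
#'   `mean_null`, `fdr`, `fdr_percent` and the six null counts as a list
#'   column.
#' @export
estimate_fdr <- function(normalized, samples, cdf,
                         presets = threshold_presets(),
                         orientation = "control/treatment",
                         observed_from = c("three-ratio", "four-ratio")) {
  observed_from <- match.arg(observed_from)
  check_columns(presets, c("preset", "target_class", "alpha_t", "alpha_f",
                           "alpha_w"), "preset grid")

  obs_ratios <- compute_ratios(normalized, samples, pairing = "block",
                               orientation = orientation)
  aug <- augmented_ratios(normalized, samples, orientation = orientation)
  obs_components <- if (observed_from == "three-ratio") {
    transcript_tests(obs_ratios, cdf)
  } else {
    transcript_tests(aug, cdf)
  }
  flips <- enumerate_balanced(ncol(aug) - 1)
  null_components <- lapply(seq_len(nrow(flips)), function(i) {
    transcript_tests(flip_ratios(aug, flips[i, ]), cdf)
  })

  count_class <- function(components, row) {
    calls <- classify_transcripts(components, row$alpha_t, row$alpha_f,
                                  row$alpha_w)
    sum(calls$status == row$target_class)
  }
  rows <- lapply(seq_len(nrow(presets)), function(j) {
    row <- presets[j, ]
    n_called <- count_class(obs_components, row)
    null_counts <- vapply(null_components, count_class, numeric(1), row = row)
    mean_null <- mean(null_counts)
    tibble(
      row,
      n_called = n_called,
      mean_null = mean_null,
      fdr = if (n_called > 0) mean_null / n_called else NA_real_,
      fdr_percent = if (n_called > 0) 100 * mean_null / n_called else NA_real_,
      null_counts = list(null_counts)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("tilecall_fdr", class(out))
  out
}

#' @export
print.tilecall_fdr <- function(x, ...) {
  cat("<tilecall_fdr> empirical FDR from balanced ratio combinations\n")
  NextMethod()
}
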