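# broom-style accessors and plots for fitted result objects.

#' @exportS3Method generics::tidy
tidy.tilecall_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @exportS3Method generics::glance
glance.tilecall_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_transcripts = nrow(x),
    n_dpg = sum(x$status == "DPG"),
    n_deg = sum(x$status == "DEG"),
    n_nc = sum(x$status == "NC"),
    alpha_t = unname(th["alpha_t"]),
    alpha_f = unname(th["alpha_f"]),
    alpha_w = unname(th["alpha_w"])
  )
}

#' @exportS3Method generics::tidy
tidy.tilecall_result <- function(x, ...) tidy(x$calls)

#' @exportS3Method generics::glance
glance.tilecall_result <- function(x, ...) {
  g <- glance(x$calls)
  g$n_genes <- nrow(x$genes)
  g$config_hash <- x$manifest$config_hash
  g
}

#' @exportS3Method ggplot2::autoplot
autoplot.tilecall_calls <- function(object, ...) {
  df <- as_tibble(object)
  df$status <- factor(df$status, levels = c("NC", "DEG", "DPG"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$whole_mean_log2_ratio,
    y = -log10(pmax(.data$min_exon_p, 1e-300)),
    colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(NC = "grey60", DEG = "#2166ac", DPG = "#b2182b")
    ) +
    ggplot2::labs(
      x = "whole-transcript mean log2 ratio (control/treatment)",
      y = "-log10 minimum exon p-value",
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tilecall_qc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$sample_id)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", fill = "grey85"
    ) +
    ggplot2::labs(x = NULL, y = "log2 intensity") +
    ggplot2::theme_minimal()
}

#' Plot the exon-wise ratio profile of one transcript
#'
#' Probe-level log2 ratios along the transcript (5'->3'), grouped by exon,
#' with per-exon mean bars — the profile read to judge which exons deviate
#' and hence which processing event a DPG call suggests.
#'
#' @param ratios A log2-ratio tibble from [compute_ratios()].
#' @param cdf A `tilecall_cdf` map.
#' @param transcript_id The transcript to plot.
#' @return A ggplot object.
#' @export
plot_transcript <- function(ratios, cdf, transcript_id) {
  sel <- as_tibble(cdf) |> filter(.data$transcript_id == !!transcript_id)
  if (nrow(sel) == 0) tc_data_error(sprintf("transcript '%s' not in map", transcript_id))
  long <- sel |>
    inner_join(ratios_long(ratios), by = "probe_id") |>
    arrange(.data$exon_index) |>
    mutate(probe_pos = match(.data$probe_id, unique(.data$probe_id)))
  means <- long |>
    group_by(.data$exon_index) |>
    summarise(mean_ratio = mean(.data$log2_ratio),
              xmin = min(.data$probe_pos) - 0.4, xmax = max(.data$probe_pos) + 0.4,
              .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$probe_pos, y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$exon_index)),
                        alpha = 0.7) +
    ggplot2::geom_segment(
      data = means,
      ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                   y = .data$mean_ratio, yend = .data$mean_ratio),
      linewidth = 1
    ) +
    ggplot2::labs(x = "probe (5' to 3')", y = "log2 ratio",
                  colour = "exon", title = transcript_id) +
    ggplot2::theme_minimal()
}
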