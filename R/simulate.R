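# Seeded generator of synthetic tiling-array experiments with known truth.
#
# Generative model, per probe p and sample s:
#   intensity = background + affinity_p * abundance_{exon(p), cond(s)}
#               * block_{block(s)} * array_s * noise_{p,s}
# with affinity = 2^N(0, sigma_affinity^2) shared across all samples (the
# mechanism the ratio step cancels), block/array/noise likewise log-normal.
# Each gene carries one annotated isoform; DPG genes additionally express an
# unannotated shorter isoform lacking a contiguous exon run (3'-terminal for
# APA, 5'-terminal for alternative initiation, internal for alternative
# splicing), and the long:short mixture proportions swap between conditions.
# DEG genes scale all exons by a common fold. All random draws are standard
# normal/uniform scaled afterwards, so the draw sequence — and hence the
# realized gene structures — do not depend on the variance settings.

# sample() treats a length-1 numeric first argument as 1:x; this doesn't.
resample <- function(x, n = 1, ...) x[sample.int(length(x), n, ...)]

#' Build a simulation configuration
#'
#' Defaults mirror a three-block Affymetrix-style tiling experiment: 25-mer
#' probes every 35 bp, probe affinity SD 0.7 log2 units and multiplicative
#' noise SD 0.25 log2 units (matching within-exon intensity SDs around
#' 0.65-0.7 and ratio SDs around 0.4 seen on real tiling data), 4-fold
#' effects for both DPG isoform shifts (80:20 to 20:80 long:short) and DEG
#' fold changes.
#'
#' @param seed Integer seed (mandatory; the generator is fully deterministic
#'   given the config).
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length Range `c(min, max)` of exon lengths in bp.
#' @param intron_length,intergenic Fixed intron / intergenic gap sizes (bp).
#' @param probe_step,probe_length Tiling step and probe length (bp).
#' @param frac_deg,deg_fold Fraction of DEG genes and their linear fold.
#' @param frac_dpg Fraction of DPG genes.
#' @param event_mix Named probabilities over `APA`, `ALT_INIT`, `ALT_SPLICE`.
#' @param isoform_major Long-isoform proportion in the condition where it
#'   dominates; it swaps to `1 - isoform_major` in the other condition, so
#'   affected exons shift by `isoform_major / (1 - isoform_major)`-fold
#'   (4-fold at the 0.8 default).
#' @param sigma_affinity,sigma_noise SDs (log2) of probe affinity and
#'   probe-by-sample noise.
#' @param block_sd,array_sd SDs (log2) of the per-block and per-array
#'   multiplicative effects.
#' @param background Additive background floor (fluorescence units). Defaults
#'   to 0: the generator emulates background-corrected data, and a zero floor
#'   makes affinities cancel exactly in ratios.
#' @param mean_log2_expr,sd_log2_expr Distribution of gene base abundance,
#'   `2^N(mean, sd^2)`.
#' @param n_blocks Number of randomized blocks (one control + one treatment
#'   sample each).
#' @param frac_nonunique Fraction of probes marked with `n_matches = 2`
#'   (removed by the unique-match filter).
#' @param intergenic_probes Also tile introns and intergenic gaps (these
#'   probes receive background-only signal and exercise the border filter).
#' @return A validated `tilecall_sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 200,
                       exons_per_gene = c(3, 8),
                       exon_length = c(90, 250),
                       intron_length = 80,
                       intergenic = 500,
                       probe_step = 35,
                       probe_length = 25,
                       frac_deg = 0.05,
                       deg_fold = 4,
                       frac_dpg = 0.05,
                       event_mix = c(APA = 0.5, ALT_INIT = 0.25, ALT_SPLICE = 0.25),
                       isoform_major = 0.8,
                       sigma_affinity = 0.7,
                       sigma_noise = 0.25,
                       block_sd = 0.2,
                       array_sd = 0.3,
                       background = 0,
                       mean_log2_expr = 9,
                       sd_log2_expr = 1,
                       n_blocks = 3,
                       frac_nonunique = 0,
                       intergenic_probes = FALSE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    tc_data_error("sim_config: a seed is mandatory")
  }
  cfg <- as.list(environment())
  stopifnot_cfg <- function(ok, msg) if (!ok) tc_data_error(paste("sim_config:", msg))
  stopifnot_cfg(n_genes >= 1, "n_genes must be >= 1")
  stopifnot_cfg(length(exons_per_gene) == 2 && exons_per_gene[1] >= 1 &&
                  exons_per_gene[1] <= exons_per_gene[2],
                "exons_per_gene must be an increasing range")
  stopifnot_cfg(all(c(frac_deg, frac_dpg, frac_nonunique) >= 0) &&
                  all(c(frac_deg, frac_dpg, frac_nonunique) <= 1),
                "fractions must lie in [0, 1]")
  stopifnot_cfg(frac_deg + frac_dpg <= 1, "effect fractions must sum to <= 1")
  stopifnot_cfg(all(c(sigma_affinity, sigma_noise, block_sd, array_sd,
                      sd_log2_expr) >= 0), "SDs must be >= 0")
  stopifnot_cfg(isoform_major > 0.5 && isoform_major < 1,
                "isoform_major must lie in (0.5, 1)")
  stopifnot_cfg(deg_fold > 0, "deg_fold must be positive")
  stopifnot_cfg(background >= 0, "background must be >= 0")
  stopifnot_cfg(n_blocks >= 2, "n_blocks must be >= 2")
  stopifnot_cfg(abs(sum(event_mix) - 1) < 1e-8 &&
                  setequal(names(event_mix), c("APA", "ALT_INIT", "ALT_SPLICE")),
                "event_mix must be named APA/ALT_INIT/ALT_SPLICE probabilities summing to 1")
  class(cfg) <- "tilecall_sim_config"
  cfg
}

# Chooses the affected exon run for an event type, in exon_index (5'->3')
# coordinates.
pick_affected_run <- function(event, n_exons) {
  if (event == "APA") {
    k <- resample(seq_len(n_exons - 1))
    (n_exons - k + 1):n_exons
  } else if (event == "ALT_INIT") {
    k <- resample(seq_len(n_exons - 1))
    1:k
  } else {
    len <- resample(seq_len(n_exons - 2))
    start <- resample(2:(n_exons - len))
    start:(start + len - 1)
  }
}

#' Simulate a tiling-array experiment
#'
#' @param cfg A [sim_config()] object.
#' @return A `tilecall_sim` list with elements `probes` (probe map tibble),
#'   `exons` (annotation table as from [read_annotation()]), `intensities`
#'   (raw probe-by-sample tibble), `samples` (sample sheet) and `truth`
#'   (per-gene class, event, realized control/treatment fold and affected
#'   exons), plus the config.
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "tilecall_sim_config")) {
    tc_data_error("cfg must come from sim_config()")
  }
  withr::with_seed(as.integer(cfg$seed), simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  tx_id <- paste0(gene_id, ".1")

  ## gene structure
  n_exons <- if (cfg$exons_per_gene[1] == cfg$exons_per_gene[2]) {
    rep(cfg$exons_per_gene[1], n)
  } else {
    resample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), n, replace = TRUE)
  }
  strand <- resample(c("+", "-"), n, replace = TRUE)
  total_exons <- sum(n_exons)
  g_of_exon <- rep(seq_len(n), n_exons)
  lens <- floor(runif(total_exons, cfg$exon_length[1], cfg$exon_length[2] + 1))
  # genomic layout: exons separated by introns within a gene, genes by
  # intergenic gaps; cumulative-sum bookkeeping instead of a per-exon loop
  within_first <- !duplicated(g_of_exon)
  gap_before <- ifelse(within_first, cfg$intergenic, cfg$intron_length)
  starts <- cumsum(gap_before + c(0, lens[-total_exons]))
  ends <- starts + lens - 1
  genomic_pos <- stats::ave(starts, g_of_exon, FUN = seq_along)
  exon_index <- as.integer(ifelse(strand[g_of_exon] == "-",
                                  n_exons[g_of_exon] - genomic_pos + 1,
                                  genomic_pos))
  exons <- tibble(
    gene_id = gene_id[g_of_exon], transcript_id = tx_id[g_of_exon],
    exon_index = exon_index, chrom = "chr1",
    start = starts, end = ends, strand = strand[g_of_exon]
  ) |>
    arrange(.data$transcript_id, .data$exon_index)
  introns <- tibble(start = head(ends, -1) + 1, end = tail(starts, -1) - 1)
  introns <- introns[head(g_of_exon, -1) == tail(g_of_exon, -1), , drop = FALSE]

  ## ground-truth classes
  n_dpg <- round(cfg$frac_dpg * n)
  n_deg <- round(cfg$frac_deg * n)
  affected_ids <- resample(seq_len(n), n_dpg + n_deg)
  class <- rep("NULL", n)
  class[affected_ids[seq_len(n_dpg)]] <- "DPG"
  if (n_deg > 0) class[affected_ids[n_dpg + seq_len(n_deg)]] <- "DEG"
  direction <- resample(c(1, -1), n, replace = TRUE)

  event <- rep(NA_character_, n)
  affected <- vector("list", n)
  l_ctrl <- l_trt <- rep(1, n)   # long-isoform fractions
  fold <- rep(1, n)              # realized control/treatment ratio on affected exons
  minor <- 1 - cfg$isoform_major
  for (g in which(class == "DPG")) {
    ev <- resample(names(cfg$event_mix), 1, prob = cfg$event_mix)
    if (ev == "ALT_SPLICE" && n_exons[g] < 3) ev <- resample(c("APA", "ALT_INIT"))
    event[g] <- ev
    affected[[g]] <- pick_affected_run(ev, n_exons[g])
    if (direction[g] == 1) {
      l_ctrl[g] <- cfg$isoform_major; l_trt[g] <- minor
    } else {
      l_ctrl[g] <- minor; l_trt[g] <- cfg$isoform_major
    }
    fold[g] <- l_ctrl[g] / l_trt[g]
  }
  for (g in which(class == "DEG")) {
    fold[g] <- cfg$deg_fold^direction[g]
    affected[[g]] <- seq_len(n_exons[g])
  }

  ## base abundance and per-exon, per-condition abundance
  base <- 2^(cfg$mean_log2_expr + cfg$sd_log2_expr * rnorm(n))
  exons$g_idx <- match(exons$gene_id, gene_id)
  affected_keys <- unlist(lapply(seq_len(n), function(g) {
    if (length(affected[[g]] %||% integer(0)) == 0) return(character(0))
    paste(g, affected[[g]])
  }))
  is_affected <- paste(exons$g_idx, exons$exon_index) %in% affected_keys
  abund_ctrl <- base[exons$g_idx] *
    ifelse(class[exons$g_idx] == "DPG" & is_affected, l_ctrl[exons$g_idx], 1) *
    ifelse(class[exons$g_idx] == "DEG", sqrt(fold[exons$g_idx]), 1)
  abund_trt <- base[exons$g_idx] *
    ifelse(class[exons$g_idx] == "DPG" & is_affected, l_trt[exons$g_idx], 1) *
    ifelse(class[exons$g_idx] == "DEG", 1 / sqrt(fold[exons$g_idx]), 1)

  ## probes: tiled within each exon (optionally introns/gaps)
  tile_starts <- function(from, to) {
    n_p <- pmax(0, (to - from + 1 - cfg$probe_length) %/% cfg$probe_step + 1)
    list(start = sequence(n_p, from = from, by = cfg$probe_step),
         src = rep(seq_along(from), n_p))
  }
  ex_tiles <- tile_starts(exons$start, exons$end)
  probes <- tibble(chrom = "chr1", start = ex_tiles$start,
                   exon_row = ex_tiles$src)
  if (cfg$intergenic_probes && nrow(introns) > 0) {
    gap_tiles <- tile_starts(introns$start, introns$end)
    probes <- bind_rows(probes, tibble(chrom = "chr1", start = gap_tiles$start,
                                       exon_row = NA_integer_))
  }
  probes <- arrange(probes, .data$start)
  np <- nrow(probes)
  probes$probe_id <- sprintf("p%06d", seq_len(np))
  probes$length <- cfg$probe_length
  probes$n_matches <- 1L
  n_nonuniq <- round(cfg$frac_nonunique * np)
  if (n_nonuniq > 0) probes$n_matches[resample(seq_len(np), n_nonuniq)] <- 2L

  ## samples
  blocks <- sprintf("B%d", seq_len(cfg$n_blocks))
  samples <- tibble(
    sample_id = c(paste0("ctrl_", seq_len(cfg$n_blocks)),
                  paste0("trt_", seq_len(cfg$n_blocks))),
    condition = rep(.conditions, each = cfg$n_blocks),
    block = rep(blocks, 2)
  )

  ## intensities
  affinity_z <- rnorm(np)
  block_z <- rnorm(cfg$n_blocks)
  array_z <- rnorm(nrow(samples))
  noise_z <- matrix(rnorm(np * nrow(samples)), nrow = np)

  p_abund_ctrl <- ifelse(is.na(probes$exon_row), 0, abund_ctrl[probes$exon_row])
  p_abund_trt <- ifelse(is.na(probes$exon_row), 0, abund_trt[probes$exon_row])
  affinity <- 2^(cfg$sigma_affinity * affinity_z)
  intens <- matrix(0, nrow = np, ncol = nrow(samples),
                   dimnames = list(probes$probe_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    ab <- if (samples$condition[s] == "control") p_abund_ctrl else p_abund_trt
    b <- match(samples$block[s], blocks)
    intens[, s] <- cfg$background +
      affinity * ab *
      2^(cfg$block_sd * block_z[b] + cfg$array_sd * array_z[s] +
           cfg$sigma_noise * noise_z[, s])
  }
  intensities <- as_tibble(intens)
  intensities$probe_id <- probes$probe_id
  intensities <- intensities[c("probe_id", samples$sample_id)]

  truth <- tibble(
    gene_id = gene_id, class = class, event = event, fold = fold,
    affected_exons = vapply(affected, function(a) paste(a %||% integer(0), collapse = ","),
                            character(1)),
    n_exons = n_exons
  )

  structure(list(
    probes = probes[c("probe_id", "chrom", "start", "length", "n_matches")],
    exons = select(exons, -"g_idx"),
    intensities = intensities,
    samples = samples,
    truth = truth,
    config = cfg
  ), class = "tilecall_sim")
}

#' @export
print.tilecall_sim <- function(x, ...) {
  cat(sprintf(
    "<tilecall_sim> %d genes (%d DPG, %d DEG), %d probes, %d samples, seed %s\n",
    nrow(x$truth), sum(x$truth$class == "DPG"), sum(x$truth$class == "DEG"),
    nrow(x$probes), nrow(x$samples), format(x$config$seed)
  ))
  invisible(x)
}

#' Write a simulated dataset as pipeline input fixtures
#'
#' Emits exactly the external formats the pipeline consumes: `probe_map.tsv`,
#' `annotation.gff3` (gene/mRNA/exon features with Parent links),
#' `intensities.tsv`, `samples.tsv` and the ground truth `truth.tsv`.
#'
#' @param sim A `tilecall_sim` object.
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  if (!inherits(sim, "tilecall_sim")) tc_data_error("sim must come from simulate_dataset()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    probe_map = file.path(dir, "probe_map.tsv"),
    annotation = file.path(dir, "annotation.gff3"),
    intensities = file.path(dir, "intensities.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$probes, paths["probe_map"], progress = FALSE)
  export_gff3(sim$exons, paths["annotation"])
  readr::write_tsv(sim$intensities, paths["intensities"], progress = FALSE)
  readr::write_tsv(sim$samples, paths["samples"], progress = FALSE)
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}

# Writes an exon table as GFF3 with gene -> mRNA -> exon Parent links.
export_gff3 <- function(exons, path) {
  tx <- exons |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  genes <- tx |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")

  feat <- bind_rows(
    tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
           strand = genes$strand, type = "gene", ID = genes$gene_id,
           Parent = NA_character_),
    tibble(chrom = tx$chrom, start = tx$start, end = tx$end,
           strand = tx$strand, type = "mRNA", ID = tx$transcript_id,
           Parent = tx$gene_id),
    tibble(chrom = exons$chrom, start = exons$start, end = exons$end,
           strand = exons$strand, type = "exon",
           ID = paste0(exons$transcript_id, ".exon", exons$exon_index),
           Parent = exons$transcript_id)
  )
  gr <- GenomicRanges::GRanges(
    feat$chrom, IRanges::IRanges(feat$start, feat$end), strand = feat$strand
  )
  gr$type <- feat$type
  gr$ID <- feat$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(feat$Parent, function(p) if (is.na(p)) character(0) else p)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
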