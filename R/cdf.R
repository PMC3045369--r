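# Probe-to-exon assignment ("CDF" construction).
#
# Three trimming rules define which probes quantify which exon of which
# annotated transcript isoform:
#   1. only perfect-match probes with a unique genomic match are kept;
#   2. probes spanning an exon border are not assigned (full containment);
#   3. exons left with fewer than `min_probes_per_exon` probes are dropped,
#      and transcripts left with no exon are dropped with them.

#' Keep unique perfect-match probes
#'
#' Retains probes with exactly one perfect genomic match (`n_matches == 1`).
#' If an `is_pm` column is present, mismatch probes are removed as well;
#' probe maps without that column are assumed to be pre-filtered to
#' perfect-match probes.
#'
#' @param probes A probe tibble (see [read_probe_map()]).
#' @return The filtered tibble, input order preserved.
#' @export
#' @examples
#' probes <- tibble::tibble(
#'   probe_id = paste0("p", 1:4), chrom = "chr1",
#'   start = c(1, 36, 71, 106), length = 25, n_matches = c(1, 2, 1, 3)
#' )
#' filter_unique_pm(probes)
filter_unique_pm <- function(probes) {
  validate_probes(probes)
  keep <- probes$n_matches == 1
  if ("is_pm" %in% names(probes)) keep <- keep & probes$is_pm
  probes[keep, , drop = FALSE]
}

#' Assign probes to exons by full containment
#'
#' Probe `p` is assigned to an exon iff the probe interval
#' `[start, start + length - 1]` lies entirely inside the exon interval on the
#' same chromosome. Border-spanning probes (partial overlap) get no
#' assignment: their targets only partially match the probe, so their signal
#' underestimates the exon's abundance. Assignment ignores strand; each
#' (probe, transcript) pair appears at most once.
#'
#' @param probes A probe tibble, already unique-filtered.
#' @param exons An exon table from [read_annotation()].
#' @return A tibble `probe_id`, `gene_id`, `transcript_id`, `exon_index`,
#'   ordered by transcript, exon and probe start.
#' @export
assign_probes <- function(probes, exons) {
  validate_probes(probes)
  check_columns(exons, c("gene_id", "transcript_id", "exon_index", "chrom",
                         "start", "end"), "exon table")
  orphan <- setdiff(unique(probes$chrom), unique(exons$chrom))
  if (length(orphan) > 0) {
    warn(sprintf(
      "probe chromosome(s) absent from annotation (probes left unassigned): %s",
      paste(orphan, collapse = ", ")
    ))
  }
  p_gr <- GenomicRanges::GRanges(
    probes$chrom,
    IRanges::IRanges(probes$start, probes$start + probes$length - 1L)
  )
  e_gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(p_gr, e_gr, type = "within")
  )
  out <- tibble(
    probe_id = probes$probe_id[S4Vectors::queryHits(hits)],
    gene_id = exons$gene_id[S4Vectors::subjectHits(hits)],
    transcript_id = exons$transcript_id[S4Vectors::subjectHits(hits)],
    exon_index = exons$exon_index[S4Vectors::subjectHits(hits)],
    probe_start = probes$start[S4Vectors::queryHits(hits)]
  )
  out |>
    distinct(.data$probe_id, .data$transcript_id, .keep_all = TRUE) |>
    arrange(.data$transcript_id, .data$exon_index, .data$probe_start) |>
    select(-"probe_start")
}

#' Build the probe-to-exon map
#'
#' Applies the single-probe rule to raw assignments: exons represented by
#' fewer than `min_probes_per_exon` probes are dropped (with only one probe,
#' only one ratio per block is available and the downstream t/F statistics
#' have too small a sample), and transcripts left without exons are dropped.
#'
#' @param assignments Output of [assign_probes()].
#' @param min_probes_per_exon Minimum probes for an exon to be retained
#'   (default 2).
#' @return A `tilecall_cdf` tibble `gene_id`, `transcript_id`, `exon_index`,
#'   `probe_id` with a `provenance` attribute counting removals.
#' @export
build_cdf <- function(assignments, min_probes_per_exon = 2) {
  check_columns(assignments, c("gene_id", "transcript_id", "exon_index",
                               "probe_id"), "assignment table")
  cdf <- assignments |>
    group_by(.data$transcript_id, .data$exon_index) |>
    filter(n() >= min_probes_per_exon) |>
    ungroup()
  provenance <- list(
    n_assignments_in = nrow(assignments),
    n_assignments_dropped_sparse_exon = nrow(assignments) - nrow(cdf),
    n_exons_in = nrow(distinct(assignments, .data$transcript_id, .data$exon_index)),
    n_exons_kept = nrow(distinct(cdf, .data$transcript_id, .data$exon_index)),
    n_transcripts_in = length(unique(assignments$transcript_id)),
    n_transcripts_kept = length(unique(cdf$transcript_id)),
    min_probes_per_exon = min_probes_per_exon
  )
  new_cdf(cdf, provenance)
}

new_cdf <- function(cdf, provenance = list()) {
  cdf <- as_tibble(cdf)
  attr(cdf, "provenance") <- provenance
  class(cdf) <- c("tilecall_cdf", class(cdf))
  cdf
}

#' Construct the full probe-to-exon map from probes and annotation
#'
#' Runs the three trimming rules in sequence ([filter_unique_pm()],
#' [assign_probes()], [build_cdf()]) and records a conservation account of
#' every input probe: kept, removed as non-unique (or mismatch), unassigned
#' (border-spanning or outside annotation), or lost when sparse exons were
#' dropped.
#'
#' @inheritParams assign_probes
#' @inheritParams build_cdf
#' @return A `tilecall_cdf` tibble; `cdf_provenance()` retrieves the counters.
#' @export
make_cdf <- function(probes, exons, min_probes_per_exon = 2) {
  unique_pm <- filter_unique_pm(probes)
  assignments <- assign_probes(unique_pm, exons)
  cdf <- build_cdf(assignments, min_probes_per_exon)

  assigned_ids <- unique(assignments$probe_id)
  kept_ids <- unique(cdf$probe_id)
  provenance <- c(attr(cdf, "provenance"), list(
    n_probes_in = nrow(probes),
    n_probes_nonunique = nrow(probes) - nrow(unique_pm),
    n_probes_unassigned = nrow(unique_pm) - length(assigned_ids),
    n_probes_lost_sparse_exon = length(assigned_ids) - length(kept_ids),
    n_probes_kept = length(kept_ids)
  ))
  new_cdf(cdf, provenance)
}

#' Retrieve provenance counters from a probe-to-exon map
#'
#' @param cdf A `tilecall_cdf` object.
#' @return A named list of counts recorded while the map was built.
#' @export
cdf_provenance <- function(cdf) {
  attr(cdf, "provenance") %||% list()
}

#' @export
print.tilecall_cdf <- function(x, ...) {
  pv <- cdf_provenance(x)
  cat(sprintf(
    "<tilecall_cdf> %d assignments: %d transcripts, %d exons, %d probes\n",
    nrow(x), length(unique(x$transcript_id)),
    nrow(distinct(x, .data$transcript_id, .data$exon_index)),
    length(unique(x$probe_id))
  ))
  if (!is.null(pv$n_probes_in)) {
    cat(sprintf(
      "probes in %d | non-unique %d | unassigned %d | lost to sparse exons %d | kept %d\n",
      pv$n_probes_in, pv$n_probes_nonunique, pv$n_probes_unassigned,
      pv$n_probes_lost_sparse_exon, pv$n_probes_kept
    ))
  }
  NextMethod()
}

#' Write / read a probe-to-exon map as TSV
#'
#' @param cdf A `tilecall_cdf` tibble.
#' @param path Output (input) TSV path.
#' @return `read_cdf()` returns a `tilecall_cdf` tibble (without provenance,
#'   which is not serialized).
#' @export
write_cdf <- function(cdf, path) {
  readr::write_tsv(
    as_tibble(cdf)[c("transcript_id", "exon_index", "probe_id", "gene_id")],
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_cdf
#' @export
read_cdf <- function(path) {
  x <- read_tc_tsv(path, "cdf")
  check_columns(x, c("transcript_id", "exon_index", "probe_id"), "cdf table")
  if (!"gene_id" %in% names(x)) x$gene_id <- x$transcript_id
  new_cdf(x[c("gene_id", "transcript_id", "exon_index", "probe_id")])
}
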