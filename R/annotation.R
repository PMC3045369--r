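# Genome annotation: GFF3 in, tidy exon table out.

#' Read a GFF3 annotation into an exon table
#'
#' Parses `gene`, `mRNA` and `exon` features (linked through `Parent`
#' attributes) and returns one row per (transcript, exon). Exons are indexed
#' 1..E in transcription order, i.e. 5' to 3' along the transcript: ascending
#' genomic start on the plus strand, descending on the minus strand. An exon
#' shared by several isoforms yields one row per isoform.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `exon_index`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) tc_format_error(sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)

  mrna <- gr[type == "mRNA"]
  if (length(mrna) == 0) tc_format_error("annotation contains no mRNA features")
  mrna_parent <- vapply(as.list(mrna$Parent), function(p) p[1] %||% NA_character_,
                        character(1))
  tx2gene <- setNames(mrna_parent, mrna$ID)

  ex <- gr[type == "exon"]
  if (length(ex) == 0) tc_format_error("annotation contains no exon features")
  parents <- ex$Parent
  n_par <- S4Vectors::elementNROWS(parents)
  if (any(n_par == 0)) tc_format_error("exon feature without a Parent attribute")
  idx <- rep(seq_along(ex), n_par)

  exons <- tibble(
    transcript_id = unlist(as.list(parents), use.names = FALSE),
    chrom = as.character(GenomicRanges::seqnames(ex))[idx],
    start = GenomicRanges::start(ex)[idx],
    end = GenomicRanges::end(ex)[idx],
    strand = as.character(GenomicRanges::strand(ex))[idx]
  )
  unknown <- setdiff(exons$transcript_id, names(tx2gene))
  if (length(unknown) > 0) {
    tc_format_error(sprintf(
      "exon Parent(s) with no mRNA feature: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  exons$gene_id <- unname(tx2gene[exons$transcript_id])
  index_exons(exons)
}

# Assigns exon_index in 5'->3' transcription order and validates invariants.
index_exons <- function(exons) {
  exons <- exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      exon_index = if (.data$strand[1] == "-") rev(seq_len(n())) else seq_len(n())
    ) |>
    ungroup()
  bad <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      overlapping = n() > 1 && any(.data$start[-1] <= head(.data$end, -1)),
      inverted = any(.data$end < .data$start),
      .groups = "drop"
    ) |>
    filter(.data$overlapping | .data$inverted)
  if (nrow(bad) > 0) {
    tc_format_error(sprintf(
      "invalid exon coordinates (overlap or end < start) in transcript(s): %s",
      paste(head(bad$transcript_id, 5), collapse = ", ")
    ))
  }
  exons |>
    select("gene_id", "transcript_id", "exon_index", "chrom", "start", "end",
           "strand") |>
    arrange(.data$transcript_id, .data$exon_index)
}
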