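# Shared fixture builders. Everything is generated in code; no binary data.

# A small, fast default simulation used across test files.
small_sim <- function(seed = 101, n_genes = 40, ...) {
  simulate_dataset(sim_config(seed = seed, n_genes = n_genes, ...))
}

# A hand-built toy annotation: one gene, three exons on the plus strand.
toy_exons <- function() {
  tibble::tibble(
    gene_id = "gA", transcript_id = "gA.1",
    exon_index = 1:3, chrom = "chr1",
    start = c(1, 281, 511), end = c(200, 430, 810), strand = "+"
  )
}

# Probes tiled every `step` bp across [1, limit].
toy_probes <- function(limit = 900, step = 35, len = 25) {
  starts <- seq(1, limit - len + 1, by = step)
  tibble::tibble(
    probe_id = sprintf("t%03d", seq_along(starts)), chrom = "chr1",
    start = starts, length = len, n_matches = 1L
  )
}

# Brute-force O(P x E) containment oracle for probe assignment.
brute_force_assign <- function(probes, exons) {
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    p_start <- probes$start[i]
    p_end <- p_start + probes$length[i] - 1
    for (j in seq_len(nrow(exons))) {
      if (probes$chrom[i] == exons$chrom[j] &&
          p_start >= exons$start[j] && p_end <= exons$end[j]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          probe_id = probes$probe_id[i],
          gene_id = exons$gene_id[j],
          transcript_id = exons$transcript_id[j],
          exon_index = exons$exon_index[j]
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dplyr::distinct(out, probe_id, transcript_id, .keep_all = TRUE)
}

# Ratio table with given matrix of log2 ratios (for direct cascade tests).
ratio_table <- function(m, probe_ids = sprintf("p%03d", seq_len(nrow(m)))) {
  colnames(m) <- paste0("B", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  out$probe_id <- probe_ids
  out[c("probe_id", colnames(m))]
}

# Minimal cdf tibble from explicit assignments.
cdf_table <- function(transcript_id, exon_index, probe_id,
                      gene_id = sub("\\.[0-9]+$", "", transcript_id)) {
  tilecall:::new_cdf(tibble::tibble(
    gene_id = gene_id, transcript_id = transcript_id,
    exon_index = exon_index, probe_id = probe_id
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Strips classes/attributes for structural comparison of tables.
plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  rownames(x) <- NULL
  x
}
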