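# The synthetic-experiment generator and its contracts.

test_that("the generator is deterministic for a fixed seed", {
  a <- small_sim(seed = 900)
  b <- small_sim(seed = 900)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth, b$truth)
  expect_identical(a$exons, b$exons)
  c <- small_sim(seed = 901)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("a noise-free effect-free run has identical conditions and zero ratios", {
  sim <- small_sim(seed = 902, sigma_affinity = 0, sigma_noise = 0,
                   block_sd = 0, array_sd = 0, frac_dpg = 0, frac_deg = 0)
  m <- as.matrix(sim$intensities[-1])
  ctrl <- m[, sim$samples$sample_id[sim$samples$condition == "control"]]
  trt <- m[, sim$samples$sample_id[sim$samples$condition == "treatment"]]
  expect_equal(unname(ctrl), unname(trt))
  r <- compute_ratios(sim$intensities, sim$samples)
  expect_true(all(as.matrix(r[-1]) == 0))
})

test_that("affinities cancel exactly: noise-free ratios do not depend on sigma_affinity", {
  r_for <- function(sa) {
    sim <- small_sim(seed = 903, sigma_affinity = sa, sigma_noise = 0,
                     frac_dpg = 0.2)
    as.matrix(compute_ratios(sim$intensities, sim$samples)[-1])
  }
  r1 <- r_for(0.5); r2 <- r_for(1); r3 <- r_for(2)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r2, r3, tolerance = 1e-12)
})

test_that("a noise-free APA gene shows the closed-form last-exon ratio", {
  sim <- simulate_dataset(sim_config(
    seed = 904, n_genes = 30, frac_dpg = 0.3, frac_deg = 0,
    event_mix = c(APA = 1, ALT_INIT = 0, ALT_SPLICE = 0),
    sigma_affinity = 0.8, sigma_noise = 0, block_sd = 0, array_sd = 0,
    isoform_major = 0.8
  ))
  ratios <- compute_ratios(sim$intensities, sim$samples)
  cdf <- make_cdf(sim$probes, sim$exons)
  long <- dplyr::inner_join(tibble::as_tibble(cdf),
                            tidyr::pivot_longer(ratios, -probe_id,
                                                names_to = "block",
                                                values_to = "lr"),
                            by = "probe_id")
  truth <- sim$truth
  for (g in which(truth$class == "DPG")) {
    affected <- as.integer(strsplit(truth$affected_exons[g], ",")[[1]])
    gl <- long[long$gene_id == truth$gene_id[g], ]
    on <- gl$exon_index %in% affected
    expect_equal(unique(round(gl$lr[on], 10)), round(log2(truth$fold[g]), 10))
    expect_true(all(abs(gl$lr[!on]) < 1e-10))
    # APA geometry: the affected run is a 3'-terminal suffix
    n_ex <- truth$n_exons[g]
    expect_equal(affected, (n_ex - length(affected) + 1):n_ex)
    expect_equal(abs(log2(truth$fold[g])), log2(0.8 / 0.2), tolerance = 1e-12)
  }
})

test_that("DEG genes scale every exon by the recorded fold", {
  sim <- simulate_dataset(sim_config(
    seed = 905, n_genes = 30, frac_dpg = 0, frac_deg = 0.3,
    sigma_affinity = 0.5, sigma_noise = 0, block_sd = 0, array_sd = 0
  ))
  ratios <- compute_ratios(sim$intensities, sim$samples)
  cdf <- make_cdf(sim$probes, sim$exons)
  long <- dplyr::inner_join(tibble::as_tibble(cdf),
                            tidyr::pivot_longer(ratios, -probe_id,
                                                names_to = "block",
                                                values_to = "lr"),
                            by = "probe_id")
  truth <- sim$truth
  for (g in which(truth$class == "DEG")) {
    gl <- long[long$gene_id == truth$gene_id[g], ]
    expect_equal(unique(round(gl$lr, 10)),
                 round(log2(truth$fold[g]), 10))
  }
})

test_that("config invariants are enforced before generation", {
  expect_error(sim_config(), class = "tilecall_data_error")
  expect_error(sim_config(seed = 1, frac_dpg = 0.7, frac_deg = 0.6),
               class = "tilecall_data_error")
  expect_error(sim_config(seed = 1, sigma_noise = -1),
               class = "tilecall_data_error")
  expect_error(sim_config(seed = 1, event_mix = c(APA = 1, ALT_INIT = 1, ALT_SPLICE = 0)),
               class = "tilecall_data_error")
})

test_that("fixtures round-trip through the pipeline's readers", {
  sim <- small_sim(seed = 906, frac_nonunique = 0.1)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim, dir)
  expect_true(all(file.exists(paths)))

  probes <- read_probe_map(paths["probe_map"])
  expect_equal(plain(probes), plain(sim$probes), tolerance = 1e-12)
  intens <- read_intensities(paths["intensities"])
  expect_equal(plain(intens), plain(sim$intensities), tolerance = 1e-12)
  samples <- read_sample_sheet(paths["samples"])
  expect_equal(plain(samples), plain(sim$samples))
  truth <- read_truth(paths["truth"])
  expect_equal(truth$gene_id, sim$truth$gene_id)

  exons <- read_annotation(paths["annotation"])
  expect_equal(
    plain(dplyr::arrange(exons, transcript_id, exon_index)),
    plain(dplyr::arrange(sim$exons, transcript_id, exon_index)),
    tolerance = 1e-12
  )
  # GFF3 coordinates are valid and parents resolve
  expect_true(all(exons$start <= exons$end))
  # probe count equals the sum of per-exon tilings
  tiled <- sum(pmax(0, (sim$exons$end - sim$exons$start + 1 - 25) %/% 35 + 1))
  expect_equal(nrow(probes), tiled)
})
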