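# Ratio generation and its diagnostics.

make_paired <- function(m_ctrl, m_trt, blocks = paste0("B", seq_len(ncol(m_ctrl)))) {
  m <- cbind(m_ctrl, m_trt)
  colnames(m) <- c(paste0("c", seq_len(ncol(m_ctrl))), paste0("t", seq_len(ncol(m_trt))))
  x <- tibble::as_tibble(m)
  x$probe_id <- sprintf("p%03d", seq_len(nrow(x)))
  samples <- tibble::tibble(
    sample_id = c(paste0("c", seq_len(ncol(m_ctrl))), paste0("t", seq_len(ncol(m_trt)))),
    condition = rep(c("control", "treatment"), c(ncol(m_ctrl), ncol(m_trt))),
    block = rep(blocks, 2)
  )
  list(x = x[c("probe_id", samples$sample_id)], samples = samples)
}

test_that("block-paired ratios follow the closed forms", {
  m <- matrix(rlnorm(30, 5), 10, 3)
  d <- make_paired(m, m)
  r <- compute_ratios(d$x, d$samples)
  expect_true(all(as.matrix(r[-1]) == 0))

  d2 <- make_paired(2 * m, m)
  r2 <- compute_ratios(d2$x, d2$samples)
  expect_equal(as.vector(as.matrix(r2[-1])), rep(1, 30))
})

test_that("ratios equal an independent elementwise evaluation on random data", {
  set.seed(500)
  mc <- matrix(rlnorm(150, 6, 1), 50, 3)
  mt <- matrix(rlnorm(150, 6, 1), 50, 3)
  d <- make_paired(mc, mt)
  r <- compute_ratios(d$x, d$samples)
  expect_equal(unname(as.matrix(r[-1])), log2(mc / mt), tolerance = 1e-14)
  # orientation flip negates everything exactly
  rflip <- compute_ratios(d$x, d$samples, orientation = "treatment/control")
  expect_equal(as.matrix(rflip[-1]), -as.matrix(r[-1]))
})

test_that("ratio computation is elementwise: commutes with row permutation", {
  set.seed(501)
  d <- make_paired(matrix(rlnorm(60), 20, 3), matrix(rlnorm(60), 20, 3))
  perm <- sample(20)
  a <- compute_ratios(d$x[perm, ], d$samples)
  b <- compute_ratios(d$x, d$samples)[perm, ]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("zero intensities and unbalanced blocks are rejected", {
  d <- make_paired(matrix(1, 3, 3), matrix(1, 3, 3))
  d$x$c1[2] <- 0
  expect_error(compute_ratios(d$x, d$samples), class = "tilecall_data_error")

  d2 <- make_paired(matrix(1, 3, 3), matrix(1, 3, 3))
  d2$samples$block[4] <- "B9"
  expect_error(compute_ratios(d2$x, d2$samples), class = "tilecall_data_error")
})

test_that("random-independent pairing draws a seeded perfect matching", {
  set.seed(502)
  d <- make_paired(matrix(rlnorm(90), 30, 3), matrix(rlnorm(90), 30, 3))
  expect_error(compute_ratios(d$x, d$samples, pairing = "random-independent"),
               class = "tilecall_data_error")
  r1 <- compute_ratios(d$x, d$samples, pairing = "random-independent", seed = 9)
  r2 <- compute_ratios(d$x, d$samples, pairing = "random-independent", seed = 9)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  pairing <- attr(r1, "pairing")
  expect_setequal(pairing$treatment_sample, c("t1", "t2", "t3"))
  expect_setequal(pairing$control_sample, c("c1", "c2", "c3"))
  # each matched pair yields exactly one ratio column
  expect_equal(ncol(r1) - 1, 3)
})

test_that("exon correlation matches textbook Pearson and hits the exact limits", {
  # perfect linear: treatment profile = 2 x control
  ctrl <- matrix(c(100, 200, 400, 800), 4, 3)
  d <- make_paired(ctrl, 2 * ctrl)
  cdf <- cdf_table(rep("gA.1", 4), rep(1L, 4), d$x$probe_id)
  r <- exon_correlation(d$x, d$samples, cdf)
  expect_equal(r$r, 1)

  # anti-linear on the log scale: treatment = c - control (log2 profiles)
  ctrl2 <- matrix(2^c(1, 2, 3, 5), 4, 3)
  trt2 <- matrix(2^(6 - c(1, 2, 3, 5)), 4, 3)
  d2 <- make_paired(ctrl2, trt2)
  r2 <- exon_correlation(d2$x, d2$samples, cdf_table(rep("gA.1", 4), rep(1L, 4), d2$x$probe_id))
  expect_equal(r2$r, -1)

  # random exon: equals direct cor() of mean log2 profiles
  set.seed(503)
  mc <- matrix(rlnorm(15, 6), 5, 3)
  mt <- matrix(rlnorm(15, 6), 5, 3)
  d3 <- make_paired(mc, mt)
  r3 <- exon_correlation(d3$x, d3$samples,
                         cdf_table(rep("gA.1", 5), rep(1L, 5), d3$x$probe_id))
  expect_equal(r3$r, cor(rowMeans(log2(mc)), rowMeans(log2(mt))), tolerance = 1e-12)

  # fewer probes than min_probes: exon not reported
  r4 <- exon_correlation(d3$x, d3$samples,
                         cdf_table(rep("gA.1", 5), rep(1L, 5), d3$x$probe_id),
                         min_probes = 6)
  expect_equal(nrow(r4), 0)
})

test_that("exon SD table matches direct formulas on a hand-computed exon", {
  set.seed(504)
  mc <- matrix(rlnorm(9, 6), 3, 3)
  mt <- matrix(rlnorm(9, 6), 3, 3)
  d <- make_paired(mc, mt)
  cdf <- cdf_table(rep("gA.1", 3), rep(1L, 3), d$x$probe_id)
  ratios <- compute_ratios(d$x, d$samples)
  out <- exon_sd(d$x, d$samples, ratios, cdf)
  expect_equal(out$sd_intensity_control, sd(rowMeans(log2(mc))), tolerance = 1e-12)
  expect_equal(out$sd_intensity_treatment, sd(rowMeans(log2(mt))), tolerance = 1e-12)
  expect_equal(out$sd_ratio, sd(rowMeans(log2(mc / mt))), tolerance = 1e-12)
})

test_that("shared affinity inflates intensity SD but cancels in ratio SD", {
  sim <- small_sim(seed = 505, sigma_affinity = 1.5, sigma_noise = 0.2)
  norm <- normalize_intensities(sim$intensities)
  cdf <- make_cdf(sim$probes, sim$exons)
  ratios <- compute_ratios(norm, sim$samples)
  out <- exon_sd(norm, sim$samples, ratios, cdf)
  med <- attr(out, "medians")
  expect_lt(med["sd_ratio"], med["sd_intensity_control"])
  expect_lt(med["sd_ratio"], med["sd_intensity_treatment"])

  # affinity-free, noise-only: no reduction to gain
  sim0 <- small_sim(seed = 505, sigma_affinity = 0, sigma_noise = 0.2)
  norm0 <- normalize_intensities(sim0$intensities)
  ratios0 <- compute_ratios(norm0, sim0$samples)
  out0 <- exon_sd(norm0, sim0$samples, ratios0, make_cdf(sim0$probes, sim0$exons))
  med0 <- attr(out0, "medians")
  expect_gt(med0["sd_ratio"] / med0["sd_intensity_control"], 0.8)
})

test_that("KS normality check is calibrated and separates heavy tails", {
  set.seed(506)
  normal <- ratio_table(matrix(rnorm(10000, 0, 0.4), ncol = 2))
  heavy <- ratio_table(matrix(0.4 * rt(10000, df = 2), ncol = 2))
  kn <- ks_normality(normal)
  kh <- ks_normality(heavy)
  expect_gt(kn$p_value, 0.01)
  expect_gt(kh$statistic, kn$statistic)
  # constant input degenerates to missing
  const <- ratio_table(matrix(1, 20, 2))
  expect_message(kc <- ks_normality(const), "undefined")
  expect_true(is.na(kc$p_value))
})
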