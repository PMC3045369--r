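# The test cascade: exon t-tests, transcript ANOVA, whole-transcript test,
# and the DPG/DEG/NC decision tree. Oracles: stats::t.test and
# stats::oneway.test on the same values.

test_that("one-sample t matches stats::t.test over many seeded samples", {
  set.seed(600)
  for (i in 1:250) {
    x <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.05, 2))
    got <- one_sample_t(x)
    want <- t.test(x, mu = 0)
    expect_equal(got$t_stat, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches stats::oneway.test over many seeded samples", {
  set.seed(601)
  for (i in 1:250) {
    k <- sample(2:6, 1)
    n <- sample(3:12, k, replace = TRUE)
    value <- rnorm(sum(n), mean = rep(runif(k, -1, 1), n))
    group <- rep(paste0("e", seq_len(k)), n)
    got <- oneway_anova(value, group)
    want <- oneway.test(value ~ factor(group), var.equal = TRUE)
    expect_equal(got$f_stat, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate inputs follow the stated conventions", {
  z <- one_sample_t(rep(0, 6))
  expect_equal(z$p_value, 1)
  expect_false(z$degenerate)

  d <- one_sample_t(rep(1, 4))
  expect_equal(d$p_value, 0)
  expect_true(d$degenerate)

  a1 <- oneway_anova(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(a1$p_value, 1)
  expect_true(a1$degenerate)

  a2 <- oneway_anova(rep(c(0, 1), each = 3), rep(c("a", "b"), each = 3))
  expect_equal(a2$p_value, 0)
  expect_true(a2$degenerate)

  expect_warning(
    a3 <- oneway_anova(c(1, 2, 3, 1.5, 2.5, 9), rep(c("a", "b", "c"), c(3, 2, 1))),
    "excluding"
  )
  expect_equal(a3$k, 2)
})

test_that("exon and whole-transcript tests pool probes x ratio columns", {
  set.seed(602)
  m <- matrix(rnorm(12, 0.5, 0.2), 4, 3)
  ratios <- ratio_table(m)
  cdf <- cdf_table(rep("gA.1", 4), c(1L, 1L, 2L, 2L), ratios$probe_id)
  ex <- exon_tests(ratios, cdf)
  expect_equal(ex$n_ratios, c(6, 6))
  e1 <- as.vector(m[1:2, ])
  want <- t.test(e1, mu = 0)
  expect_equal(ex$t_stat[1], unname(want$statistic), tolerance = 1e-10)
  expect_equal(ex$p_value[1], want$p.value, tolerance = 1e-10)

  comp <- transcript_tests(ratios, cdf)
  whole <- t.test(as.vector(m), mu = 0)
  expect_equal(comp$whole_t, unname(whole$statistic), tolerance = 1e-10)
  expect_equal(comp$whole_p, whole$p.value, tolerance = 1e-10)
  aov_want <- oneway.test(as.vector(m) ~ rep(rep(c("e1", "e2"), each = 2), 3),
                          var.equal = TRUE)
  expect_equal(comp$anova_p, aov_want$p.value, tolerance = 1e-10)

  # single-exon transcript: whole test reduces to the exon test, no ANOVA
  cdf1 <- cdf_table(rep("gB.1", 4), rep(1L, 4), ratios$probe_id)
  comp1 <- transcript_tests(ratios, cdf1)
  ex1 <- exon_tests(ratios, cdf1)
  expect_true(is.na(comp1$anova_p))
  expect_equal(comp1$whole_p, ex1$p_value)
})

test_that("the decision tree routes DPG, DEG and NC correctly", {
  comp <- tibble::tibble(
    gene_id = paste0("g", 1:4), transcript_id = paste0("g", 1:4, ".1"),
    n_exons = c(2L, 2L, 2L, 1L), n_ratios = 12L,
    min_exon_p = c(0.5, 1e-6, 1e-6, 1e-7),
    anova_p = c(0.5, 0.001, 0.9, NA),
    whole_p = c(0.9, 0.5, 1e-8, 1e-3),
    whole_mean_log2_ratio = 1
  )
  calls <- classify_transcripts(comp, alpha_t = 1e-4, alpha_f = 0.05,
                                alpha_w = 0.05)
  expect_equal(calls$status, c("NC", "DPG", "DEG", "DEG"))

  # non-significant whole test drops single-exon candidates back to NC
  comp$whole_p[4] <- 0.2
  expect_equal(classify_transcripts(comp)$status[4], "NC")
})

test_that("gene summaries honour the DPG > DEG > NC priority", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    transcript_id = c("g1.1", "g1.2", "g2.1", "g3.1"),
    status = c("DEG", "DPG", "NC", "NC")
  )
  genes <- summarize_genes(calls)
  expect_equal(genes$status[genes$gene_id == "g1"], "DPG")
  expect_equal(genes$status[genes$gene_id == "g2"], "NC")
  expect_equal(nrow(genes), 3)
})

test_that("negating all ratios leaves p-values and statuses unchanged", {
  sim <- small_sim(seed = 603)
  norm <- normalize_intensities(sim$intensities)
  cdf <- make_cdf(sim$probes, sim$exons)
  r <- compute_ratios(norm, sim$samples)
  rneg <- r
  rneg[-1] <- -rneg[-1]
  ex_a <- exon_tests(r, cdf)
  ex_b <- exon_tests(rneg, cdf)
  expect_equal(ex_a$p_value, ex_b$p_value, tolerance = 1e-12)
  calls_a <- call_transcripts(r, cdf)
  calls_b <- call_transcripts(rneg, cdf)
  expect_equal(calls_a$status, calls_b$status)
  expect_equal(calls_a$anova_p, calls_b$anova_p, tolerance = 1e-12)
})

test_that("tightening alpha_t only shrinks the DPG-or-DEG set", {
  sim <- small_sim(seed = 604, frac_dpg = 0.2, frac_deg = 0.2,
                   sigma_noise = 0.6)
  norm <- normalize_intensities(sim$intensities)
  cdf <- make_cdf(sim$probes, sim$exons)
  comp <- transcript_tests(compute_ratios(norm, sim$samples), cdf)
  hits <- function(a) {
    calls <- classify_transcripts(comp, alpha_t = a)
    calls$transcript_id[calls$status != "NC"]
  }
  alphas <- c(0.05, 0.01, 0.001, 1e-4, 1e-5)
  sets <- lapply(alphas, hits)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("calls expose tidy/glance/autoplot interfaces", {
  sim <- small_sim(seed = 605)
  norm <- normalize_intensities(sim$intensities)
  cdf <- make_cdf(sim$probes, sim$exons)
  calls <- call_transcripts(compute_ratios(norm, sim$samples), cdf)
  td <- tidy(calls)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "tilecall_calls"))
  gl <- glance(calls)
  expect_equal(gl$n_transcripts, nrow(calls))
  expect_equal(gl$n_dpg + gl$n_deg + gl$n_nc, nrow(calls))
  expect_s3_class(autoplot(calls), "ggplot")
})
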