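test_that("moment matching hits target means on the discrete support", {
  # binary items reduce to a Bernoulli
  d <- moment_match_item(0.79, NA, 0, 1, kind = "binary")
  expect_equal(d$prob, c(0.21, 0.79))
  expect_equal(d$mean, 0.79)

  # ordinal: achieved mean within 0.01, sd close to target
  d <- moment_match_item(4.19, 1.04, 0, 5)
  expect_lt(abs(d$mean - 4.19), 0.01)
  expect_lt(abs(d$sd - 1.04), 0.05)
  expect_equal(sum(d$prob), 1)

  # Monte-Carlo check of the quantile sampler against the analytic mean
  set.seed(1)
  draws <- bladderphen:::.item_quantile(d, stats::runif(2e4))
  se <- d$sd / sqrt(2e4)
  expect_lt(abs(mean(draws) - d$mean), 3 * se)

  # symmetric target at the scale midpoint with huge sd
  d <- moment_match_item(2.5, 10, 0, 5)
  expect_equal(d$prob, rev(d$prob), tolerance = 1e-6)

  expect_error(moment_match_item(7, 1, 0, 5), "outside")
})

test_that("every calibration-table entry is matched within tolerance", {
  pp <- phenotype_profiles()
  for (g in c("mfp", "bps", "nupp", "control")) {
    for (i in seq_len(nrow(pp))) {
      r <- pp[i, ]
      d <- moment_match_item(r[[paste0(g, "_mean")]], r[[paste0(g, "_sd")]],
                             r$scale_min, r$scale_max, r$kind)
      expect_lt(abs(d$mean - r[[paste0(g, "_mean")]]), 0.01)
    }
  }
})

test_that("cohort generation is a pure function of config and seed", {
  small <- phenotype_group_sizes()
  small$n <- c(8L, 5L, 8L, 6L)
  g1 <- generate_cohort(cohort_config(groups = small, seed = 99))
  g2 <- generate_cohort(cohort_config(groups = small, seed = 99))
  expect_identical(g1, g2)
  g3 <- generate_cohort(cohort_config(groups = small, seed = 100))
  expect_false(identical(g1$responses, g3$responses))
  expect_equal(nrow(g1$responses), sum(small$n))
  expect_true(all(g1$true_labels %in% small$group))
  # every generated value respects its item scale
  b <- battery_items()
  for (id in b$item_id) {
    expect_true(all(g1$responses[[id]] >= b[id, "scale_min"] &
                      g1$responses[[id]] <= b[id, "scale_max"]))
  }
})

test_that("generated item means converge to their calibration targets", {
  groups <- data.frame(group = "MFP", n = 2000L, age_mean = 31.34,
                       age_sd = 19.7, stringsAsFactors = FALSE)
  g <- generate_cohort(cohort_config(groups = groups, seed = 12))
  pp <- phenotype_profiles()
  # spot-check a spread of items at 3 standard errors
  for (id in c("icsi_2", "oabq_4", "fgupi_2c", "fgupi_4", "pfdi_05", "pfdi_14")) {
    target <- pp[id, "mfp_mean"]
    v <- g$responses[[id]]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), max(3 * se, 0.02))
  }
})

test_that("mixed-phenotype generation blends parameter vectors", {
  small <- phenotype_group_sizes()
  small$n <- c(10L, 10L, 10L, 0L)
  pure <- generate_cohort(cohort_config(groups = small, seed = 4,
                                        mixed_fraction = 0))
  expect_true(all(pure$true_labels %in% c("BPS", "NUPP", "MFP")))
  mixed <- generate_cohort(cohort_config(groups = small, seed = 4,
                                         mixed_fraction = 0.5))
  expect_true(any(grepl("\\+", mixed$true_labels)))
  expect_equal(mean(grepl("\\+", mixed$true_labels)), 0.5)
})

test_that("latent severity factor induces positive item correlation", {
  groups <- data.frame(group = "BPS", n = 400L, age_mean = 31.5,
                       age_sd = 7.2, stringsAsFactors = FALSE)
  ind <- generate_cohort(cohort_config(groups = groups, seed = 8))
  dep <- generate_cohort(cohort_config(groups = groups, seed = 8,
                                       correlation = 0.8))
  mean_cor <- function(g) {
    m <- as.matrix(g$responses[, c("icsi_1", "icsi_2", "oabq_2", "pfdi_15")])
    mean(stats::cor(m)[upper.tri(diag(4))])
  }
  expect_gt(mean_cor(dep), mean_cor(ind) + 0.2)
})

test_that("treatment records follow configured response rates", {
  labels <- stats::setNames(rep(c("BPS", "MFP", "NUPP"), times = c(56, 58, 31)),
                            sprintf("S%04d", 1:145))
  rates <- treatment_response_rates()
  rec <- generate_treatment_records(labels, rates, seed = 2)
  expect_true(all(rec$attempted[rec$responded])) # responded implies attempted
  expect_identical(rec, generate_treatment_records(labels, rates, seed = 2))

  r1 <- rates; r1$rate <- 1
  expect_true(all(generate_treatment_records(labels, r1, seed = 3)$responded))
  r0 <- rates; r0$rate <- 0
  expect_false(any(generate_treatment_records(labels, r0, seed = 3)$responded))

  # empirical responder proportion converges to the configured rate
  big <- stats::setNames(rep("BPS", 4000), sprintf("S%04d", 1:4000))
  rb <- data.frame(phenotype = "BPS", therapy = "instillation",
                   responded = NA, attempted = 4000, rate = 0.9)
  rec <- generate_treatment_records(big, rb, seed = 5)
  se <- sqrt(0.9 * 0.1 / 4000)
  expect_lt(abs(mean(rec$responded) - 0.9), 3 * se)

  expect_error(generate_treatment_records(labels[1:56], rates, seed = 1),
               "MFP")
})
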