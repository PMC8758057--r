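test_that("subscale scoring reproduces the per-group mean-profile values", {
  mfp <- bladderphen:::mean_profile("MFP")
  bps <- bladderphen:::mean_profile("BPS")
  nupp <- bladderphen:::mean_profile("NUPP")

  ics <- score_ics_indices(mfp)
  expect_equal(ics$icsi_total, 2.98 + 4.19 + 2.95 + 2.13)
  expect_equal(ics$icpi_total, 3.12 + 3.10 + 2.84 + 3.10)
  expect_equal(ics$ols_total, ics$icsi_total + ics$icpi_total)

  expect_equal(score_oabq_sf(bps), 20.74)

  expect_equal(score_fgupi(nupp)$fgupi_pain, 10.11)
  expect_equal(score_fgupi(mfp)$fgupi_pain, 14.66)
  expect_equal(round(score_fgupi(nupp)$fgupi_bother, 2), 7.78)

  pf <- score_pfdi(mfp)
  expect_equal(round(pf$popdi6, 1), 51.0)
  expect_equal(round(pf$udi6, 1), 63.2)
})

test_that("scoring respects floors, ceilings and additivity identities", {
  lo <- floor_response()
  ics <- score_ics_indices(lo)
  expect_equal(unlist(ics), c(icsi_total = 0, icpi_total = 0, ols_total = 0))
  expect_equal(score_oabq_sf(lo), 6) # OAB-q items floor at 1
  expect_equal(unlist(score_fgupi(lo)),
               c(fgupi_pain = 0, fgupi_urinary = 0, fgupi_bother = 0,
                 fgupi_total = 0))

  hi <- ceiling_response()
  ics <- score_ics_indices(hi)
  expect_equal(unlist(ics), c(icsi_total = 20, icpi_total = 16, ols_total = 36))
  expect_equal(score_oabq_sf(hi), 36)
  pf <- score_pfdi(hi)
  expect_equal(unlist(pf), c(popdi6 = 100, cradi8 = 100, udi6 = 100,
                             pfdi_total = 300))

  # additivity holds on arbitrary valid responses
  set.seed(42)
  for (i in 1:20) {
    r <- random_response()
    ics <- score_ics_indices(r)
    expect_equal(ics$ols_total, ics$icsi_total + ics$icpi_total)
    fg <- score_fgupi(r)
    expect_equal(fg$fgupi_total,
                 fg$fgupi_pain + fg$fgupi_urinary + fg$fgupi_bother)
    pf <- score_pfdi(r)
    expect_equal(pf$pfdi_total, pf$popdi6 + pf$cradi8 + pf$udi6)
  }
})

test_that("scores are monotone in their items and stay in range", {
  set.seed(7)
  b <- battery_items()
  for (i in 1:15) {
    r <- random_response()
    pf <- score_pfdi(r)
    expect_true(pf$popdi6 >= 0 && pf$popdi6 <= 100)
    expect_true(pf$cradi8 >= 0 && pf$cradi8 <= 100)
    expect_true(pf$udi6 >= 0 && pf$udi6 <= 100)
    fg <- score_fgupi(r)
    expect_true(fg$fgupi_total >= 0 && fg$fgupi_total <= 8 + 5 + 10 + 10 + 12)
    # bump one random item that is below its ceiling; no score decreases
    id <- sample(b$item_id[unlist(r) < b$scale_max], 1)
    r2 <- r; r2[id] <- r2[id] + 1
    expect_gte(score_ics_indices(r2)$ols_total, score_ics_indices(r)$ols_total)
    expect_gte(score_fgupi(r2)$fgupi_total, fg$fgupi_total)
    expect_gte(score_pfdi(r2)$pfdi_total, pf$pfdi_total)
    expect_gte(score_oabq_sf(r2), score_oabq_sf(r))
  }
})

test_that("scoring errors name missing or out-of-range items", {
  r <- floor_response()
  expect_error(score_ics_indices(r[setdiff(names(r), "icsi_2")]), "icsi_2")
  r_bad <- r; r_bad["icsi_1"] <- 9
  expect_error(score_ics_indices(r_bad), "icsi_1")
  r_bin <- r; r_bin["fgupi_2c"] <- 2
  expect_error(score_fgupi(r_bin), "fgupi_2c")
})

test_that("BPCI gate classifies by the >4 / <3 thresholds", {
  r <- floor_response()
  cfg <- composite_config()
  r["icsi_4"] <- 5
  expect_equal(compute_bpci(r, cfg)$classification, "case")
  r["icsi_4"] <- 2
  expect_equal(compute_bpci(r, cfg)$classification, "control")
  r["icsi_4"] <- 3.5
  expect_equal(compute_bpci(r, cfg)$classification, "indeterminate")
  expect_error(compute_bpci(r, composite_config(bpci_items = character(0))),
               "empty")
  expect_error(composite_config(bpci_case_threshold = 2,
                                bpci_control_threshold = 3))
  expect_error(composite_config(bpci_weights = c(-1, 1, 1, 1)))
})

test_that("UICI separates the incontinence-dominant phenotype", {
  cfg <- composite_config()
  lo <- floor_response()
  expect_equal(compute_uici(lo, cfg), 1 + 1 + 0) # OAB-q items floor at 1
  hi <- ceiling_response()
  expect_equal(compute_uici(hi, cfg), 6 + 6 + 4)
  # incontinence items run higher in the myofascial group's mean profile
  expect_gt(compute_uici(bladderphen:::mean_profile("MFP"), cfg),
            compute_uici(bladderphen:::mean_profile("BPS"), cfg))
})

test_that("phenotype measures are centered, bounded and scale-anchored", {
  cohort <- generate_cohort(cohort_config(seed = 3))$responses
  ps <- population_item_stats(cohort)
  mu <- stats::setNames(ps$mean, ps$item_id)
  m <- compute_phenotype_measures(mu, ps)
  expect_equal(m$bps_measure, 0) # subject exactly at cohort means
  lo <- floor_response(); hi <- ceiling_response()
  expect_equal(compute_phenotype_measures(lo, ps)$mfp_measure, 0)
  expect_equal(compute_phenotype_measures(hi, ps)$mfp_measure, 1)
  nupp_items <- paste0("fgupi_", c("1a", "1b", "1c", "2a", "2b"))
  r <- lo; r[nupp_items] <- 1
  expect_equal(compute_phenotype_measures(r, ps)$nupp_measure, 5)
  ps_bad <- ps; ps_bad["icsi_4", "sd"] <- 0
  expect_error(compute_phenotype_measures(lo, ps_bad), "degenerate")
})

test_that("score_cohort produces one complete profile per subject", {
  cohort <- generate_cohort(cohort_config(seed = 5))$responses
  sc <- score_cohort(cohort)
  expect_equal(nrow(sc), nrow(cohort))
  expect_equal(sc$ols_total, sc$icsi_total + sc$icpi_total)
  expect_equal(sc$pfdi_total, sc$popdi6 + sc$cradi8 + sc$udi6)
  expect_true(all(sc$bpci_class %in% c("case", "control", "indeterminate")))
  expect_error(score_cohort(cohort[, -which(names(cohort) == "pfdi_20")]),
               "pfdi_20")
})
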