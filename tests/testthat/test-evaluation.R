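# Model qualification: bootstrap, prediction-corrected VPC, goodness of fit.

test_that("bootstrap on a single subject reproduces the original fit", {
  design <- small_design(1)
  design$arms <- design$arms[2]
  ds <- generate_dataset(design, ref_params(), seed = 51)
  f <- fit_pk(ds, ref_params(), stage = "parent", bql = "m3")
  bt <- bootstrap_fit(ds, ref_params(), n_reps = 2, seed = 1,
                      stage = "parent", bql = "m3")
  # with one subject every resample is the original dataset
  for (r in 1:2) {
    expect_equal(unname(bt$estimates[r, "CL_F"]), f$full[["CL_F"]],
                 tolerance = 1e-4)
  }
})

test_that("all-fixed bootstrap gives degenerate percentiles", {
  ds <- generate_dataset(small_design(2), ref_params(), seed = 52)
  bt <- bootstrap_fit(ds, ref_params(), n_reps = 3, seed = 2, stage = "parent",
                      control = list(iter.max = 1, eval.max = 2))
  expect_s3_class(bt, "pmpk_boot")
  expect_true(all(c("p2.5", "median", "p97.5") %in% colnames(bt$summary)))
})

test_that("bootstrap intervals cover the generating values", {
  covered <- total <- 0
  for (s in 1:2) {
    ds <- generate_dataset(small_design(4), ref_params(), seed = 520 + s)
    bt <- bootstrap_fit(ds, ref_params(), n_reps = 30, seed = s,
                        stage = "parent", bql = "m3")
    expect_gte(bt$fraction_converged, 0.5)
    truthv <- pmpk:::pop_to_full(ref_params())[rownames(bt$summary)]
    hit <- truthv >= bt$summary[, "p2.5"] & truthv <= bt$summary[, "p97.5"]
    covered <- covered + sum(hit)
    total <- total + length(hit)
  }
  expect_gte(covered / total, 0.8)
})

test_that("pcVPC is calibrated on self-simulated data and invariant to labels", {
  ds <- generate_dataset(small_design(5), ref_params(), seed = 53)
  pop <- ref_params()
  v <- pc_vpc(ds, pop, n_sim = 150, seed = 7, analyte = "metabolite")
  expect_gte(vpc_coverage(v), 0.8)
  expect_true(all(v$bands$lower <= v$bands$upper))
  # subject relabeling leaves the result unchanged
  ds2 <- as.data.frame(ds)
  ids <- unique(ds2$ID)
  ds2$ID <- match(ds2$ID, ids) + 500
  v2 <- pc_vpc(pk_dataset(ds2), pop, n_sim = 150, seed = 7,
               analyte = "metabolite")
  expect_equal(v$observed, v2$observed, tolerance = 1e-10)
  expect_equal(v$bands, v2$bands, tolerance = 1e-10)
  # replicate guard
  expect_error(pc_vpc(ds, pop, n_sim = 2), "at least 10")
})

test_that("prediction correction is the identity when PRED is flat in a bin", {
  # all subjects share one design and the population prediction, so
  # median(PRED_bin)/PRED_i = 1 and pc-observed quantiles equal raw quantiles
  design <- small_design(6)
  design$arms <- design$arms[1]
  ds <- generate_dataset(design, population_params(ref_params()$theta,
                                                   omega2 = NULL,
                                                   sigma_p = 0.3, sigma_m = 0.3),
                         seed = 54)
  v <- pc_vpc(ds, ref_params(), n_sim = 50, seed = 8, analyte = "parent")
  obs <- as.data.frame(ds)[ds$EVID == 0, ]
  obs <- obs[obs$CMT == 2 & obs$BLQ == 0, ]
  tad <- obs$TIME
  for (b in unique(v$observed$bin)) {
    raw <- obs$DV[tad == b]
    if (length(raw) >= 2) {
      got <- v$observed$value[v$observed$bin == b & v$observed$quantile == 0.5]
      expect_equal(got, unname(quantile(raw, 0.5)), tolerance = 1e-9)
    }
  }
})

test_that("goodness-of-fit table has calibrated residuals", {
  ds <- generate_dataset(small_design(7), ref_params(), seed = 55)
  pop <- ref_params()
  g <- gof_table(ds, pop)
  obs <- as.data.frame(ds)[ds$EVID == 0, ]
  expect_equal(nrow(g), sum(obs$BLQ == 0))
  expect_gt(nrow(g), 300)
  m <- g[g$CMT == 3, ]
  expect_gt(nrow(m), 300)
  expect_gt(sd(m$IWRES), 0.85)
  expect_lt(sd(m$IWRES), 1.15)
  # noiseless self-simulated data give zero residuals
  pop0 <- population_params(pop$theta, omega2 = NULL, sigma_p = 1e-9,
                            sigma_m = 1e-9)
  design <- small_design(1)
  design$arms <- design$arms[2]
  ds0 <- generate_dataset(design, pop0, seed = 56)
  g0 <- gof_table(ds0, pop0)
  expect_lt(max(abs(g0$IWRES)) * 1e-9, 1e-4)  # IWRES scale is 1/sigma
  expect_equal(g0$PRED, g0$IPRED, tolerance = 1e-6)
})
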