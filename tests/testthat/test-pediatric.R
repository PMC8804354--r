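# Pediatric extrapolation: virtual population, BSA dosing rules, exposure
# metrics and tier-dose optimization.

test_that("virtual population matches the published cohort summaries", {
  vp <- generate_virtual_population(1000, seed = 61)
  expect_identical(vp, generate_virtual_population(1000, seed = 61))
  expect_true(all(vp$age >= 6 & vp$age < 18))
  # calibration targets (published medians): age ~12, weight ~42 kg,
  # BMI ~18.4, BSA ~1.3 m2; tolerance 15%
  expect_equal(median(vp$age), 12, tolerance = 0.15)
  expect_equal(median(vp$weight), 42.3, tolerance = 0.15)
  expect_equal(median(vp$bmi), 18.4, tolerance = 0.15)
  expect_equal(median(vp$bsa), 1.3, tolerance = 0.15)
  expect_equal(vp$bmi, vp$weight / (vp$height / 100)^2, tolerance = 1e-12)
  big <- generate_virtual_population(1e4, seed = 62)
  expect_equal(mean(big$sex), 0.541, tolerance = 0.02)
})

test_that("body surface area formulas behave as expected", {
  expect_equal(body_surface_area(170, 60), sqrt(170 * 60 / 3600))
  expect_equal(body_surface_area(170, 60), 1.683, tolerance = 1e-3)
  # sqrt homogeneity: x2 on both inputs doubles BSA
  expect_equal(body_surface_area(2 * 170, 2 * 60),
               2 * body_surface_area(170, 60))
  expect_gt(body_surface_area(30, 1.2), 0)
  expect_equal(body_surface_area(170, 60, "dubois"),
               0.007184 * 170^0.725 * 60^0.425)
  expect_error(body_surface_area(-1, 60), "positive")
})

test_that("initial dose rule and rounding reproduce the worked example", {
  expect_equal(initial_dose(1.0), 305.2)
  expect_equal(initial_dose(1.30), 396.76)
  expect_equal(round_dose(initial_dose(1.30), 50), 400)
  expect_equal(round_dose(244.2, 50), 250)
  expect_equal(round_dose(375, 50), 400)  # exact midpoint rounds up
  expect_equal(initial_dose(c(1, 2)), c(305.2, 610.4))  # linear in BSA
  expect_error(initial_dose(0), "positive")
  expect_error(round_dose(100, 0), "positive")
})

test_that("derived tiers partition the BSA axis at rounding midpoints", {
  tiers <- derive_tiers(c(0.74, 2.2), step = 50)
  # contiguous and exhaustive
  expect_equal(tiers$bsa_low[-1], tiers$bsa_high[-nrow(tiers)],
               tolerance = 1e-12)
  expect_equal(tiers$bsa_low[1], 0.74)
  expect_equal(tiers$bsa_high[nrow(tiers)], 2.2)
  # boundaries sit exactly where the dose line crosses rounding midpoints
  inner <- tiers$bsa_low[-1]
  expect_equal(initial_dose(inner) %% 50, rep(25, length(inner)),
               tolerance = 1e-9)
  # every BSA inside a tier rounds to that tier's dose
  for (k in seq_len(nrow(tiers))) {
    mid <- (tiers$bsa_low[k] + tiers$bsa_high[k]) / 2
    expect_equal(round_dose(initial_dose(mid), 50), tiers$dose[k])
  }
  # a narrow range within one rounding cell gives a single tier
  expect_equal(nrow(derive_tiers(c(1.0, 1.02))), 1)
  # comparable tier count to the published 5-tier regimen
  expect_true(nrow(tiers) >= 5 && nrow(tiers) <= 10)
})

test_that("tier assignment covers the whole BSA axis", {
  tiers <- recommended_tiers()
  expect_equal(assign_tier(c(0.5, 0.8, 0.895, 1.0, 1.3, 1.5, 1.7, 2.5), tiers),
               c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L))
  expect_equal(tiers$dose, c(250, 350, 400, 450, 550))
})

test_that("exposure metrics follow linear-kinetics identities", {
  pop <- ref_params()
  uc <- unit_constants()
  # typical 59-kg subject without IIV: AUC_ss = FM_mass * dose / CL_ss
  typ <- data.frame(id = 1, age = 17, sex = 1, height = 170, weight = 59,
                    bmi = 59 / 1.7^2, bsa = body_surface_area(170, 59))
  m <- simulate_exposure(typ, 300, pop, include_iiv = FALSE)
  expect_equal(m$auc_0_12_ss, 300 * uc$molar_factor / 74.34 * 1000,
               tolerance = 0.01)
  # doubling the dose doubles both metrics exactly
  m2 <- simulate_exposure(typ, 600, pop, include_iiv = FALSE)
  expect_equal(m2$cmax_ss, 2 * m$cmax_ss, tolerance = 1e-8)
  expect_equal(m2$auc_0_12_ss, 2 * m$auc_0_12_ss, tolerance = 1e-8)
  expect_lte(m$auc_0_12_ss, 12 * m$cmax_ss)
  # without IIV, exposure depends on the subject only through weight
  two <- data.frame(id = 1:2, age = c(8, 14), sex = c(0, 1),
                    height = c(120, 160), weight = c(40, 40),
                    bmi = c(27.8, 15.6),
                    bsa = body_surface_area(c(120, 160), c(40, 40)))
  mm <- simulate_exposure(two, 400, pop, include_iiv = FALSE)
  expect_equal(mm$cmax_ss[1], mm$cmax_ss[2], tolerance = 1e-10)
  expect_equal(mm$auc_0_12_ss[1], mm$auc_0_12_ss[2], tolerance = 1e-10)
})

test_that("simulated GM AUC agrees with the analytic mixture oracle", {
  pop <- ref_params()
  uc <- unit_constants()
  vp <- generate_virtual_population(150, seed = 63)
  m <- simulate_exposure(vp, 350, pop, include_iiv = TRUE, seed = 64)
  # GM over subjects of FM_mass * dose / (CL_ss(W) e^eta): the eta term has
  # log-mean zero, so the oracle is the GM over the weight mixture alone
  cl_ss <- 74.34 * (vp$weight / 59)^0.75
  oracle <- exp(mean(log(350 * uc$molar_factor * 1000 / cl_ss)))
  got <- exp(mean(log(m$auc_0_12_ss)))
  # eta sampling noise at n=150 with omega_CLm = 0.341: tolerate 3% + trapezoid
  expect_equal(got, oracle, tolerance = 0.1)
  # dose-normalised AUC is approximately tier-invariant
  tiers <- recommended_tiers()
  doses <- tiers$dose[assign_tier(vp$bsa, tiers)]
  mt <- simulate_exposure(vp, doses, pop, include_iiv = TRUE, seed = 65)
  s <- summarize_by_tier(mt, tiers)
  norm <- s$mean_auc_norm[s$n >= 10]
  expect_lt(max(norm) / min(norm), 1.2 / 0.8)
})

test_that("tier-dose optimization matches the closed-form target", {
  pop <- ref_params()
  uc <- unit_constants()
  ref <- reference_exposure()
  # single typical subject: optimal dose solves FM * dose / CL_ss = 6530
  typ <- data.frame(id = 1, age = 17, sex = 1, height = 170, weight = 59,
                    bmi = 59 / 1.7^2, bsa = 1.67)
  tiers <- data.frame(bsa_low = 0.7, bsa_high = Inf, dose = 300)
  class(tiers) <- c("dose_tiers", "data.frame")
  out <- optimize_tier_doses(typ, tiers, pop, include_iiv = FALSE)
  target <- ref$gm_auc / (uc$molar_factor * 1000 / 74.34)
  expect_equal(out$dose, round_dose(target, 50) , tolerance = 0)
  # monotonicity: doubling the reference weakly increases every dose
  vp <- generate_virtual_population(200, seed = 66)
  tiers5 <- recommended_tiers()
  o1 <- optimize_tier_doses(vp, tiers5, pop, seed = 67)
  ref2 <- ref; ref2$gm_auc <- 2 * ref$gm_auc
  o2 <- optimize_tier_doses(vp, tiers5, pop, reference = ref2, seed = 67)
  expect_true(all(o2$dose[o2$n > 0] >= o1$dose[o1$n > 0]))
})

test_that("tier summaries reduce correctly in degenerate cases", {
  m <- data.frame(id = 1:4, bsa = c(0.8, 0.8, 1.3, 1.3), weight = 30,
                  dose = c(250, 250, 400, 400), cmax_ss = c(5, 5, 7, 7),
                  auc_0_12_ss = c(50, 50, 70, 70),
                  auc_per_dose_per_bsa = 1)
  s <- summarize_by_tier(m, recommended_tiers())
  r1 <- s[s$tier == 1, ]
  expect_equal(r1$gm_cmax, 5)
  expect_equal(r1$mean_cmax, 5)
  expect_equal(r1$median_cmax, 5)
  expect_equal(r1$sd_cmax, 0)
  # GM ~ median for a log-normal sample
  set.seed(5)
  x <- rlnorm(2e4, 1, 0.5)
  expect_equal(exp(mean(log(x))), median(x), tolerance = 0.02)
})

test_that("malformed growth tables are rejected", {
  expect_s3_class(growth_reference(), "data.frame")
  # the loader checks structure, not just existence
  expect_true(all(c("male", "female") %in% growth_reference()$sex))
})
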