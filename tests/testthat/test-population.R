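# Stochastic layer: IIV, covariate effect functions, residual error,
# allometric scaling.

test_that("individual parameters compose typical values, covariates and etas", {
  pop <- ref_params()
  expect_equal(unclass(individual_params(pop)), unclass(pop$theta))
  # power covariate factor, frozen from direct evaluation of the form
  ef <- covariate_effect("CL_F", "WT", "power", theta2 = 0.75, reference = 58.3)
  expect_equal(covariate_factor(ef, 80), (80 / 58.3)^0.75)
  got <- individual_params(pop, cov_effects = list(ef), covariates = list(WT = 80))
  expect_equal(got[["CL_F"]], 2850 * (80 / 58.3)^0.75, tolerance = 1e-12)
  # fractional form
  ef2 <- covariate_effect("V_F", "SEX", "fractional", theta2 = 0.8)
  expect_equal(individual_params(pop, cov_effects = list(ef2),
                                 covariates = list(SEX = 1))[["V_F"]],
               4200 * 0.8)
  expect_equal(individual_params(pop, cov_effects = list(ef2),
                                 covariates = list(SEX = 0))[["V_F"]], 4200)
  # eta acts multiplicatively on the log scale
  got <- individual_params(pop, etas = c(CL_F = 0.3))
  expect_equal(got[["CL_F"]], 2850 * exp(0.3))
  # composition order of covariate factors is immaterial
  efs <- list(ef, covariate_effect("CL_F", "AGE", "power", theta2 = -0.2,
                                   reference = 49.5))
  covs <- list(WT = 70, AGE = 60)
  expect_equal(individual_params(pop, cov_effects = efs, covariates = covs),
               individual_params(pop, cov_effects = rev(efs), covariates = covs))
})

test_that("etas on parameters without IIV are rejected", {
  pop <- ref_params()
  expect_error(individual_params(pop, etas = c(KA = 0.1)), "without IIV")
  pop2 <- population_params(pop$theta, omega2 = c(CL_F = 0.1),
                            sigma_p = 0.7, sigma_m = 0.3)
  expect_error(individual_params(pop2, etas = c(V_F = 0.1)), "without IIV")
  expect_error(population_params(pop$theta, omega2 = c(KA = 0.1),
                                 sigma_p = 0.7, sigma_m = 0.3), "not modelled")
})

test_that("eta sampling is seeded, diagonal and correctly scaled", {
  pop <- ref_params()
  a <- sample_etas(pop, 50, seed = 7)
  b <- sample_etas(pop, 50, seed = 7)
  expect_identical(a, b)
  big <- sample_etas(pop, 1e5, seed = 8)
  expect_equal(apply(big, 2, sd), sqrt(pop$omega2), tolerance = 0.01,
               ignore_attr = TRUE)
  # log-normal median property: median of e^eta -> 1
  expect_equal(median(exp(big[, "CL_F"])), 1, tolerance = 0.01)
  pop0 <- population_params(pop$theta, omega2 = c(CL_F = 0.1),
                            sigma_p = 0.7, sigma_m = 0.3)
  expect_true(all(sample_etas(pop0, 10, seed = 1)[, "V_F"] == 0))
})

test_that("proportional residual error has the configured CV", {
  expect_equal(apply_residual_error(100, 0.3, eps_draw = 0), 100)
  expect_equal(apply_residual_error(0, 0.3, eps_draw = 2), 0)
  set.seed(42)
  y <- apply_residual_error(rep(100, 1e5), 0.319)
  expect_equal(sd(y) / mean(y), 0.319, tolerance = 0.01)
  # additive form preserves the absolute SD instead
  set.seed(43)
  ya <- apply_residual_error(rep(100, 1e5), 5, form = "additive")
  expect_equal(sd(ya), 5, tolerance = 0.05)
})

test_that("allometric scaling uses exponents 0.75 (CL) and 1 (V)", {
  p <- ref_params()$theta
  expect_equal(allometric_scale(p, 59), p)
  sc <- allometric_scale(p, 42.3, 59)
  expect_equal(sc[["CLM0_FM"]], 126 * (42.3 / 59)^0.75, tolerance = 1e-12)
  expect_equal(sc[["CL_F"]], 2850 * (42.3 / 59)^0.75, tolerance = 1e-12)
  expect_equal(sc[["V_F"]], 4200 * 42.3 / 59, tolerance = 1e-12)
  expect_equal(sc[["KA"]], 51.9)
  expect_equal(sc[["TDPK"]], 0.41)
  # half the weight, half the volume
  expect_equal(allometric_scale(p, 29.5, 59)[["VCM_FM"]], 2300 / 2)
  # invertibility
  back <- allometric_scale(allometric_scale(p, 42.3, 59), 59, 42.3)
  expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
  expect_error(allometric_scale(p, -1), "positive")
})
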