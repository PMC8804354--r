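# Approximate-likelihood machinery: conditional -2LL, censored-likelihood
# handling, the FOCE-type objective against an adaptive quadrature oracle,
# and basic fitting behaviour.

toy_subject <- function(tobs, yobs, dose = 200, bql = 0, lloq = 0.491) {
  n <- length(tobs)
  bql <- rep_len(bql, n)
  yobs <- rep_len(yobs, n)
  pk_dataset(data.frame(
    ID = 1,
    TIME = c(0, tobs), AMT = c(dose, rep(NA, n)),
    EVID = c(1, rep(0, n)), CMT = c(1, rep(2, n)),
    DV = c(NA, ifelse(bql == 1, NA, yobs)), MDV = c(1, bql),
    BLQ = c(0, bql), LLOQ = c(NA, rep(lloq, n))))
}

test_that("conditional -2LL reduces to its closed forms in degenerate cases", {
  th <- ref_params()$theta
  # exact-fit data at eta = 0: only normalisation constants remain
  tobs <- c(1, 2)
  f <- as.numeric(parent_concentration(th, tobs, dose = 200))
  pop <- population_params(th, omega2 = c(CL_F = 0.09), sigma_p = 0.3,
                           sigma_m = 0.3)
  got <- conditional_neg2ll(toy_subject(tobs, f), pop, etas = c(CL_F = 0))
  want <- sum(log(2 * pi) + 2 * log(0.3 * f)) + log(2 * pi * 0.09)
  expect_equal(got, want, tolerance = 1e-8)
  # a censored record predicted exactly at the LLOQ contributes -2 log(0.5)
  pop0 <- population_params(th, omega2 = NULL, sigma_p = 0.3, sigma_m = 0.3)
  g_m3 <- conditional_neg2ll(toy_subject(1, 0, bql = 1, lloq = f[1]), pop0,
                             bql = "m3")
  expect_equal(g_m3, -2 * log(0.5), tolerance = 1e-10)
  # M1 discards the censored record entirely
  g_m1 <- conditional_neg2ll(toy_subject(1, 0, bql = 1, lloq = f[1]), pop0,
                             bql = "m1")
  expect_equal(g_m1, 0)
})

test_that("M1 and M3 objectives coincide when nothing is censored", {
  ds <- generate_dataset(small_design(2), ref_params(), seed = 31)
  keep <- ds$EVID == 1 | ds$BLQ == 0
  ds0 <- pk_dataset(as.data.frame(ds)[keep, ])
  pop <- ref_params()
  expect_equal(foce_ofv(ds0, pop, "m1"), foce_ofv(ds0, pop, "m3"),
               tolerance = 1e-8)
})

test_that("FOCE objective matches the adaptive Gauss-Hermite oracle", {
  th <- ref_params()$theta
  cases <- expand.grid(omega = c(0.1, 0.3, 0.5), sigma = c(0.1, 0.3, 0.5),
                       one_obs = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    tobs <- if (cs$one_obs) 2 else c(2, 6)
    yobs <- if (cs$one_obs) 18 else c(18, 2.4)
    pop <- population_params(th, omega2 = c(CL_F = cs$omega^2),
                             sigma_p = cs$sigma, sigma_m = cs$sigma)
    got <- foce_ofv(toy_subject(tobs, yobs), pop, "m1")
    f_eta <- function(eta) {
      oracle_bateman(200, tobs, 2850 * exp(eta), 4200, 51.9)
    }
    want <- oracle_neg2ll_aghq(yobs, f_eta, cs$sigma, cs$omega)
    expect_lt(abs(got - want), 0.5)
  }
})

test_that("with all IIV at zero the objective is extended least squares", {
  th <- ref_params()$theta
  tobs <- c(0.5, 2, 4)
  yobs <- c(20, 30, 10)
  pop0 <- population_params(th, omega2 = NULL, sigma_p = 0.4, sigma_m = 0.4)
  got <- foce_ofv(toy_subject(tobs, yobs), pop0, "m1")
  f <- as.numeric(parent_concentration(th, tobs, dose = 200))
  want <- sum(log(2 * pi) + 2 * log(0.4 * f) + ((yobs - f) / (0.4 * f))^2)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("subject independence: duplicating every subject doubles the OFV", {
  ds <- generate_dataset(small_design(2), ref_params(), seed = 32)
  d2 <- as.data.frame(ds)
  d2$ID <- d2$ID + 1000
  both <- pk_dataset(rbind(as.data.frame(ds), d2))
  pop <- ref_params()
  expect_equal(foce_ofv(both, pop, "m1"), 2 * foce_ofv(ds, pop, "m1"),
               tolerance = 1e-6)
})

test_that("a fit with every parameter fixed returns the initial state", {
  ds <- generate_dataset(small_design(2), ref_params(), seed = 33)
  pop <- ref_params()
  f <- fit_pk(ds, pop, stage = "parent", free = character(0))
  expect_equal(unclass(f$estimates$theta), unclass(pop$theta))
  expect_equal(f$ofv, foce_ofv(pmpk:::filter_analyte(ds, "parent"), pop, "m1"),
               tolerance = 1e-5)
  expect_true(f$convergence)
})

test_that("noiseless data identify a single free parameter to 0.1%", {
  pop0 <- population_params(ref_params()$theta, omega2 = NULL,
                            sigma_p = 1e-6, sigma_m = 1e-6)
  ds <- generate_dataset(small_design(2), pop0, seed = 34)
  init <- population_params(
    structural_params(cl_f = 2850 * 1.4, v_f = 4200, ka = 51.9, clm0_fm = 126,
                      vcm_fm = 2300, qm_fm = 113, vpm_fm = 1480,
                      tdpk = 0.41, k_tdpk = 0.0363),
    omega2 = NULL, sigma_p = 0.05, sigma_m = 0.05)
  f <- fit_pk(ds, init, stage = "parent", free = "CL_F", bql = "m1")
  expect_equal(f$full[["CL_F"]], 2850, tolerance = 1e-3)
})

test_that("sequential fitting fixes the parent stage and needs both analytes", {
  ds <- generate_dataset(small_design(3), ref_params(), seed = 35)
  expect_error(fit_sequential(pmpk:::filter_analyte(ds, "parent"),
                              ref_params()),
               "metabolite observations")
  sf <- fit_sequential(ds, ref_params(), bql = "m3", try_m3 = TRUE)
  # stage 2 must not move the parent parameters fixed from stage 1
  expect_equal(sf$combined$full[c("CL_F", "V_F", "KA")],
               sf$parent$full[c("CL_F", "V_F", "KA")])
  expect_equal(sf$combined$full[["SIGMA_P"]], sf$parent$full[["SIGMA_P"]])
  expect_s3_class(sf$m3_attempt, "pmpk_fit")
  # nested-model inequality: freeing the time-dependence cannot fit worse
  est <- sf$combined$estimates
  th0 <- unclass(est$theta); th0["TDPK"] <- 1e-9
  init0 <- population_params(structure(th0, class = "structural_params"),
                             omega2 = est$omega2, sigma_p = est$sigma_p,
                             sigma_m = est$sigma_m)
  f0 <- fit_pk(ds, init0, stage = "combined", bql = "m1",
               fixed = c("TDPK", "K_TDPK"))
  expect_lte(sf$combined$ofv, f0$ofv + 0.2)
})

test_that("standard errors are finite and on a plausible scale", {
  ds <- generate_dataset(small_design(3), ref_params(), seed = 36)
  f <- fit_pk(ds, ref_params(), stage = "parent", bql = "m3", se = TRUE)
  expect_true(all(is.finite(f$se[c("CL_F", "V_F", "SIGMA_P")])))
  expect_true(all(f$rse[c("CL_F", "V_F")] > 0.5 &
                    f$rse[c("CL_F", "V_F")] < 100))
})
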