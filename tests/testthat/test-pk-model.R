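# Structural model: time-varying metabolite clearance, closed-form parent
# kinetics, ODE simulation against independent oracles, derived half-lives.

test_that("metabolite clearance follows the exponential time-decline", {
  p <- ref_params()$theta
  expect_equal(metabolite_clearance_at(p, 0), 126)
  # asymptote: CLm0 * (1 - TDPK), reached exactly in the limit
  expect_equal(metabolite_clearance_at(p, 1e9), 126 * (1 - 0.41))
  tt <- seq(0, 400, by = 0.5)
  cl <- metabolite_clearance_at(p, tt)
  expect_true(all(diff(cl) <= 0))
  expect_true(all(cl >= 126 * (1 - 0.41) - 1e-12))
  # no time dependence when TDPK = 0
  p0 <- structural_params(cl_f = 2850, v_f = 4200, ka = 51.9, clm0_fm = 126,
                          vcm_fm = 2300, qm_fm = 113, vpm_fm = 1480,
                          tdpk = 0, k_tdpk = 0.0363)
  expect_equal(metabolite_clearance_at(p0, c(0, 10, 500)), rep(126, 3))
  expect_error(metabolite_clearance_at(p, -1), "finite and >= 0")
})

test_that("closed-form parent concentration matches independent Bateman", {
  p <- ref_params()$theta
  expect_equal(as.numeric(parent_concentration(p, 0, dose = 200)), 0)
  # frozen from independent evaluation: 200 mg, t = 1 h, ke = 2850/4200
  expect_equal(as.numeric(parent_concentration(p, 1, dose = 200)), 24.479,
               tolerance = 1e-4)
  tt <- c(0.1, 0.5, 1, 2, 5, 12)
  expect_equal(parent_concentration(p, tt, dose = 200),
               unname(oracle_bateman(200, tt, 2850, 4200, 51.9)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # AUC(0-inf) = dose / CL by numerical quadrature (ng*h/mL scale)
  auc <- stats::integrate(function(t) parent_concentration(p, t, dose = 200),
                          0, Inf, rel.tol = 1e-10)$value
  expect_equal(auc, 200 / 2850 * 1000, tolerance = 1e-6)
})

test_that("ka == ke degenerate case uses the analytic limit branch", {
  p <- structural_params(cl_f = 100, v_f = 100, ka = 1, clm0_fm = 126,
                         vcm_fm = 2300, qm_fm = 113, vpm_fm = 1480)
  cc <- parent_concentration(p, c(0.5, 1, 2), dose = 100)
  expect_identical(attr(cc, "bateman_branch"), "ka_equals_ke")
  # limit form (D/V) ka t e^(-ka t), in ng/mL
  expect_equal(as.numeric(cc), 1000 * (100 / 100) * 1 * c(0.5, 1, 2) *
                 exp(-c(0.5, 1, 2)), tolerance = 1e-12)
  p2 <- ref_params()$theta
  expect_identical(attr(parent_concentration(p2, 1, dose = 100),
                        "bateman_branch"), "general")
})

test_that("simulated parent channel equals Bateman superposition", {
  p <- ref_params()$theta
  for (reg in list(regimen_single(200), regimen_bid(300, 3))) {
    tt <- sort(c(seq(0.25, max(reg$time) + 12, length.out = 40), reg$time + 0.01))
    prof <- simulate_profile(p, reg, tt)
    oracle <- rowSums(vapply(seq_len(nrow(reg)), function(j) {
      tau <- tt - reg$time[j]
      ifelse(tau >= 0, oracle_bateman(reg$amount[j], pmax(tau, 0),
                                      2850, 4200, 51.9), 0)
    }, numeric(length(tt))))
    expect_equal(prof$parent, oracle, tolerance = 1e-6)
  }
})

test_that("full system matches an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  p <- ref_params()$theta
  reg <- regimen_bid(250, 3)
  tt <- c(0.5, 1, 2, 6, 12, 23.9, 36, 48, 60, 71.9)
  prof <- simulate_profile(p, reg, tt)
  oracle <- oracle_desolve_profile(p, reg, tt, unit_constants()$molar_factor)
  expect_equal(prof$parent, oracle$parent, tolerance = 1e-5)
  expect_equal(prof$metabolite, oracle$metabolite, tolerance = 1e-5)
})

test_that("mass balance closes to the administered dose", {
  p <- ref_params()$theta
  reg <- regimen_bid(300, 4)
  prof <- simulate_profile(p, reg, c(50, 96, 2000), balance = TRUE)
  total <- unname(rowSums(prof[, c("A_depot", "A_parent", "A_met_central",
                                   "A_met_peripheral", "A_met_eliminated")]))
  # mid-schedule: everything administered so far (5 of 8 doses by t = 50)
  expect_equal(total[1], 300 * 5, tolerance = 1e-6)
  # after the last dose: the full administered amount
  expect_equal(total[2], 300 * 8, tolerance = 1e-6)
  # long after the last dose: all mass eliminated via the metabolite
  expect_equal(prof$A_met_eliminated[3], 300 * 8, tolerance = 1e-6)
  expect_lt(prof$A_parent[3] + prof$A_met_central[3], 1e-4)
})

test_that("negligible parent elimination yields no metabolite", {
  p <- structural_params(cl_f = 1e-9, v_f = 4200, ka = 51.9, clm0_fm = 126,
                         vcm_fm = 2300, qm_fm = 113, vpm_fm = 1480)
  prof <- simulate_profile(p, regimen_single(200), c(1, 10, 100), balance = TRUE)
  expect_true(all(prof$metabolite < 1e-6))
  expect_equal(prof$A_depot + prof$A_parent, rep(200, 3), tolerance = 1e-6)
})

test_that("steady-state metabolite AUC over the last interval is dose/CL_ss", {
  p <- ref_params()$theta
  uc <- unit_constants()
  grid <- seq(648, 660, by = 0.25)
  prof <- simulate_profile(p, regimen_bid(300, 28), grid)
  auc <- auc_trapezoid(grid - 648, prof$metabolite)
  expect_equal(auc, 300 * uc$molar_factor / (126 * (1 - 0.41)) * 1000,
               tolerance = 0.005)
  # with TDPK = 0 the same identity holds against CLm0 (superposition check)
  p0 <- structural_params(cl_f = 2850, v_f = 4200, ka = 51.9, clm0_fm = 126,
                          vcm_fm = 2300, qm_fm = 113, vpm_fm = 1480)
  prof0 <- simulate_profile(p0, regimen_qd(200, 28), seq(648, 672, by = 0.25))
  auc0 <- auc_trapezoid(seq(0, 24, by = 0.25), prof0$metabolite)
  expect_equal(auc0, 200 * uc$molar_factor / 126 * 1000, tolerance = 0.005)
})

test_that("derived half-lives reproduce the reported values", {
  p <- ref_params()$theta
  expect_equal(round(parent_half_life(p), 1), 1.0)
  expect_equal(parent_half_life(p), log(2) * 4200 / 2850, tolerance = 1e-12)
  hl <- metabolite_half_lives_ss(p)
  expect_equal(round(unname(hl), 1), c(4.9, 39.4))
  # Vieta identities for the macro constants
  cl_ss <- 126 * (1 - 0.41)
  k10 <- cl_ss / 2300; k12 <- 113 / 2300; k21 <- 113 / 1480
  alpha <- log(2) / hl[["distribution"]]; beta <- log(2) / hl[["elimination"]]
  expect_equal(alpha * beta, k10 * k21, tolerance = 1e-12)
  expect_equal(alpha + beta, k10 + k12 + k21, tolerance = 1e-12)
  # proportionality and the 1-compartment limit
  p2 <- structural_params(cl_f = 2850, v_f = 8400, ka = 51.9, clm0_fm = 126,
                          vcm_fm = 2300, qm_fm = 113, vpm_fm = 1480,
                          tdpk = 0.41, k_tdpk = 0.0363)
  expect_equal(parent_half_life(p2), 2 * parent_half_life(p))
  # vanishing inter-compartmental exchange: the disposition collapses to a
  # single exponential with rate CL_ss/Vcm (the other macro root is the
  # vestigial, empty peripheral mode)
  p3 <- structural_params(cl_f = 2850, v_f = 4200, ka = 51.9, clm0_fm = 126,
                          vcm_fm = 2300, qm_fm = 1e-6, vpm_fm = 1480,
                          tdpk = 0.41, k_tdpk = 0.0363)
  expect_equal(metabolite_half_lives_ss(p3)[["distribution"]],
               log(2) * 2300 / cl_ss, tolerance = 1e-3)
})

test_that("parameter and regimen validation reject malformed input", {
  expect_error(structural_params(cl_f = -1, v_f = 4200, ka = 51.9,
                                 clm0_fm = 126, vcm_fm = 2300, qm_fm = 113,
                                 vpm_fm = 1480), "strictly positive")
  expect_error(structural_params(cl_f = 2850, v_f = 4200, ka = 51.9,
                                 clm0_fm = 126, vcm_fm = 2300, qm_fm = 113,
                                 vpm_fm = 1480, tdpk = 1.2), "TDPK")
  expect_error(regimen(c(0, 0), 100), "strictly increasing")
  expect_error(regimen(0, -5), "> 0")
  expect_equal(nrow(regimen_bid(300, 28)), 56)
  expect_equal(regimen_qd(100, 28)$time, 24 * (0:27))
})
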