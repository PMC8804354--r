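# Independent oracles and small fixtures shared across the suite.
# Everything here is deliberately written without reference to the package's
# own computational paths (plain-R closed forms, quadrature, deSolve).

ref_params <- function() adult_reference_params()

# Independent Bateman evaluation (single oral dose, 1-compartment parent).
oracle_bateman <- function(dose_mg, t, cl, v, ka) {
  ke <- cl / v
  1000 * (dose_mg / v) * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix),
# for integrals of the form  int f(x) exp(-x^2) dx.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Adaptive Gauss-Hermite approximation of the exact -2 log marginal
# likelihood for a single subject with one active eta:
#   L = int p(y | eta) phi(eta; 0, omega^2) d eta,
# with p the proportional-error normal evaluated at the conditional
# prediction f(eta) (interaction). f_of_eta is supplied by the test.
oracle_neg2ll_aghq <- function(y, f_of_eta, sigma, omega, n_nodes = 60) {
  g <- function(eta) {  # -2 log joint
    f <- f_of_eta(eta)
    sum(log(2 * pi) + 2 * log(sigma * f) + ((y - f) / (sigma * f))^2) +
      eta^2 / omega^2 + log(2 * pi * omega^2)
  }
  mode <- stats::optimize(g, c(-6 * omega, 6 * omega))$minimum
  h <- 1e-4
  hess <- (g(mode + h) - 2 * g(mode) + g(mode - h)) / h^2  # of -2 log joint
  sd_hat <- sqrt(2 / hess)                                 # Laplace sd
  gh <- gauss_hermite(n_nodes)
  # int e^{-g(eta)/2} deta  with  eta = mode + sqrt(2) sd x:
  #   = sqrt(2) sd * sum_i w_i exp(-g(x_i)/2 + x_i^2)
  x <- mode + sqrt(2) * sd_hat * gh$nodes
  vals <- -0.5 * vapply(x, g, numeric(1)) + gh$nodes^2
  m <- max(vals)
  integral <- sqrt(2) * sd_hat * sum(gh$weights * exp(vals - m)) * exp(m)
  -2 * log(integral)
}

# deSolve oracle for the full 4-state system (depot, parent, metabolite
# central/peripheral) with the time-varying metabolite clearance.
oracle_desolve_profile <- function(params, reg, times, molar) {
  p <- as.list(unclass(params))
  rhs <- function(t, y, parms) {
    ke <- p$CL_F / p$V_F
    clm <- p$CLM0_FM * (1 - p$TDPK * (1 - exp(-p$K_TDPK * t)))
    dAa <- -p$KA * y[1]
    dAp <- p$KA * y[1] - ke * y[2]
    dAcm <- ke * y[2] - (clm / p$VCM_FM) * y[3] - (p$QM_FM / p$VCM_FM) * y[3] +
      (p$QM_FM / p$VPM_FM) * y[4]
    dApm <- (p$QM_FM / p$VCM_FM) * y[3] - (p$QM_FM / p$VPM_FM) * y[4]
    list(c(dAa, dAp, dAcm, dApm))
  }
  ev <- data.frame(var = "Aa", time = reg$time, value = reg$amount,
                   method = "add")
  tt <- sort(unique(c(times, reg$time)))
  out <- deSolve::lsoda(c(Aa = 0, Ap = 0, Acm = 0, Apm = 0), tt, rhs, NULL,
                        events = list(data = ev), rtol = 1e-10, atol = 1e-12)
  idx <- match(times, out[, 1])
  data.frame(time = times,
             parent = out[idx, 3] / p$V_F * 1000,
             metabolite = out[idx, 4] / p$VCM_FM * 1000 * molar)
}

# A small, fast design (subset of the study arms) for estimation tests.
small_design <- function(n_per_arm = 3) {
  d <- default_study_design()
  arms <- d$arms[c(2, 5, 8)]  # 200 single, 300 QD, 250 BID
  arms <- lapply(arms, function(a) { a$n <- n_per_arm; a$n_adol <- 0; a })
  structure(list(arms = arms), class = "study_design")
}
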