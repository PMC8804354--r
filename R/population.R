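# Stochastic layer: inter-individual variability, covariate effect
# functions, residual error, and allometric weight scaling.

#' Define a covariate effect on a PK parameter
#'
#' Continuous covariates act through a power function normalized to the
#' population median, `P = theta1 * (cov/ref)^theta2`; categorical covariates
#' through a fractional-change function, `P = theta1 * theta2^factor` with
#' `factor` in \{0, 1\}.
#'
#' @param parameter name of the structural parameter (e.g. `"CL_F"`)
#' @param covariate name of the covariate column (e.g. `"WT"`)
#' @param form `"power"` or `"fractional"`
#' @param theta2 effect coefficient; `NA` means "to be estimated"
#' @param reference population median (power form) or reference category
#'   value (ignored for fractional, which keys on factor = 0/1)
#' @return object of class `covariate_effect`
#' @export
covariate_effect <- function(parameter, covariate,
                             form = c("power", "fractional"),
                             theta2 = NA_real_, reference = NA_real_) {
  form <- match.arg(form)
  if (form == "power" && !is.na(reference) && reference <= 0) {
    stop("power-form reference must be positive")
  }
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 theta2 = theta2, reference = reference),
            class = "covariate_effect")
}

#' Multiplicative covariate factor for one subject
#' @param effect a [covariate_effect()]
#' @param value the subject's covariate value
#' @return scalar factor
#' @export
covariate_factor <- function(effect, value) {
  if (is.na(value)) return(1)
  if (effect$form == "power") {
    if (value <= 0) stop("power-form covariates must be positive")
    (value / effect$reference)^effect$theta2
  } else {
    if (!value %in% c(0, 1)) stop("fractional-form factor must be 0 or 1")
    effect$theta2^value
  }
}

#' Individual parameters from typical values, covariates and random effects
#'
#' `theta_i = theta_TV * prod(covariate factors) * exp(eta)`, with log-normal
#' etas on CL/F, V/F, CLm0/Fm, Vcm/Fm and Vpm/Fm only; other parameters pass
#' through their typical values.
#'
#' @param pop a [population_params()] object
#' @param etas named numeric vector of random effects; names must be among
#'   the parameters that carry IIV. Missing entries are 0.
#' @param cov_effects optional list of [covariate_effect()]s (with `theta2`
#'   and `reference` set)
#' @param covariates optional named list/vector of the subject's covariates
#' @return a [structural_params()] object
#' @export
individual_params <- function(pop, etas = NULL, cov_effects = NULL,
                              covariates = NULL) {
  stopifnot(inherits(pop, "population_params"))
  theta <- unclass(pop$theta)
  eta_ok <- names(pop$omega2)[pop$omega2 > 0]
  if (!is.null(etas) && length(etas)) {
    bad <- setdiff(names(etas), eta_ok)
    if (length(bad)) {
      stop("eta supplied for parameter(s) without IIV: ",
           paste(bad, collapse = ", "))
    }
    theta[names(etas)] <- theta[names(etas)] * exp(unlist(etas))
  }
  for (ef in cov_effects %||% list()) {
    val <- covariates[[ef$covariate]]
    if (is.null(val)) stop("covariate not available: ", ef$covariate)
    theta[ef$parameter] <- theta[ef$parameter] * covariate_factor(ef, val)
  }
  structure(theta, class = "structural_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample inter-individual random effects
#'
#' Independent mean-zero normal draws with the diagonal covariance implied by
#' `pop$omega2`; parameters with zero variance get exactly zero.
#'
#' @param pop a [population_params()] object
#' @param n number of subjects
#' @param seed optional integer seed (uses the current RNG stream when NULL)
#' @return `n x 5` matrix with columns `CL_F`, `V_F`, `CLM0_FM`, `VCM_FM`,
#'   `VPM_FM`
#' @export
sample_etas <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sds <- sqrt(pop$omega2)
  m <- vapply(sds, function(s) if (s > 0) stats::rnorm(n, 0, s) else rep(0, n),
              numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(sds)))
  m
}

#' Apply proportional residual error
#'
#' `y = f * (1 + eps)` with `eps ~ N(0, sigma^2)`; additive
#' (`y = f + eps`, eps in ng/mL) and combined forms are available as options.
#'
#' @param conc predicted concentrations (>= 0)
#' @param sigma proportional SD (fraction), or additive SD for `"additive"`
#' @param eps_draw optional pre-drawn standard-normal deviates (recycled);
#'   drawn internally when NULL
#' @param form `"proportional"` (default), `"additive"` or `"combined"`
#' @param sigma_add additive SD used by `"combined"`
#' @return perturbed concentrations
#' @export
apply_residual_error <- function(conc, sigma, eps_draw = NULL,
                                 form = c("proportional", "additive", "combined"),
                                 sigma_add = 0) {
  form <- match.arg(form)
  if (any(conc < 0)) stop("conc must be >= 0")
  if (is.null(eps_draw)) eps_draw <- stats::rnorm(length(conc))
  eps_draw <- rep_len(eps_draw, length(conc))
  switch(form,
         proportional = conc * (1 + sigma * eps_draw),
         additive = conc + sigma * eps_draw,
         combined = conc * (1 + sigma * eps_draw) +
           sigma_add * rep_len(stats::rnorm(length(conc)), length(conc)))
}

#' Allometric scaling of clearances and volumes with body weight
#'
#' Clearance-type parameters (CL/F, CLm0/Fm, Qm/Fm) scale with
#' `(weight/ref_weight)^0.75`; volumes (V/F, Vcm/Fm, Vpm/Fm) scale linearly;
#' Ka, TDPK and K_TDPK are unchanged. The default reference is 59 kg, the
#' adult median body weight of the analysis population (the total-population
#' median, 58.3 kg, is the common alternative).
#'
#' @param params a [structural_params()] object (typical adult values)
#' @param weight body weight (kg), > 0
#' @param ref_weight reference weight (kg)
#' @param cl_exponent,v_exponent fixed allometric exponents
#' @return scaled [structural_params()]
#' @export
allometric_scale <- function(params, weight, ref_weight = 59,
                             cl_exponent = 0.75, v_exponent = 1) {
  validate_structural_params(params)
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive")
  r <- weight / ref_weight
  p <- unclass(params)
  p[c("CL_F", "CLM0_FM", "QM_FM")] <- p[c("CL_F", "CLM0_FM", "QM_FM")] * r^cl_exponent
  p[c("V_F", "VCM_FM", "VPM_FM")] <- p[c("V_F", "VCM_FM", "VPM_FM")] * r^v_exponent
  structure(p, class = "structural_params")
}
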