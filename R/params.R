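# Structural and population parameters, packaged reference estimates,
# and config-file serialization.

#' Nominal molecular weights and derived unit constants
#'
#' The assay quantified both analytes in molar units (LLOQ 1 nmol/L for each);
#' the true molecular weights are proprietary, so the package carries nominal
#' values: 491 g/mol for the parent and 449 g/mol for the metabolite (the
#' parent minus an acetyl group, and consistent with the 1.09 parent/crizotinib
#' mass ratio used in the pediatric starting-dose rule). They are used only to
#' convert the molar LLOQ to mass units and to convert metabolite amounts
#' (tracked in parent-mass equivalents, FM = 1 on the molar scale) to mass
#' concentrations.
#'
#' @return Named list with `mw_parent`, `mw_metabolite`, `molar_factor`
#'   (= mw_metabolite/mw_parent), `lloq_parent` and `lloq_metabolite` in ng/mL.
#' @export
unit_constants <- function() {
  mw_p <- 491
  mw_m <- 449
  list(
    mw_parent = mw_p,
    mw_metabolite = mw_m,
    molar_factor = mw_m / mw_p,
    lloq_parent = 1e-3 * mw_p,     # 1 nmol/L in ng/mL
    lloq_metabolite = 1e-3 * mw_m
  )
}

#' Structural (fixed-effect) PK parameters
#'
#' Parameters of the coupled parent/metabolite model: a 1-compartment parent
#' with first-order absorption and elimination, and a 2-compartment metabolite
#' whose apparent clearance declines exponentially with time on treatment,
#' `CLm(t) = CLm0/Fm * (1 - TDPK * (1 - exp(-K_TDPK * t)))`.
#'
#' @param cl_f apparent parent clearance CL/F (L/h)
#' @param v_f apparent parent central volume V/F (L)
#' @param ka first-order absorption rate constant (1/h)
#' @param clm0_fm apparent metabolite clearance at time zero CLm0/Fm (L/h)
#' @param vcm_fm apparent metabolite central volume Vcm/Fm (L)
#' @param qm_fm apparent metabolite inter-compartmental clearance Qm/Fm (L/h)
#' @param vpm_fm apparent metabolite peripheral volume Vpm/Fm (L)
#' @param tdpk maximum fractional reduction of metabolite clearance, in [0, 1)
#' @param k_tdpk rate constant of the clearance decline (1/h)
#' @return A named numeric vector of class `structural_params`. The conversion
#'   fraction FM is fixed at 1 (molar) and is not a free field.
#' @export
structural_params <- function(cl_f, v_f, ka, clm0_fm, vcm_fm, qm_fm, vpm_fm,
                              tdpk = 0, k_tdpk = 0) {
  p <- c(CL_F = cl_f, V_F = v_f, KA = ka, CLM0_FM = clm0_fm, VCM_FM = vcm_fm,
         QM_FM = qm_fm, VPM_FM = vpm_fm, TDPK = tdpk, K_TDPK = k_tdpk)
  validate_structural_params(p)
  structure(p, class = "structural_params")
}

validate_structural_params <- function(p) {
  need <- c("CL_F", "V_F", "KA", "CLM0_FM", "VCM_FM", "QM_FM", "VPM_FM",
            "TDPK", "K_TDPK")
  if (!all(need %in% names(p))) {
    stop("structural_params is missing fields: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  }
  pos <- c("CL_F", "V_F", "KA", "CLM0_FM", "VCM_FM", "QM_FM", "VPM_FM")
  if (any(!is.finite(p[need])) || any(p[pos] <= 0)) {
    stop("rate, volume and clearance parameters must be strictly positive")
  }
  if (p[["TDPK"]] < 0 || p[["TDPK"]] >= 1) stop("TDPK must lie in [0, 1)")
  if (p[["K_TDPK"]] < 0) stop("K_TDPK must be non-negative")
  invisible(p)
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural PK parameters (oral, apparent; FM = 1 molar):\n")
  print(unclass(x))
  invisible(x)
}

#' Population parameters: typical values, IIV variances and residual SDs
#'
#' Inter-individual variability is log-normal (`theta_i = theta_tv * exp(eta)`)
#' with independent, mean-zero etas on CL/F, V/F, CLm0/Fm, Vcm/Fm and Vpm/Fm;
#' the remaining structural parameters carry no IIV. Residual error is
#' proportional for both analytes, `y = f * (1 + eps)`.
#'
#' @param theta a [structural_params()] vector of typical values
#' @param omega2 named variances of the etas; names among
#'   `CL_F`, `V_F`, `CLM0_FM`, `VCM_FM`, `VPM_FM`. Missing entries are 0.
#' @param sigma_p,sigma_m proportional residual SD for parent and metabolite
#' @return object of class `population_params`
#' @export
population_params <- function(theta, omega2 = NULL, sigma_p, sigma_m) {
  validate_structural_params(theta)
  onames <- c("CL_F", "V_F", "CLM0_FM", "VCM_FM", "VPM_FM")
  om <- stats::setNames(numeric(5), onames)
  if (!is.null(omega2)) {
    bad <- setdiff(names(omega2), onames)
    if (length(bad)) {
      stop("IIV is not modelled on: ", paste(bad, collapse = ", "))
    }
    om[names(omega2)] <- omega2
  }
  if (any(om < 0)) stop("omega2 entries must be >= 0")
  if (sigma_p <= 0 || sigma_m <= 0) stop("sigma_p and sigma_m must be > 0")
  structure(list(theta = structure(theta, class = "structural_params"),
                 omega2 = om, sigma_p = sigma_p, sigma_m = sigma_m),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population PK parameters\n  Typical values:\n")
  print(unclass(x$theta))
  cat("  IIV variances (omega^2):\n")
  print(x$omega2)
  cat(sprintf("  Residual proportional SD: parent %.3f, metabolite %.3f\n",
              x$sigma_p, x$sigma_m))
  invisible(x)
}

#' Packaged adult reference estimates of the final model
#'
#' The fixed effects, IIV magnitudes and residual error of the final adult /
#' adolescent model: CL/F 2850 L/h, V/F 4200 L, Ka 51.9 1/h, CLm0/Fm 126 L/h,
#' Vcm/Fm 2300 L, Qm/Fm 113 L/h, Vpm/Fm 1480 L, TDPK 0.41, K_TDPK 0.0363 1/h;
#' eta \%CVs 28.1/32.6/34.1/53.1/83.6 on CL/F, V/F, CLm0/Fm, Vcm/Fm, Vpm/Fm;
#' proportional residual \%CVs 71.1 (parent) and 31.9 (metabolite). A reported
#' \%CV is interpreted as 100 times the SD of the corresponding eta (or eps).
#'
#' @return a [population_params()] object
#' @export
adult_reference_params <- function() {
  theta <- structural_params(cl_f = 2850, v_f = 4200, ka = 51.9,
                             clm0_fm = 126, vcm_fm = 2300, qm_fm = 113,
                             vpm_fm = 1480, tdpk = 0.41, k_tdpk = 0.0363)
  population_params(
    theta,
    omega2 = c(CL_F = 0.281^2, V_F = 0.326^2, CLM0_FM = 0.341^2,
               VCM_FM = 0.531^2, VPM_FM = 0.836^2),
    sigma_p = 0.711, sigma_m = 0.319
  )
}

#' Write / read model parameters as a YAML config
#'
#' Keys follow the conventional parameter symbols (`CL_F`, `V_F`, `KA`,
#' `CLM0_FM`, `VCM_FM`, `QM_FM`, `VPM_FM`, `TDPK`, `K_TDPK`, `FM`) with
#' `OMEGA_*` variance and `SIGMA_P`/`SIGMA_M` residual entries.
#'
#' @param pop a [population_params()] or [structural_params()] object
#' @param path file path
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns the deserialized object.
#' @export
write_model_config <- function(pop, path) {
  if (inherits(pop, "structural_params")) {
    pop <- population_params(pop, sigma_p = 1e-6, sigma_m = 1e-6)
    pop$sigma_p <- NULL
    pop$sigma_m <- NULL
    out <- c(as.list(unclass(pop$theta)), list(FM = 1))
  } else {
    out <- c(as.list(unclass(pop$theta)), list(FM = 1),
             stats::setNames(as.list(pop$omega2),
                             paste0("OMEGA_", names(pop$omega2))),
             list(SIGMA_P = pop$sigma_p, SIGMA_M = pop$sigma_m))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  theta <- structural_params(cl_f = x$CL_F, v_f = x$V_F, ka = x$KA,
                             clm0_fm = x$CLM0_FM, vcm_fm = x$VCM_FM,
                             qm_fm = x$QM_FM, vpm_fm = x$VPM_FM,
                             tdpk = x$TDPK, k_tdpk = x$K_TDPK)
  if (!is.null(x$FM) && x$FM != 1) stop("FM is fixed to 1")
  omn <- grep("^OMEGA_", names(x), value = TRUE)
  if (!length(omn) && is.null(x$SIGMA_P)) return(theta)
  om <- stats::setNames(unlist(x[omn]), sub("^OMEGA_", "", omn))
  population_params(theta, omega2 = om, sigma_p = x$SIGMA_P, sigma_m = x$SIGMA_M)
}
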