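# Synthetic study-data generator: reproduces the two source study designs
# (single-dose and 28-day QD arms; 28-day BID arms with adolescents), the
# reported covariate distributions, proportional residual error and LLOQ
# censoring, so the whole pipeline is testable without clinical data.

#' Default study design
#'
#' Two pooled studies. Study 1 (adults with solid tumours): single doses of
#' 100 or 200 mg sampled to 168 h; 100/200/300 mg QD for 28 days sampled on
#' days 1 and 28 plus pre-dose troughs on days 7/14/21. Study 2 (adults and
#' adolescents): 200/250/300/350 mg BID for 28 days with the analogous
#' schedule. The per-arm subject allocation was not reported; the default
#' splits 40 subjects (34 adults, 6 adolescents) evenly across arms within
#' each study, with adolescents only in the BID arms.
#'
#' @param n_scale multiply all per-arm subject counts (keeps the design shape)
#' @return object of class `study_design`: a list of arm descriptions
#' @export
default_study_design <- function(n_scale = 1) {
  sd_times <- c(0, 0.5, 1, 2, 3, 4, 6, 10, 24, 48, 72, 120, 168)
  qd_day1 <- c(0, 0.5, 1, 2, 4, 6, 10, 24)
  qd_times <- c(qd_day1, 144, 312, 480, 648 + qd_day1)
  bid_day1 <- c(0, 0.5, 1, 2, 4, 6, 10, 12)
  bid_times <- c(bid_day1, 144, 312, 480, 648 + bid_day1)
  arms <- list()
  for (dose in c(100, 200)) {
    arms[[length(arms) + 1]] <- list(study = "phase1", schedule = "single",
                                     dose = dose, days = 1, n = 4, n_adol = 0,
                                     sample_times = sd_times)
  }
  for (dose in c(100, 200, 300)) {
    arms[[length(arms) + 1]] <- list(study = "phase1", schedule = "qd",
                                     dose = dose, days = 28, n = 4, n_adol = 0,
                                     sample_times = qd_times)
  }
  n_adol <- c(2, 2, 1, 1)
  doses_bid <- c(200, 250, 300, 350)
  for (k in seq_along(doses_bid)) {
    arms[[length(arms) + 1]] <- list(study = "phase2", schedule = "bid",
                                     dose = doses_bid[k], days = 28, n = 5,
                                     n_adol = n_adol[k],
                                     sample_times = bid_times)
  }
  if (n_scale != 1) {
    arms <- lapply(arms, function(a) {
      a$n <- max(1L, as.integer(round(a$n * n_scale)))
      a$n_adol <- min(a$n_adol, a$n)
      a
    })
  }
  structure(list(arms = arms), class = "study_design")
}

# Baseline covariate distribution specs per stratum. Continuous covariates
# are log-normal (positivity) except age/albumin/eGFR (normal), all truncated
# to the observed ranges; serum creatinine was not tabulated and uses a
# plausible synthetic spec (micromol/L).
covariate_spec_table <- function() {
  rbind(
    data.frame(cov = "WT", stratum = "adult", dist = "lnorm", m = 59.0, s = 0.201, lo = 42.0, hi = 87.7),
    data.frame(cov = "WT", stratum = "adol", dist = "lnorm", m = 41.8, s = 0.275, lo = 32.9, hi = 68.0),
    data.frame(cov = "BMI", stratum = "adult", dist = "lnorm", m = 21.6, s = 0.182, lo = 16.1, hi = 34.7),
    data.frame(cov = "BMI", stratum = "adol", dist = "lnorm", m = 17.5, s = 0.190, lo = 16.0, hi = 25.3),
    data.frame(cov = "AGE", stratum = "adult", dist = "norm", m = 52.0, s = 12.8, lo = 28, hi = 73),
    data.frame(cov = "AGE", stratum = "adol", dist = "norm", m = 12.8, s = 1.3, lo = 11, hi = 14),
    data.frame(cov = "ALB", stratum = "adult", dist = "norm", m = 39.9, s = 4.5, lo = 28.2, hi = 46.2),
    data.frame(cov = "ALB", stratum = "adol", dist = "norm", m = 44.8, s = 3.7, lo = 40.5, hi = 49.5),
    data.frame(cov = "ALT", stratum = "adult", dist = "lnorm", m = 39.0, s = 0.59, lo = 9, hi = 153),
    data.frame(cov = "ALT", stratum = "adol", dist = "lnorm", m = 37.8, s = 0.46, lo = 26.8, hi = 87.2),
    data.frame(cov = "AST", stratum = "adult", dist = "lnorm", m = 37.5, s = 0.44, lo = 18, hi = 93),
    data.frame(cov = "AST", stratum = "adol", dist = "lnorm", m = 30.5, s = 0.28, lo = 18.9, hi = 46.9),
    data.frame(cov = "TBIL", stratum = "adult", dist = "lnorm", m = 8.4, s = 0.284, lo = 5.0, hi = 15.9),
    data.frame(cov = "TBIL", stratum = "adol", dist = "lnorm", m = 4.9, s = 0.40, lo = 2.4, hi = 8.7),
    data.frame(cov = "EGFR", stratum = "adult", dist = "norm", m = 83.8, s = 22.3, lo = 51.1, hi = 138.8),
    data.frame(cov = "EGFR", stratum = "adol", dist = "norm", m = 117.9, s = 19.0, lo = 95.9, hi = 140.4),
    data.frame(cov = "SCR", stratum = "adult", dist = "lnorm", m = 70, s = 0.20, lo = 30, hi = 140),
    data.frame(cov = "SCR", stratum = "adol", dist = "lnorm", m = 50, s = 0.20, lo = 25, hi = 100)
  )
}

# location calibrated so that the TRUNCATED distribution keeps the published
# median: asymmetric range truncation would otherwise shift it
calibrated_meanlog <- function(m, s, lo, hi) {
  f <- function(mu) {
    flo <- stats::plnorm(lo, mu, s)
    fhi <- stats::plnorm(hi, mu, s)
    stats::qlnorm((flo + fhi) / 2, mu, s) - m
  }
  stats::uniroot(f, c(log(m) - 2 * s, log(m) + 2 * s), tol = 1e-10)$root
}

rtrunc <- function(n, dist, m, s, lo, hi) {
  mu <- if (dist == "lnorm") calibrated_meanlog(m, s, lo, hi) else m
  draw <- function(k) {
    if (dist == "lnorm") stats::rlnorm(k, mu, s) else stats::rnorm(k, m, s)
  }
  x <- draw(n)
  for (i in 1:200) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- draw(sum(bad))
  }
  pmin(pmax(x, lo), hi)
}

#' Sample baseline covariates for one stratum
#'
#' Draws the tabulated baseline covariates (log-normal / normal, truncated to
#' the observed ranges) for adults or adolescents; height is derived from
#' weight and BMI, BSA by the Mosteller formula; male fraction 0.50 (adult)
#' or 0.667 (adolescent); obesity prevalence 5.9\% (adult) / 0\%.
#'
#' @param n number of subjects
#' @param stratum `"adult"` or `"adol"`
#' @return data.frame with the covariate columns of the dataset dialect
#' @export
sample_covariates <- function(n, stratum = c("adult", "adol")) {
  stratum <- match.arg(stratum)
  spec <- covariate_spec_table()
  spec <- spec[spec$stratum == stratum, ]
  out <- list()
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    out[[s$cov]] <- rtrunc(n, s$dist, s$m, s$s, s$lo, s$hi)
  }
  out$HT <- sqrt(out$WT / out$BMI) * 100
  out$BSA <- body_surface_area(out$HT, out$WT)
  out$SEX <- stats::rbinom(n, 1, if (stratum == "adult") 0.50 else 0.667)
  out$OBESE <- stats::rbinom(n, 1, if (stratum == "adult") 0.059 else 0)
  out$ADOL <- as.integer(stratum == "adol")
  as.data.frame(out)[, DATASET_COVARIATES]
}

#' Generate a synthetic PK dataset
#'
#' Draws covariates and random effects, simulates individual concentration
#' profiles at the design sampling times, applies proportional residual
#' error per analyte and censors below the (molar-derived) LLOQs, keeping
#' censored records with `BLQ = 1` and `DV = NA`. A pre-dose sample taken at
#' a dose time is treated as pre-dose.
#'
#' @param design a [default_study_design()]-style object
#' @param truth generating [population_params()]
#' @param seed integer seed
#' @param cov_effects optional list of [covariate_effect()]s active in the
#'   generating model (none in the final model)
#' @return a [pk_dataset()]
#' @export
generate_dataset <- function(design = default_study_design(),
                             truth = adult_reference_params(),
                             seed = 1, cov_effects = NULL) {
  set.seed(seed)
  uc <- unit_constants()
  rows <- list()
  id <- 0
  for (arm in design$arms) {
    reg <- switch(arm$schedule,
                  single = regimen_single(arm$dose),
                  qd = regimen_qd(arm$dose, arm$days),
                  bid = regimen_bid(arm$dose, arm$days))
    strata <- c(rep("adol", arm$n_adol), rep("adult", arm$n - arm$n_adol))
    covs_adult <- if (arm$n - arm$n_adol > 0) sample_covariates(arm$n - arm$n_adol, "adult")
    covs_adol <- if (arm$n_adol > 0) sample_covariates(arm$n_adol, "adol")
    covs <- rbind(covs_adol, covs_adult)
    etas <- sample_etas(truth, arm$n)
    for (i in seq_len(arm$n)) {
      id <- id + 1
      eta_i <- etas[i, ]
      th_i <- individual_params(truth, etas = eta_i[names(eta_i) %in%
                                                      names(truth$omega2)[truth$omega2 > 0]],
                                cov_effects = cov_effects,
                                covariates = as.list(covs[i, ]))
      prof <- simulate_profile(th_i, reg, arm$sample_times)
      n_t <- length(arm$sample_times)
      obs <- data.frame(
        TIME = rep(arm$sample_times, 2),
        CMT = rep(c(2, 3), each = n_t),
        F = c(prof$parent, prof$metabolite)
      )
      obs$DV <- apply_residual_error(obs$F,
                                     ifelse(obs$CMT == 2, truth$sigma_p, truth$sigma_m))
      obs$DV <- pmax(obs$DV, 0)
      obs$LLOQ <- ifelse(obs$CMT == 2, uc$lloq_parent, uc$lloq_metabolite)
      obs$BLQ <- as.integer(obs$DV < obs$LLOQ)
      obs$DV[obs$BLQ == 1] <- NA
      sub <- rbind(
        data.frame(TIME = reg$time, AMT = reg$amount, EVID = 1, CMT = 1,
                   DV = NA, MDV = 1, BLQ = 0, LLOQ = NA),
        data.frame(TIME = obs$TIME, AMT = NA, EVID = 0, CMT = obs$CMT,
                   DV = obs$DV, MDV = as.integer(obs$BLQ == 1), BLQ = obs$BLQ,
                   LLOQ = obs$LLOQ)
      )
      # stable sort: observations at a dose time precede the dose (pre-dose)
      sub <- sub[order(sub$TIME, sub$EVID), ]
      sub <- cbind(ID = id, sub, covs[rep(i, nrow(sub)), , drop = FALSE])
      rownames(sub) <- NULL
      rows[[length(rows) + 1]] <- sub
    }
  }
  pk_dataset(do.call(rbind, rows))
}
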