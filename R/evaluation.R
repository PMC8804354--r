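# Model qualification: nonparametric bootstrap, prediction-corrected visual
# predictive check, and goodness-of-fit tabulation.

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original subject count, refits
#' each replicate from the original initial values, and summarizes the
#' converged replicates by median and 2.5th/97.5th percentiles.
#'
#' @param dataset a [pk_dataset()]
#' @param init initial [population_params()]
#' @param n_reps number of bootstrap replicates
#' @param seed integer seed
#' @param stage,bql,control passed to [fit_pk()]
#' @return object of class `pmpk_boot`: `estimates` (replicate x parameter),
#'   `converged` (logical), `summary` (median/2.5/97.5 over converged
#'   replicates), `fraction_converged`
#' @export
bootstrap_fit <- function(dataset, init, n_reps = 500, seed = 1,
                          stage = "parent", bql = "m1", control = list()) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  ds <- as.data.frame(dataset)
  ids <- unique(ds$ID)
  by_id <- split(ds, ds$ID)
  est <- NULL
  conv <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    boot_ds <- do.call(rbind, lapply(seq_along(pick), function(k) {
      d <- by_id[[as.character(pick[k])]]
      d$ID <- k
      d
    }))
    f <- tryCatch(fit_pk(pk_dataset(boot_ds), init, stage = stage, bql = bql,
                         control = control),
                  error = function(e) NULL)
    if (is.null(f)) {
      conv[r] <- FALSE
      row <- rep(NA_real_, length(est_names(init, stage)))
    } else {
      conv[r] <- f$convergence
      row <- f$full[est_names(init, stage)]
    }
    est <- rbind(est, row)
  }
  if (!any(conv)) stop("no bootstrap replicate converged")
  colnames(est) <- est_names(init, stage)
  rownames(est) <- NULL
  keep <- est[conv, , drop = FALSE]
  summ <- t(apply(keep, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                  na.rm = TRUE))
  colnames(summ) <- c("p2.5", "median", "p97.5")
  structure(list(estimates = est, converged = conv, summary = summ,
                 fraction_converged = mean(conv)),
            class = "pmpk_boot")
}

est_names <- function(init, stage) {
  if (stage == "parent") PARENT_FREE else COMBINED_FREE
}

#' @export
print.pmpk_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %.0f%% converged\n",
              length(x$converged), 100 * x$fraction_converged))
  print(round(x$summary, 4))
  invisible(x)
}

# nominal time after the most recent earlier dose (pre-dose convention);
# observations at or before the first dose map to 0
time_after_dose <- function(ds) {
  tad <- rep(NA_real_, nrow(ds))
  for (d in split(seq_len(nrow(ds)), ds$ID)) {
    dose_t <- ds$TIME[d][ds$EVID[d] == 1]
    for (i in d) {
      if (ds$EVID[i] == 1) next
      prev <- dose_t[dose_t < ds$TIME[i]]
      tad[i] <- if (length(prev)) ds$TIME[i] - max(prev) else 0
    }
  }
  tad
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the fitted model under the
#' original design, prediction-corrects observed and simulated values by the
#' binwise median population prediction
#' (`pcY = Y * median(PRED_bin) / PRED_individual`), and returns the observed
#' percentile curves with the simulated 95\% confidence band of each
#' percentile. Binning is by nominal time after dose; bins with fewer than
#' two observations are merged with their left neighbour (logged in
#' `merged_bins`). Records censored below the LLOQ are excluded on both the
#' observed and simulated side, as are records with a zero population
#' prediction (pre-first-dose samples).
#'
#' @param dataset a [pk_dataset()]
#' @param pop fitted [population_params()] (or a `pmpk_fit`'s `estimates`)
#' @param n_sim number of simulation replicates (>= 10)
#' @param bins optional numeric vector of nominal time-after-dose bin labels;
#'   default: the distinct nominal times present
#' @param seed integer seed
#' @param analyte `"parent"` or `"metabolite"`
#' @param quantiles percentile curves to assess
#' @param control see [conditional_neg2ll()]
#' @return object of class `pmpk_vpc` with elements `observed` (per-bin
#'   percentiles), `bands` (per-bin simulated CI for each percentile),
#'   `n_sim`, `merged_bins`
#' @export
pc_vpc <- function(dataset, pop, n_sim = 500, bins = NULL, seed = 1,
                   analyte = c("metabolite", "parent"),
                   quantiles = c(0.025, 0.5, 0.975), control = list()) {
  analyte <- match.arg(analyte)
  if (n_sim < 10) stop("n_sim must be at least 10 for meaningful bands")
  set.seed(seed)
  control <- default_fit_control(control)
  cmt <- if (analyte == "parent") 2 else 3
  sig <- if (analyte == "parent") pop$sigma_p else pop$sigma_m

  ds <- as.data.frame(dataset)
  obs_rows <- which(ds$EVID == 0)
  pred <- predict_dataset(dataset, pop, control = control)
  tad <- time_after_dose(ds)[obs_rows]

  sel0 <- ds$CMT[obs_rows] == cmt & pred > 0
  lloq <- ds$LLOQ[obs_rows]

  bin_of <- function(x, centers) {
    centers[max.col(-abs(outer(x, centers, "-")), ties.method = "first")]
  }
  if (is.null(bins)) bins <- sort(unique(tad[sel0]))
  bin_id <- bin_of(tad, bins)
  uncens <- sel0 & ds$BLQ[obs_rows] == 0

  # bins with no uncensored observation carry nothing to compare: drop them
  # (and their records) rather than contaminating a neighbour
  counts0 <- table(factor(bin_id[uncens], levels = bins))
  dropped <- bins[counts0 == 0]
  sel0 <- sel0 & !bin_id %in% dropped
  uncens <- uncens & sel0
  bins <- bins[counts0 > 0]

  # merge remaining sparse bins into their left neighbour
  merged <- character(0)
  repeat {
    counts <- table(factor(bin_id[uncens], levels = bins))
    small <- which(counts < 2)
    if (!length(small) || length(bins) == 1) break
    k <- small[1]
    tgt <- if (k > 1) k - 1 else 2
    merged <- c(merged, sprintf("%g -> %g", bins[k], bins[tgt]))
    bin_id[bin_id == bins[k]] <- bins[tgt]
    bins <- bins[-k]
  }

  # binwise median population prediction over the uncensored records
  med_pred_bin <- tapply(pred[uncens], bin_id[uncens], stats::median)
  pc_factor <- unname(med_pred_bin[as.character(bin_id)]) / pred

  obs_keep <- sel0 & ds$BLQ[obs_rows] == 0
  pc_obs <- ds$DV[obs_rows][obs_keep] * pc_factor[obs_keep]
  bin_obs <- bin_id[obs_keep]
  observed <- do.call(rbind, lapply(sort(unique(bin_obs)), function(b) {
    q <- stats::quantile(pc_obs[bin_obs == b], probs = quantiles, names = FALSE)
    data.frame(bin = b, quantile = quantiles, value = q, n = sum(bin_obs == b))
  }))

  # simulate replicates under the original design
  subjects <- split_subjects(dataset)
  sim_q <- array(NA_real_, c(n_sim, length(bins), length(quantiles)),
                 dimnames = list(NULL, as.character(bins), as.character(quantiles)))
  for (r in seq_len(n_sim)) {
    etas <- sample_etas(pop, length(subjects))
    f <- predict_dataset(dataset, pop, etas = etas, control = control)
    yv <- apply_residual_error(pmax(f, 0), sig)
    keep <- sel0 & yv >= lloq
    pcy <- yv[keep] * pc_factor[keep]
    bk <- bin_id[keep]
    for (bi in seq_along(bins)) {
      v <- pcy[bk == bins[bi]]
      if (length(v) >= 2) {
        sim_q[r, bi, ] <- stats::quantile(v, probs = quantiles, names = FALSE)
      }
    }
  }
  bands <- do.call(rbind, lapply(seq_along(bins), function(bi) {
    do.call(rbind, lapply(seq_along(quantiles), function(qi) {
      v <- stats::na.omit(sim_q[, bi, qi])
      data.frame(bin = bins[bi], quantile = quantiles[qi],
                 lower = stats::quantile(v, 0.025, names = FALSE),
                 upper = stats::quantile(v, 0.975, names = FALSE))
    }))
  }))
  structure(list(observed = observed, bands = bands, n_sim = n_sim,
                 analyte = analyte, merged_bins = merged,
                 dropped_bins = dropped),
            class = "pmpk_vpc")
}

#' Fraction of observed percentile points inside their simulated band
#' @param vpc a [pc_vpc()] result
#' @return scalar between 0 and 1
#' @export
vpc_coverage <- function(vpc) {
  m <- merge(vpc$observed, vpc$bands, by = c("bin", "quantile"))
  mean(m$value >= m$lower & m$value <= m$upper)
}

#' @export
print.pmpk_vpc <- function(x, ...) {
  cat(sprintf("pcVPC (%s, %d simulations, %d bins): %.0f%% of observed percentile points inside the 95%% bands\n",
              x$analyte, x$n_sim, length(unique(x$observed$bin)),
              100 * vpc_coverage(x)))
  invisible(x)
}

#' Plot a pcVPC
#' @param x a [pc_vpc()] result
#' @param ... unused
#' @export
plot.pmpk_vpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = x$bands,
                         ggplot2::aes(x = bin, ymin = lower, ymax = upper,
                                      group = factor(quantile)), alpha = 0.25) +
    ggplot2::geom_line(data = x$observed,
                       ggplot2::aes(x = bin, y = value,
                                    linetype = factor(quantile))) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nominal time after dose (h)",
                  y = "prediction-corrected concentration (ng/mL)",
                  linetype = "percentile")
}

#' Goodness-of-fit table
#'
#' Per uncensored observation: observed value, population prediction (eta 0),
#' individual prediction (conditional-mode eta) and the individual weighted
#' residual `IWRES = (DV - IPRED) / (sigma * IPRED)`. Censored records are
#' excluded (M1 convention).
#'
#' @param dataset a [pk_dataset()]
#' @param pop fitted [population_params()]
#' @param cov_effects optional covariate effects
#' @param control see [conditional_neg2ll()]
#' @return data.frame with columns `ID`, `TIME`, `TAD`, `CMT`, `DV`, `PRED`,
#'   `IPRED`, `IWRES`
#' @export
gof_table <- function(dataset, pop, cov_effects = NULL, control = list()) {
  ds <- as.data.frame(dataset)
  obs_rows <- which(ds$EVID == 0)
  pred <- predict_dataset(dataset, pop, cov_effects = cov_effects,
                          control = control)
  etas <- conditional_modes(dataset, pop, cov_effects = cov_effects,
                            control = control)
  ipred <- predict_dataset(dataset, pop, etas = etas,
                           cov_effects = cov_effects, control = control)
  tad <- time_after_dose(ds)[obs_rows]
  keep <- ds$BLQ[obs_rows] == 0
  sig <- ifelse(ds$CMT[obs_rows] == 2, pop$sigma_p, pop$sigma_m)
  out <- data.frame(ID = ds$ID[obs_rows], TIME = ds$TIME[obs_rows], TAD = tad,
                    CMT = ds$CMT[obs_rows], DV = ds$DV[obs_rows],
                    PRED = pred, IPRED = ipred,
                    IWRES = (ds$DV[obs_rows] - ipred) / (sig * pmax(ipred, 1e-10)))
  out[keep, , drop = FALSE]
}
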