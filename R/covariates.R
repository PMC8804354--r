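# Stepwise covariate model building: greedy forward inclusion at
# delta-OFV > 3.8 (p < 0.05, 1 df) and backward elimination keeping effects
# whose removal raises the OFV by > 6.6 (p < 0.01).

#' Enumerate candidate covariate effects
#'
#' Builds (parameter, covariate, form) candidates with power form for
#' continuous covariates (reference = dataset median) and fractional form
#' for 0/1 covariates.
#'
#' @param dataset a [pk_dataset()]
#' @param parameters structural parameters to screen (default parent CL/F, V/F)
#' @param covariates covariate columns to screen; default all present
#' @return list of [covariate_effect()]s with `theta2 = NA` (to estimate)
#' @export
candidate_effects <- function(dataset,
                              parameters = c("CL_F", "V_F"),
                              covariates = NULL) {
  ds <- as.data.frame(dataset)
  first <- ds[!duplicated(ds$ID), , drop = FALSE]
  if (is.null(covariates)) {
    covariates <- intersect(DATASET_COVARIATES, names(ds))
  }
  out <- list()
  for (p in parameters) {
    for (cv in covariates) {
      vals <- first[[cv]]
      if (all(is.na(vals))) next
      categorical <- all(stats::na.omit(vals) %in% c(0, 1))
      out[[length(out) + 1]] <- if (categorical) {
        covariate_effect(p, cv, "fractional")
      } else {
        covariate_effect(p, cv, "power",
                         reference = stats::median(vals, na.rm = TRUE))
      }
    }
  }
  out
}

effect_label <- function(ef) {
  paste0(ef$covariate, " (", ef$form, ") on ", ef$parameter)
}

#' Stepwise covariate selection
#'
#' Greedy forward inclusion: at each step every remaining candidate is added
#' to the current model and refitted; the candidate with the largest OFV drop
#' among those exceeding 3.8 enters. Backward elimination then removes, one
#' at a time, the retained effect whose removal increases the OFV the least,
#' while that increase is below 6.6. Candidate fits that fail to converge are
#' skipped and logged.
#'
#' @param dataset a [pk_dataset()]
#' @param init initial [population_params()]
#' @param candidates list of [covariate_effect()]s (see [candidate_effects()])
#' @param stage,bql,control passed to [fit_pk()]
#' @param max_forward cap on forward inclusions
#' @return list of class `pmpk_scm`: `selected` (list of effects with
#'   estimated theta2), `final_fit`, `trail` (decision log data.frame)
#' @export
stepwise_covariates <- function(dataset, init, candidates,
                                stage = "parent", bql = "m1",
                                control = list(), max_forward = Inf) {
  forward_cut <- 3.8
  backward_cut <- 6.6
  refit <- function(effects) {
    fit_pk(dataset, init, stage = stage, bql = bql,
           cov_effects = effects, control = control)
  }
  base_fit <- refit(NULL)
  current <- list()
  current_fit <- base_fit
  trail <- list()
  note <- function(phase, ef, delta, action) {
    trail[[length(trail) + 1]] <<- data.frame(
      phase = phase, effect = effect_label(ef), delta_ofv = delta,
      action = action, stringsAsFactors = FALSE)
  }
  remaining <- candidates
  while (length(remaining) && length(current) < max_forward) {
    deltas <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      f <- tryCatch(refit(c(current, remaining[k])), error = function(e) NULL)
      if (is.null(f) || !f$convergence) {
        note("forward", remaining[[k]], NA_real_, "skipped (non-converged)")
        next
      }
      deltas[k] <- current_fit$ofv - f$ofv
      fits[[k]] <- f
    }
    if (all(is.na(deltas)) || max(deltas, na.rm = TRUE) <= forward_cut) {
      for (k in seq_along(remaining)) {
        if (!is.na(deltas[k])) note("forward", remaining[[k]], deltas[k], "rejected")
      }
      break
    }
    best <- which.max(deltas)
    for (k in seq_along(remaining)) {
      if (is.na(deltas[k])) next
      note("forward", remaining[[k]], deltas[k],
           if (k == best) "included" else "not best")
    }
    current <- c(current, remaining[best])
    current_fit <- fits[[best]]
    remaining <- remaining[-best]
  }
  # backward elimination
  repeat {
    if (!length(current)) break
    increases <- rep(NA_real_, length(current))
    fits <- vector("list", length(current))
    for (k in seq_along(current)) {
      f <- tryCatch(refit(current[-k]), error = function(e) NULL)
      if (is.null(f) || !f$convergence) next
      increases[k] <- f$ofv - current_fit$ofv
      fits[[k]] <- f
    }
    if (all(is.na(increases))) break
    worst <- which.min(increases)
    if (increases[worst] < backward_cut) {
      note("backward", current[[worst]], increases[worst], "removed")
      current_fit <- fits[[worst]]
      current <- current[-worst]
    } else {
      for (k in seq_along(current)) {
        if (!is.na(increases[k])) note("backward", current[[k]], increases[k], "retained")
      }
      break
    }
  }
  selected <- current_fit$cov_effects
  structure(list(selected = selected, final_fit = current_fit,
                 base_fit = base_fit,
                 trail = if (length(trail)) do.call(rbind, trail) else
                   data.frame(phase = character(), effect = character(),
                              delta_ofv = numeric(), action = character())),
            class = "pmpk_scm")
}
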