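# End-to-end pipeline driver: synthesis -> sequential fit -> covariate
# screening -> bootstrap -> pcVPC -> pediatric simulation, under a single
# config with per-stage seed namespacing.

#' Default pipeline configuration
#'
#' @param seed master seed; each stage derives its own sub-seed so stages
#'   can be re-run in isolation
#' @return a named list understood by [run_pipeline()]
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    synth = list(enabled = TRUE),
    fit = list(enabled = TRUE, bql = "m1", try_m3 = FALSE, se = FALSE),
    stepwise = list(enabled = FALSE, parameters = c("CL_F", "V_F"),
                    covariates = c("WT")),
    bootstrap = list(enabled = FALSE, n_reps = 100, stage = "parent"),
    vpc = list(enabled = FALSE, n_sim = 200, analyte = "metabolite"),
    pediatric = list(enabled = TRUE, n = 1000, include_iiv = TRUE,
                     use_recommended_tiers = TRUE)
  )
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  if (is.null(config$seed) || !is.numeric(config$seed) ||
      length(config$seed) != 1 || config$seed != as.integer(config$seed)) {
    stop("config$seed must be a single integer")
  }
  stages <- c("synth", "fit", "stepwise", "bootstrap", "vpc", "pediatric")
  for (s in intersect(stages, names(config))) {
    if (!is.list(config[[s]])) stop("config$", s, " must be a list")
  }
  invisible(config)
}

stage_seed <- function(seed, stage) {
  offsets <- c(synth = 11, fit = 23, stepwise = 31, bootstrap = 41, vpc = 53,
               pediatric = 67)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the modelling pipeline end to end
#'
#' Executes the enabled stages in order on a supplied or synthesized dataset
#' and returns the artifact bundle. A stage failure aborts downstream stages
#' but preserves the partial bundle (with the error recorded).
#'
#' @param config see [default_run_config()]
#' @param dataset optional [pk_dataset()]; synthesized when NULL and
#'   `config$synth$enabled`
#' @param init initial [population_params()] (default packaged reference)
#' @return list of class `pmpk_run` with per-stage results, the per-stage
#'   seeds, and `errors`
#' @export
run_pipeline <- function(config = default_run_config(), dataset = NULL,
                         init = adult_reference_params()) {
  validate_run_config(config)
  bundle <- list(config = config, seeds = list(), errors = list())
  abort <- FALSE
  run_stage <- function(name, expr) {
    if (abort) return(NULL)
    tryCatch(expr, error = function(e) {
      bundle$errors[[name]] <<- conditionMessage(e)
      abort <<- TRUE
      NULL
    })
  }
  if (is.null(dataset) && isTRUE(config$synth$enabled)) {
    bundle$seeds$synth <- stage_seed(config$seed, "synth")
    dataset <- run_stage("synth", generate_dataset(seed = bundle$seeds$synth))
  }
  bundle$dataset <- dataset
  fit <- NULL
  if (isTRUE(config$fit$enabled) && !is.null(dataset)) {
    fit <- run_stage("fit", fit_sequential(dataset, init,
                                           bql = config$fit$bql %||% "m1",
                                           try_m3 = isTRUE(config$fit$try_m3),
                                           se = isTRUE(config$fit$se)))
    bundle$fit <- fit
  }
  if (isTRUE(config$stepwise$enabled) && !is.null(fit)) {
    bundle$stepwise <- run_stage("stepwise", {
      cands <- candidate_effects(dataset,
                                 parameters = config$stepwise$parameters,
                                 covariates = config$stepwise$covariates)
      stepwise_covariates(dataset, init, cands)
    })
  }
  if (isTRUE(config$bootstrap$enabled) && !is.null(dataset)) {
    bundle$seeds$bootstrap <- stage_seed(config$seed, "bootstrap")
    bundle$bootstrap <- run_stage("bootstrap",
      bootstrap_fit(dataset, init, n_reps = config$bootstrap$n_reps,
                    seed = bundle$seeds$bootstrap,
                    stage = config$bootstrap$stage %||% "parent"))
  }
  if (isTRUE(config$vpc$enabled) && !is.null(fit)) {
    bundle$seeds$vpc <- stage_seed(config$seed, "vpc")
    bundle$vpc <- run_stage("vpc",
      pc_vpc(dataset, fit$combined$estimates, n_sim = config$vpc$n_sim,
             seed = bundle$seeds$vpc,
             analyte = config$vpc$analyte %||% "metabolite"))
  }
  if (isTRUE(config$pediatric$enabled)) {
    bundle$seeds$pediatric <- stage_seed(config$seed, "pediatric")
    bundle$pediatric <- run_stage("pediatric", {
      pop_params <- if (!is.null(fit)) fit$combined$estimates else init
      vpop <- generate_virtual_population(n = config$pediatric$n %||% 1000,
                                          seed = bundle$seeds$pediatric)
      tiers <- recommended_tiers()
      doses <- tiers$dose[assign_tier(vpop$bsa, tiers)]
      metrics <- simulate_exposure(vpop, doses, pop_params,
                                   include_iiv = isTRUE(config$pediatric$include_iiv),
                                   seed = bundle$seeds$pediatric + 1L)
      list(population = vpop, tiers = tiers, metrics = metrics,
           summary = summarize_by_tier(metrics, tiers))
    })
  }
  structure(bundle, class = "pmpk_run")
}
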