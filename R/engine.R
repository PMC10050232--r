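ESTIMANDS <- c("LR", "HR", "SD", "RMST")

#' One Monte-Carlo replicate
#'
#' Generates the cohort(s) a replicate needs and computes every requested
#' contrast on them.  The comparative clinical-utility contrast is evaluated
#' on a biomarker-strategy trial and the experimental one on a
#' modified-biomarker-strategy trial; when both are requested, two trials are
#' simulated within the replicate under the same scenario (they share
#' parameters, not patients).  Subgroup and differential contrasts use the
#' scenario's own design.
#'
#' Randomness is fully determined by `(config$seed, index)`: each replicate
#' re-seeds its own stream, so replicates are reproducible independently of
#' execution order.  Estimation failures (e.g. separation) are recorded as
#' `NA` rows, not raised.
#'
#' @param config a [scenario_config()].
#' @param index replicate index (1-based).
#' @param requests list of [contrast_request()]s.
#' @return A data.frame with one row per request: `contrast`, `estimand`,
#'   `estimate`, `se`, `statistic`, `p_value`, `hr_reciprocal`, `estimable`.
#' @export
run_replicate <- function(config, index,
                          requests = default_requests(config)) {
  set_replicate_seed(config$seed, index)
  needs <- vapply(requests, function(rq) replicate_design(config, rq), "")
  cohorts <- list()
  for (d in unique(needs))            # fixed generation order: unique() order
    cohorts[[d]] <- generate_cohort(override_design(config, d))
  out <- lapply(seq_along(requests), function(i) {
    rq <- requests[[i]]
    fit <- tryCatch(estimate_contrast(cohorts[[needs[i]]], rq),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(contrast = rq$contrast, estimand = rq$estimand,
                 estimate = NA_real_, se = NA_real_, statistic = NA_real_,
                 p_value = NA_real_, hr_reciprocal = NA_real_,
                 estimable = FALSE)
    } else {
      data.frame(contrast = rq$contrast, estimand = rq$estimand,
                 estimate = fit$estimate, se = fit$se,
                 statistic = fit$statistic, p_value = fit$p_value,
                 hr_reciprocal = fit$hr_reciprocal %||% NA_real_,
                 estimable = TRUE)
    }
  })
  res <- do.call(rbind, out)
  res$replicate <- index
  res
}

replicate_design <- function(config, request) {
  switch(request$contrast,
    clinical_utility_comparative = "strategy",
    clinical_utility_experimental = "modified_strategy",
    config$design)
}

override_design <- function(config, design) {
  if (identical(config$design, design)) return(config)
  config$design <- design
  config
}

default_requests <- function(config) {
  contrasts <- switch(config$design,
    strategy = "clinical_utility_comparative",
    modified_strategy = "clinical_utility_experimental",
    enrichment = "subgroup_effect",
    stratified = c("subgroup_effect", "differential_effect"))
  out <- list()
  for (ct in contrasts) for (es in ESTIMANDS) {
    if (ct == "differential_effect" && es == "LR") next
    out[[length(out) + 1L]] <- contrast_request(ct, es)
  }
  out
}

#' Monte-Carlo operating characteristics of a scenario
#'
#' Replicates the trial `config$n_reps` times and aggregates, per (contrast,
#' estimand): the rejection rate of the two-sided test at level `alpha`, the
#' mean estimate, its empirical standard error, the bias against the analytic
#' truth from [true_contrast_value()], and Monte-Carlo standard errors for
#' the rejection rate and mean.  Non-estimable replicates are dropped from
#' the summaries with a logged count.
#'
#' @param config a [scenario_config()].
#' @param requests list of [contrast_request()]s.
#' @param reps number of replicates (default `config$n_reps`).
#' @return A data.frame of class `"pdt_oc"`, one row per (contrast, estimand).
#' @export
operating_characteristics <- function(config,
                                      requests = default_requests(config),
                                      reps = config$n_reps) {
  if (reps < 2L) stop("need at least 2 replicates")
  reps <- as.integer(reps)
  all <- do.call(rbind, lapply(seq_len(reps), run_replicate,
                               config = config, requests = requests))
  keys <- unique(all[c("contrast", "estimand")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- all[all$contrast == keys$contrast[i] &
                 all$estimand == keys$estimand[i], ]
    ok <- sub[sub$estimable, ]
    n_ok <- nrow(ok)
    if (n_ok == 0L) stop("no estimable replicates for ", keys$contrast[i],
                         " / ", keys$estimand[i])
    rej <- mean(ok$p_value < config$alpha)
    truth <- suppressWarnings(true_contrast_value(config, contrast_request(
      keys$contrast[i], keys$estimand[i])))
    mean_est <- mean(ok$estimate)
    data.frame(contrast = keys$contrast[i], estimand = keys$estimand[i],
               rejection_rate = rej,
               rejection_mc_se = sqrt(rej * (1 - rej) / n_ok),
               mean_estimate = mean_est,
               mean_hr_reciprocal = mean(ok$hr_reciprocal),
               empirical_se = stats::sd(ok$estimate),
               mean_mc_se = stats::sd(ok$estimate) / sqrt(n_ok),
               true_value = truth, bias = mean_est - truth,
               n_estimable = n_ok, n_reps = reps)
  })
  oc <- do.call(rbind, rows)
  structure(oc, class = c("pdt_oc", "data.frame"), alpha = config$alpha,
            replicates = all)
}

#' @export
print.pdt_oc <- function(x, digits = 3, ...) {
  cat(sprintf("Operating characteristics (%d replicates, alpha = %g)\n",
              x$n_reps[1], attr(x, "alpha")))
  print.data.frame(x[, c("contrast", "estimand", "rejection_rate",
                         "mean_estimate", "empirical_se", "true_value",
                         "bias", "n_estimable")],
                   digits = digits, row.names = FALSE)
  invisible(x)
}

#' Ideal-physician clinical-utility experiment over the scenario grid
#'
#' Runs the six-scenario grid comparing the experimental and comparative
#' clinical-utility contrasts under an ideal physician's choice (zero true
#' clinical utility): median survival for biomarker-positive patients on
#' treatment B takes 9, 12 and 21 months, crossed with biomarker prevalence
#' 0.25 and 0.50; medians for positives on A, negatives on B and negatives on
#' A are 9, 9 and 12 months.  For each scenario both a strategy trial
#' (comparative contrast) and a modified-strategy trial (experimental
#' contrast) are replicated, and rejection rates and mean estimates are
#' tabulated for the logrank, hazard-ratio, RMST and survival-difference
#' analyses.
#'
#' Arm-level hazard-ratio direction: `hr_mean_comp` is the mean of
#' `exp(b0)` from the directed-arm-indicator Cox model (a ratio of 1 under
#' the null, so direction-free), while `hr_mean_exp` is reported as the mean
#' reciprocal hazard ratio (randomized-over-directed hazard), the convention
#' under which a beneficial directed arm gives values above 1.  Both
#' directions are available in the per-scenario `pdt_oc` objects attached as
#' attribute `"oc"`.
#'
#' @param base_config scenario defaults; the grid overrides `medians["pos_B"]`
#'   and `prevalence` (and forces the ideal physician model).
#' @param reps replicates per scenario.
#' @param median_pos_B,prevalences grid margins.
#' @return A data.frame of class `"pdt_grid"`: columns `median_posB`,
#'   `prevalence`, then `<est>_reject_exp`, `<est>_reject_comp` and
#'   `<est>_mean_*` columns in the order LR, HR, RMST, SD, with Monte-Carlo
#'   standard errors of the rejection rates appended.
#' @export
utility_contrast_grid <- function(base_config = scenario_config(),
                              reps = base_config$n_reps,
                              median_pos_B = c(9, 12, 21),
                              prevalences = c(0.25, 0.50)) {
  stopifnot(inherits(base_config, "pdt_scenario"))
  requests <- c(lapply(ESTIMANDS, contrast_request,
                       contrast = "clinical_utility_experimental"),
                lapply(ESTIMANDS, contrast_request,
                       contrast = "clinical_utility_comparative"))
  grid <- expand.grid(median_posB = median_pos_B, prevalence = prevalences)
  grid <- grid[order(grid$median_posB, grid$prevalence), , drop = FALSE]
  ocs <- list()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$medians["pos_B"] <- grid$median_posB[i]
    cfg$prevalence <- grid$prevalence[i]
    cfg$physician_model <- physician_model("ideal")
    ## distinct but deterministic seed per scenario row
    cfg$seed <- replicate_seed(base_config$seed, 7919L * i)
    oc <- operating_characteristics(cfg, requests, reps = reps)
    ocs[[i]] <<- oc
    cell <- function(contrast, estimand, col) {
      oc[[col]][oc$contrast == contrast & oc$estimand == estimand]
    }
    row <- data.frame(median_posB = grid$median_posB[i],
                      prevalence = grid$prevalence[i])
    for (es in c("LR", "HR", "RMST", "SD")) {
      row[[paste0(tolower(es), "_reject_exp")]] <-
        cell("clinical_utility_experimental", es, "rejection_rate")
      row[[paste0(tolower(es), "_reject_comp")]] <-
        cell("clinical_utility_comparative", es, "rejection_rate")
      if (es != "LR") {
        mean_col_exp <- if (es == "HR") "mean_hr_reciprocal" else "mean_estimate"
        row[[paste0(tolower(es), "_mean_exp")]] <-
          cell("clinical_utility_experimental", es, mean_col_exp)
        row[[paste0(tolower(es), "_mean_comp")]] <-
          cell("clinical_utility_comparative", es, "mean_estimate")
      }
      row[[paste0(tolower(es), "_reject_exp_mcse")]] <-
        cell("clinical_utility_experimental", es, "rejection_mc_se")
      row[[paste0(tolower(es), "_reject_comp_mcse")]] <-
        cell("clinical_utility_comparative", es, "rejection_mc_se")
    }
    row
  })
  out <- do.call(rbind, rows)
  ## Table-2 column order first, MC SEs appended after
  mcse <- grep("_mcse$", names(out), value = TRUE)
  main <- setdiff(names(out), mcse)
  structure(out[c(main, mcse)], class = c("pdt_grid", "data.frame"),
            oc = ocs, reps = reps, seed = base_config$seed)
}
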