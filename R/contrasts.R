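#' Contrast request
#'
#' Pairs a contrast of interest with an estimand (and, where relevant, the
#' subgroup and horizon).  The logrank statistic tests equality of two whole
#' survival distributions and is therefore not available for the differential
#' treatment effect, whose null leaves the two subgroup-specific effects free.
#'
#' @param contrast one of `"subgroup_effect"`, `"differential_effect"`,
#'   `"clinical_utility_comparative"`, `"clinical_utility_experimental"`.
#' @param estimand `"LR"` (logrank test), `"HR"` (Cox hazard ratio), `"SD"`
#'   (survival-probability difference at `horizon`) or `"RMST"` (restricted
#'   mean survival time difference at `horizon`).
#' @param subgroup 0 or 1; only for `subgroup_effect`.
#' @param horizon months; only for `"SD"`/`"RMST"`.  `NULL` defers to the
#'   scenario's `horizon_t`.
#' @return An object of class `"contrast_request"`.
#' @export
contrast_request <- function(contrast = CONTRAST_KINDS,
                             estimand = c("HR", "LR", "SD", "RMST"),
                             subgroup = 1L, horizon = NULL) {
  contrast <- match.arg(contrast)
  estimand <- match.arg(estimand)
  if (contrast == "differential_effect" && estimand == "LR")
    stop("the logrank statistic cannot test a differential treatment effect: ",
         "its null is equality of all four survival distributions")
  if (!subgroup %in% c(0L, 1L)) stop("`subgroup` must be 0 or 1")
  structure(list(contrast = contrast, estimand = estimand,
                 subgroup = as.integer(subgroup), horizon = horizon),
            class = "contrast_request")
}

identifiability_error <- function(contrast, design) {
  msg <- sprintf(paste0(
    "contrast '%s' is not identifiable from the %s design without ",
    "additional assumptions (see identifiable_contrasts())"), contrast, design)
  stop(errorCondition(msg, class = c("pdt_identifiability_error", "error")))
}

#' Estimate a contrast from a trial cohort
#'
#' Routes a (design, contrast, estimand) triple to the correct analysis and
#' refuses non-identifiable requests:
#' \itemize{
#'   \item subgroup treatment effect: two-group comparison of B vs A restricted
#'     to the requested marker subgroup (Cox treatment model / pseudo-value
#'     regression on the treatment indicator / logrank);
#'   \item differential treatment effect: treatment-by-marker interaction
#'     coefficient (Cox) or interaction pseudo-value coefficient;
#'   \item clinical utility, comparative: biomarker-directed vs
#'     physician's-choice arm of a strategy trial;
#'   \item clinical utility, experimental: biomarker-directed vs randomized
#'     arm of a modified-strategy trial.
#' }
#' Patients whose marker was not assayed are excluded from marker-dependent
#' analyses (they carry no marker information for the analyst); arm-level
#' analyses use all patients.
#'
#' The experimental-utility estimator regresses on the arm indicator and so
#' needs a cohort that actually contains a biomarker-directed and a randomized
#' arm, i.e. a modified-strategy trial.  A stratified trial identifies the
#' contrast in principle (all four cell distributions are estimable) but not
#' via this arm-level regression; requesting it on a stratified cohort is an
#' error directing the user to simulate the modified design.
#'
#' @param cohort a [generate_cohort()] cohort (or any data.frame in the same
#'   dialect carrying a `design` attribute).
#' @param request a [contrast_request()].
#' @return A `"pdt_fit"`; for `"HR"` fits on arm contrasts the reciprocal
#'   hazard ratio is attached as `$hr_reciprocal` (direction conventions for
#'   arm-level hazard ratios differ across the literature).
#' @export
estimate_contrast <- function(cohort, request) {
  stopifnot(inherits(request, "contrast_request"))
  design <- attr(cohort, "design")
  if (is.null(design)) stop("cohort carries no design attribute")
  spec <- as_design_spec(attr(cohort, "config"))
  ok <- withCallingHandlers(identifiable_contrasts(spec),
                            warning = function(w) invokeRestart("muffleWarning"))
  if (!request$contrast %in% ok) identifiability_error(request$contrast, design)
  horizon <- request$horizon %||% attr(cohort, "config")$horizon_t

  fit <- switch(request$contrast,
    subgroup_effect = {
      if (design == "enrichment" && request$subgroup == 0L)
        identifiability_error("subgroup_effect (negatives)", design)
      d <- cohort[cohort$marker_measured & cohort$marker == request$subgroup, ]
      if (nrow(d) < 2L) stop("subgroup has fewer than 2 marker-measured patients")
      two_group_fit(d$time, d$event, d$treatment == "B", request$estimand,
                    horizon, indicator_name = "trtB")
    },
    differential_effect = {
      d <- cohort[cohort$marker_measured, ]
      interaction_fit(d, request$estimand, horizon)
    },
    clinical_utility_comparative = {
      two_group_fit(cohort$time, cohort$event, cohort$arm == "directed",
                    request$estimand, horizon, indicator_name = "directed")
    },
    clinical_utility_experimental = {
      if (design != "modified_strategy")
        stop("experimental clinical utility is estimated from the arm ",
             "indicator of a modified biomarker-strategy trial; simulate ",
             "that design (a ", design, " cohort has no directed arm)")
      two_group_fit(cohort$time, cohort$event, cohort$arm == "directed",
                    request$estimand, horizon, indicator_name = "directed")
    })
  fit$contrast <- request$contrast
  fit
}

two_group_fit <- function(times, events, indicator, estimand, horizon,
                          indicator_name) {
  ind <- as.integer(indicator)
  switch(estimand,
    LR = logrank_test(times, events, ind),
    HR = {
      f <- if (indicator_name == "directed")
        cox_fit(times, events, arm = ifelse(ind == 1L, "directed", "other"),
                model = "arm")
      else
        cox_fit(times, events, treatment = ifelse(ind == 1L, "B", "A"),
                model = "treatment")
      f$hr_reciprocal <- 1 / f$estimate
      f
    },
    {
      fun <- if (estimand == "SD") "survival" else "rmst"
      ps <- pseudo_observations(times, events, fun, horizon)
      Z <- cbind(intercept = 1, ind)
      colnames(Z)[2L] <- indicator_name
      glm_identity(ps, Z, indicator_name)
    })
}

interaction_fit <- function(d, estimand, horizon) {
  if (estimand == "HR")
    return(cox_fit(d$time, d$event, treatment = d$treatment,
                   marker = d$marker, model = "interaction"))
  fun <- if (estimand == "SD") "survival" else "rmst"
  ps <- pseudo_observations(d$time, d$event, fun, horizon)
  tB <- as.integer(d$treatment == "B")
  Z <- cbind(intercept = 1, trtB = tB, marker = d$marker,
             trtB_marker = tB * d$marker)
  glm_identity(ps, Z, "trtB_marker")
}

## ---- analytic truth ------------------------------------------------------

exp_surv <- function(rate, t) exp(-rate * t)
exp_rmst <- function(rate, t) (1 - exp(-rate * t)) / rate

arm_mixture <- function(config, pB_pos, pB_neg) {
  ## component weights/rates of the arm's event-time mixture
  p <- config$prevalence
  rates <- median_to_rate(config$medians)
  w <- c(pos_B = p * pB_pos, pos_A = p * (1 - pB_pos),
         neg_B = (1 - p) * pB_neg, neg_A = (1 - p) * (1 - pB_neg))
  list(w = w, rates = rates[names(w)])
}

mixture_surv <- function(mix, t) sum(mix$w * exp_surv(mix$rates, t))
mixture_rmst <- function(mix, t) sum(mix$w * exp_rmst(mix$rates, t))

#' Analytic (generative-truth) value of a contrast
#'
#' Closed-form value of the requested contrast under the scenario's
#' exponential generative model, for bias assessment without simulation.
#' Arm-level survival laws are mixtures of exponentials over the marker and
#' treatment distribution of the arm; SD and RMST contrasts are linear in the
#' survival function and so have exact mixture expressions.  A single hazard
#' ratio only exists when the two compared laws are proportional; for
#' arm-level mixtures this holds exactly when the two arms share the same
#' (marker, treatment) law — then HR = 1 — and otherwise `NA` is returned
#' with a warning (except within-subgroup contrasts, which compare plain
#' exponentials).
#'
#' Signs follow the fitted models: SD/RMST contrasts are (indicator = 1 group)
#' minus (indicator = 0 group), i.e. B minus A, or biomarker-directed arm
#' minus comparison arm; the HR multiplies the hazard of the indicator group.
#'
#' @param config a [scenario_config()].
#' @param request a [contrast_request()].
#' @return A single number (HR on the ratio scale; SD as a probability
#'   difference; RMST in months; LR has no magnitude: 0 when the two laws are
#'   identical, otherwise `NA`).
#' @export
true_contrast_value <- function(config, request) {
  stopifnot(inherits(config, "pdt_scenario"),
            inherits(request, "contrast_request"))
  t <- request$horizon %||% config$horizon_t
  rates <- median_to_rate(config$medians)
  pm <- config$physician_model

  subgroup_value <- function(m, estimand) {
    rB <- rates[[median_key(m, "B")]]
    rA <- rates[[median_key(m, "A")]]
    switch(estimand,
      HR = rB / rA,
      SD = exp_surv(rB, t) - exp_surv(rA, t),
      RMST = exp_rmst(rB, t) - exp_rmst(rA, t),
      LR = if (rB == rA) 0 else NA_real_)
  }

  arm_pair <- function(mix1, mix0, estimand) {
    same <- isTRUE(all.equal(mix1$w, mix0$w)) &&
      isTRUE(all.equal(mix1$rates, mix0$rates))
    switch(estimand,
      HR = if (same) 1 else {
        warning("arm-level mixture hazards are not proportional; ",
                "no single true HR exists")
        NA_real_
      },
      SD = mixture_surv(mix1, t) - mixture_surv(mix0, t),
      RMST = mixture_rmst(mix1, t) - mixture_rmst(mix0, t),
      LR = if (same) 0 else NA_real_)
  }

  switch(request$contrast,
    subgroup_effect = subgroup_value(request$subgroup, request$estimand),
    differential_effect = switch(request$estimand,
      HR = subgroup_value(1L, "HR") / subgroup_value(0L, "HR"),
      SD = subgroup_value(1L, "SD") - subgroup_value(0L, "SD"),
      RMST = subgroup_value(1L, "RMST") - subgroup_value(0L, "RMST")),
    clinical_utility_comparative = arm_pair(
      arm_mixture(config, 1, 0),
      arm_mixture(config, pm$p_B_given_pos, pm$p_B_given_neg),
      request$estimand),
    clinical_utility_experimental = arm_pair(
      arm_mixture(config, 1, 0),
      arm_mixture(config, config$r_pos2, config$r_neg2),
      request$estimand))
}
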