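#' Physician-choice model
#'
#' Describes how a physician, blinded to the biomarker result, would assign
#' treatment in the physician's-choice arm of a biomarker-strategy trial.  The
#' physician may nevertheless act on routinely collected patient data that
#' correlate with the marker; the model therefore conditions on the (latent)
#' marker value.
#'
#' The `"ideal"` kind describes a physician whose choice always coincides with
#' the biomarker-directed rule (treat positives with B, negatives with A), the
#' situation in which a marker has perfect clinical validity but zero clinical
#' utility.  It is equivalent to `"bernoulli"` with `p_B_given_pos = 1` and
#' `p_B_given_neg = 0`.
#'
#' @param kind `"ideal"` or `"bernoulli"`.
#' @param p_B_given_pos,p_B_given_neg probability that the physician prescribes
#'   treatment B to a biomarker-positive (resp. -negative) patient; used only by
#'   the `"bernoulli"` kind.
#' @return An object of class `"physician_model"`.
#' @export
physician_model <- function(kind = c("ideal", "bernoulli"),
                            p_B_given_pos = 1, p_B_given_neg = 0) {
  kind <- match.arg(kind)
  if (kind == "ideal") {
    p_B_given_pos <- 1
    p_B_given_neg <- 0
  }
  stopifnot(is.numeric(p_B_given_pos), length(p_B_given_pos) == 1L,
            p_B_given_pos >= 0, p_B_given_pos <= 1,
            is.numeric(p_B_given_neg), length(p_B_given_neg) == 1L,
            p_B_given_neg >= 0, p_B_given_neg <= 1)
  structure(list(kind = kind,
                 p_B_given_pos = p_B_given_pos,
                 p_B_given_neg = p_B_given_neg),
            class = "physician_model")
}

#' Scenario configuration for a prediction-driven trial simulation
#'
#' Bundles the full generative and analytic specification of one simulation
#' scenario: the biomarker prevalence, the exponential median survival times
#' (months) for the four cells defined by marker status and treatment, the
#' design and its randomization probabilities, the physician-choice model,
#' accrual and administrative censoring, the horizon at which survival
#' difference and restricted mean survival time are evaluated, the significance
#' level and the replication count.
#'
#' @param prevalence probability that a patient is biomarker positive (M = 1).
#' @param medians named numeric vector (or list) with elements `pos_A`,
#'   `pos_B`, `neg_A`, `neg_B`: median survival in months for each
#'   (marker, treatment) cell.  All must be positive.
#' @param n_per_arm patients per arm; total enrolment is `2 * n_per_arm` with
#'   individual-level randomization (arm sizes are binomial, not blocked).
#' @param design one of `"enrichment"`, `"stratified"`, `"strategy"`,
#'   `"modified_strategy"`.
#' @param r_strat probability of the biomarker-directed arm in the strategy and
#'   modified-strategy designs.
#' @param r_pos1,r_neg1 probability of treatment B for positives/negatives in
#'   the stratified (and enrichment, via `r_pos1`) design.
#' @param r_pos2,r_neg2 probability of treatment B within the randomized arm of
#'   the modified-strategy design.
#' @param test_marker_in_randomized_arm is the biomarker assayed in the
#'   randomized arm of the modified-strategy design?
#' @param physician_model a [physician_model()].
#' @param accrual_duration length of the uniform accrual window in months;
#'   `0` enters everyone at calendar time zero.
#' @param admin_censor_time calendar time of analysis (months); follow-up is
#'   administratively censored at `admin_censor_time - entry_time`.
#' @param horizon_t horizon (months) for survival-difference and RMST
#'   estimands; must not exceed `admin_censor_time`.
#' @param alpha two-sided significance level.
#' @param n_reps Monte-Carlo replicates for operating characteristics.
#' @param seed base seed; each replicate derives its own stream from it.
#' @return An object of class `"pdt_scenario"`.
#' @examples
#' cfg <- scenario_config(prevalence = 0.25,
#'                        medians = c(pos_A = 9, pos_B = 9, neg_A = 12, neg_B = 9))
#' @export
scenario_config <- function(prevalence = 0.5,
                            medians = c(pos_A = 9, pos_B = 9,
                                        neg_A = 12, neg_B = 9),
                            n_per_arm = 500L,
                            design = c("strategy", "enrichment",
                                       "stratified", "modified_strategy"),
                            r_strat = 0.5, r_pos1 = 0.5, r_neg1 = 0.5,
                            r_pos2 = 0.5, r_neg2 = 0.5,
                            test_marker_in_randomized_arm = TRUE,
                            physician_model = pdtrials::physician_model("ideal"),
                            accrual_duration = 0,
                            admin_censor_time = 60,
                            horizon_t = 36,
                            alpha = 0.05,
                            n_reps = 1000L,
                            seed = 1L) {
  design <- match.arg(design)
  medians <- unlist(medians)
  needed <- c("pos_A", "pos_B", "neg_A", "neg_B")
  if (!all(needed %in% names(medians)))
    stop("`medians` must provide pos_A, pos_B, neg_A and neg_B")
  medians <- medians[needed]
  if (any(!is.finite(medians)) || any(medians <= 0))
    stop("all median survival times must be positive and finite")
  probs <- c(prevalence = prevalence, r_strat = r_strat, r_pos1 = r_pos1,
             r_neg1 = r_neg1, r_pos2 = r_pos2, r_neg2 = r_neg2,
             alpha = alpha)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities out of [0,1]: ", paste(names(probs)[bad], collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)")
  n_per_arm <- as.integer(n_per_arm)
  if (is.na(n_per_arm) || n_per_arm < 2L) stop("`n_per_arm` must be >= 2")
  if (!inherits(physician_model, "physician_model"))
    stop("`physician_model` must be built with physician_model()")
  if (accrual_duration < 0) stop("`accrual_duration` must be >= 0")
  if (admin_censor_time <= 0) stop("`admin_censor_time` must be > 0")
  if (accrual_duration >= admin_censor_time)
    stop("accrual must finish before the analysis time")
  if (horizon_t <= 0 || horizon_t > admin_censor_time)
    stop("`horizon_t` must lie in (0, admin_censor_time]")
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("`n_reps` must be >= 1")
  structure(list(prevalence = prevalence, medians = medians,
                 n_per_arm = n_per_arm, design = design,
                 r_strat = r_strat, r_pos1 = r_pos1, r_neg1 = r_neg1,
                 r_pos2 = r_pos2, r_neg2 = r_neg2,
                 test_marker_in_randomized_arm =
                   isTRUE(test_marker_in_randomized_arm),
                 physician_model = physician_model,
                 accrual_duration = accrual_duration,
                 admin_censor_time = admin_censor_time,
                 horizon_t = horizon_t, alpha = alpha,
                 n_reps = n_reps, seed = as.integer(seed)),
            class = "pdt_scenario")
}

#' @export
print.pdt_scenario <- function(x, ...) {
  cat("Prediction-driven trial scenario (", x$design, " design)\n", sep = "")
  cat(sprintf("  prevalence %.2f; n_per_arm %d; medians [months]: %s\n",
              x$prevalence, x$n_per_arm,
              paste(names(x$medians), x$medians, sep = "=", collapse = " ")))
  cat(sprintf("  physician model: %s; admin censor %g mo; horizon t = %g mo\n",
              x$physician_model$kind, x$admin_censor_time, x$horizon_t))
  cat(sprintf("  alpha %.3f; %d replicates; seed %d\n",
              x$alpha, x$n_reps, x$seed))
  invisible(x)
}

#' Exponential rate from a median survival time
#'
#' The exponential distribution with rate \eqn{\lambda} has median
#' \eqn{\log(2)/\lambda}; event times for each (marker, treatment) cell are
#' drawn from the exponential with the rate matching that cell's median.
#'
#' @param median median survival time in months (> 0).
#' @return Event rate per month.
#' @examples
#' median_to_rate(12)   # log(2) / 12
#' @export
median_to_rate <- function(median) {
  if (any(!is.finite(median)) || any(median <= 0))
    stop("`median` must be positive and finite")
  log(2) / median
}

median_key <- function(marker, treatment) {
  paste(ifelse(marker == 1L, "pos", "neg"), treatment, sep = "_")
}

#' Draw a latent event time for one (marker, treatment) cell
#'
#' Event times are independent exponential draws whose median is set per cell
#' by the scenario; survival is independent of everything else by construction.
#'
#' @param marker 0/1 biomarker status (vectorized).
#' @param treatment `"A"`/`"B"` (vectorized, recycled with `marker`).
#' @param config a [scenario_config()].
#' @return Vector of event times in months.
#' @export
draw_survival_time <- function(marker, treatment, config) {
  key <- median_key(marker, treatment)
  med <- config$medians[key]
  if (any(is.na(med)))
    stop("no median configured for cell(s): ", paste(unique(key[is.na(med)]), collapse = ", "))
  stats::rexp(length(key), rate = median_to_rate(unname(med)))
}

#' Physician's treatment choice
#'
#' @param marker 0/1 biomarker status (vectorized).
#' @param model a [physician_model()].
#' @return Character vector of `"A"`/`"B"`.
#' @export
physician_choice <- function(marker, model) {
  stopifnot(inherits(model, "physician_model"))
  p <- ifelse(marker == 1L, model$p_B_given_pos, model$p_B_given_neg)
  ifelse(stats::runif(length(marker)) < p, "B", "A")
}

#' Apply administrative censoring
#'
#' Follow-up ends at the analysis calendar time `admin_censor_time`; a patient
#' entering at `entry_time` is observed for at most
#' `admin_censor_time - entry_time` months.  Censoring therefore depends only
#' on the accrual calendar, never on marker, treatment or the event process
#' (completely independent censoring).
#'
#' @param event_time latent event time(s), months from entry.
#' @param entry_time entry (accrual) time(s), months; must precede the
#'   analysis time.
#' @param admin_censor_time calendar analysis time, months.
#' @return A list with `time` (observed, months from entry) and `event` (0/1).
#' @export
apply_censoring <- function(event_time, entry_time, admin_censor_time) {
  if (any(entry_time >= admin_censor_time))
    stop("entry at or after the analysis time: patient would contribute no follow-up")
  fu <- admin_censor_time - entry_time
  event <- as.integer(event_time <= fu)
  list(time = pmin(event_time, fu), event = event)
}

#' Read a scenario configuration from YAML or JSON
#'
#' Keys mirror the arguments of [scenario_config()]; `medians` is a mapping
#' with keys `pos_A`, `pos_B`, `neg_A`, `neg_B`, and `physician_model` a
#' mapping with `kind` and (for the bernoulli kind) `p_B_given_pos` /
#' `p_B_given_neg`.
#'
#' @param path file path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return A [scenario_config()] object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("malformed config: top level must be a mapping")
  if (!is.null(raw$physician_model)) {
    pm <- raw$physician_model
    raw$physician_model <- physician_model(
      kind = pm$kind %||% "ideal",
      p_B_given_pos = pm$p_B_given_pos %||% 1,
      p_B_given_neg = pm$p_B_given_neg %||% 0)
  }
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(scenario_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Order-independent replicate streams: each replicate re-seeds the global RNG
## with a value derived from (base seed, replicate index) so any subset of
## replicates can be regenerated in isolation.
replicate_seed <- function(seed, index) {
  as.integer((as.double(seed) + 999983 * as.double(index)) %% 2147483647)
}

set_replicate_seed <- function(seed, index) {
  set.seed(replicate_seed(seed, index), kind = "Mersenne-Twister")
}
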