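#' Generate one trial cohort
#'
#' Simulates a full patient-level dataset for one trial under the scenario's
#' design: biomarker status is Bernoulli(prevalence); arm and treatment follow
#' the design's randomization (see [design_assign()]); latent event times are
#' exponential with the cell-specific median; entry times are uniform on
#' `[0, accrual_duration]`; follow-up is administratively censored at the
#' analysis calendar time.
#'
#' Total enrolment is `2 * n_per_arm`.  Under the enrichment design, screening
#' continues (marker draws Bernoulli(prevalence)) until `2 * n_per_arm`
#' positives are found; the number screened is recorded in attribute
#' `n_screened`.
#'
#' In the physician arm of the strategy design the marker is used to generate
#' outcomes (it is a patient characteristic) but is never assayed; exported
#' data mark it unmeasured.  The returned data.frame keeps the latent value in
#' `marker` and the information set in `marker_measured`.
#'
#' @param config a [scenario_config()].  The caller is responsible for seeding
#'   the RNG (see [run_replicate()] for the per-replicate convention).
#' @return A data.frame of class `"pdt_cohort"` with columns `id`, `arm`,
#'   `marker`, `marker_measured`, `treatment`, `entry_time`, `event_time`
#'   (latent), `time` (observed), `event`; attributes `design`, `config`,
#'   and (enrichment) `n_screened`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "pdt_scenario"))
  n <- 2L * config$n_per_arm
  spec <- as_design_spec(config)

  if (config$design == "enrichment") {
    if (config$prevalence <= 0)
      stop("enrichment design needs a positive prevalence")
    marker <- integer(0)
    n_screened <- 0L
    while (length(marker) < n) {
      batch <- stats::rbinom(max(n, 64L), 1L, config$prevalence)
      n_screened <- n_screened + length(batch)
      keep <- which(batch == 1L)
      excess <- length(marker) + length(keep) - n
      if (excess > 0) {
        keep <- keep[seq_len(length(keep) - excess)]
        # uncounted tail of the batch was never screened
        n_screened <- n_screened - (length(batch) - max(keep))
      }
      marker <- c(marker, batch[keep])
    }
  } else {
    marker <- stats::rbinom(n, 1L, config$prevalence)
    n_screened <- n
  }

  asg <- design_assign(marker, spec, config$physician_model)
  entry <- if (config$accrual_duration > 0)
    stats::runif(n, 0, config$accrual_duration) else rep(0, n)
  event_time <- draw_survival_time(marker, asg$treatment, config)
  obs <- apply_censoring(event_time, entry, config$admin_censor_time)

  out <- data.frame(id = seq_len(n), arm = asg$arm, marker = marker,
                    marker_measured = asg$marker_measured,
                    treatment = asg$treatment, entry_time = entry,
                    event_time = event_time, time = obs$time,
                    event = obs$event)
  structure(out, design = config$design, config = config,
            n_screened = n_screened,
            class = c("pdt_cohort", "data.frame"))
}

#' Write / read a cohort as CSV
#'
#' The on-disk dialect has header `id,arm,marker,treatment,entry_time,time,
#' event`; `marker` is written as the empty string when it was not measured in
#' the trial (e.g. the physician arm of a strategy design).  Latent columns
#' (`event_time`, true `marker` where unmeasured) are deliberately not
#' exported: the file reflects the information set of the trial analyst.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param path output file.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   data.frame in the same dialect (`marker` is `NA` where unmeasured).
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(id = cohort$id, arm = cohort$arm,
                    marker = ifelse(cohort$marker_measured,
                                    as.character(cohort$marker), ""),
                    treatment = cohort$treatment,
                    entry_time = cohort$entry_time,
                    time = cohort$time, event = cohort$event)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(marker = "character"))
  df$marker_measured <- df$marker != ""
  df$marker <- ifelse(df$marker_measured, as.integer(df$marker), NA_integer_)
  df
}

#' @export
print.pdt_cohort <- function(x, ...) {
  cat(sprintf("Trial cohort: %d patients, %s design\n", nrow(x),
              attr(x, "design")))
  tab <- table(arm = x$arm, treatment = x$treatment)
  print(tab)
  cat(sprintf("events: %d / %d observed\n", sum(x$event), nrow(x)))
  invisible(x)
}
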