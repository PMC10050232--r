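## Arm labels are fixed strings shared by the generator, the estimators and the
## exported CSV dialect: "A"/"B" (enrichment, stratified), "directed"/
## "physician" (strategy) and "directed"/"randomized" (modified strategy).

CONTRAST_KINDS <- c("subgroup_effect", "differential_effect",
                    "clinical_utility_comparative",
                    "clinical_utility_experimental")

#' Design specification
#'
#' Randomization structure for one of the four prediction-driven designs.
#' Fields irrelevant to the chosen `kind` are ignored.
#'
#' @param kind `"enrichment"`, `"stratified"`, `"strategy"` or
#'   `"modified_strategy"`.
#' @param r_pos1,r_neg1 probability of treatment B for positive/negative
#'   patients under individual randomization (enrichment uses `r_pos1`).
#' @param r_strat probability of the biomarker-directed arm (strategy and
#'   modified designs).
#' @param r_pos2,r_neg2 probability of treatment B within the randomized arm
#'   of the modified design.
#' @param test_marker_in_randomized_arm is the biomarker assayed in the
#'   randomized arm of the modified design?
#' @return An object of class `"design_spec"`.
#' @export
design_spec <- function(kind = c("enrichment", "stratified", "strategy",
                                 "modified_strategy"),
                        r_pos1 = 0.5, r_neg1 = 0.5, r_strat = 0.5,
                        r_pos2 = 0.5, r_neg2 = 0.5,
                        test_marker_in_randomized_arm = TRUE) {
  kind <- match.arg(kind)
  p <- c(r_pos1 = r_pos1, r_neg1 = r_neg1, r_strat = r_strat,
         r_pos2 = r_pos2, r_neg2 = r_neg2)
  if (any(p < 0 | p > 1))
    stop("randomization probabilities must lie in [0,1]")
  structure(c(as.list(p),
              list(kind = kind,
                   test_marker_in_randomized_arm =
                     isTRUE(test_marker_in_randomized_arm))),
            class = "design_spec")
}

as_design_spec <- function(config) {
  design_spec(kind = config$design, r_pos1 = config$r_pos1,
              r_neg1 = config$r_neg1, r_strat = config$r_strat,
              r_pos2 = config$r_pos2, r_neg2 = config$r_neg2,
              test_marker_in_randomized_arm =
                config$test_marker_in_randomized_arm)
}

#' Assign arm and treatment under a prediction-driven design
#'
#' Vectorized randomization for a batch of patients.  Under the enrichment
#' design only biomarker-positive patients may be enrolled; under the strategy
#' design patients are randomized between a biomarker-directed arm (treatment
#' follows the rule: positives get B, negatives get A) and a physician's-choice
#' arm, where the marker result is never assayed; under the modified design the
#' comparison arm is instead fully randomized.
#'
#' @param marker integer vector of 0/1 biomarker statuses.
#' @param design a [design_spec()].
#' @param physician a [physician_model()]; needed for the strategy design.
#' @return A data.frame with columns `arm`, `treatment` and `marker_measured`.
#' @export
design_assign <- function(marker, design, physician = physician_model("ideal")) {
  stopifnot(inherits(design, "design_spec"))
  n <- length(marker)
  directed_rule <- ifelse(marker == 1L, "B", "A")
  switch(design$kind,
    enrichment = {
      if (any(marker != 1L))
        stop("enrichment design enrolls biomarker-positive patients only")
      trt <- ifelse(stats::runif(n) < design$r_pos1, "B", "A")
      data.frame(arm = trt, treatment = trt, marker_measured = TRUE)
    },
    stratified = {
      pB <- ifelse(marker == 1L, design$r_pos1, design$r_neg1)
      trt <- ifelse(stats::runif(n) < pB, "B", "A")
      data.frame(arm = trt, treatment = trt, marker_measured = TRUE)
    },
    strategy = {
      directed <- stats::runif(n) < design$r_strat
      trt <- ifelse(directed, directed_rule, physician_choice(marker, physician))
      data.frame(arm = ifelse(directed, "directed", "physician"),
                 treatment = trt,
                 marker_measured = directed)
    },
    modified_strategy = {
      directed <- stats::runif(n) < design$r_strat
      pB <- ifelse(marker == 1L, design$r_pos2, design$r_neg2)
      trt <- ifelse(directed, directed_rule,
                    ifelse(stats::runif(n) < pB, "B", "A"))
      data.frame(arm = ifelse(directed, "directed", "randomized"),
                 treatment = trt,
                 marker_measured = directed |
                   design$test_marker_in_randomized_arm)
    })
}

#' Which contrasts can a design estimate without extra assumptions?
#'
#' Reproduces the identifiability logic of the four designs: randomization
#' within marker strata identifies within-subgroup treatment effects (and so
#' their difference), whereas only randomization against a physician's-choice
#' arm identifies the comparative form of clinical utility.  The experimental
#' form (biomarker-directed versus randomized assignment) is identified
#' whenever both a directed and a randomized assignment distribution are
#' observed or reconstructible.
#'
#' For the modified design without marker testing in the randomized arm,
#' within-subgroup contrasts are lost; the directed-vs-randomized (experimental
#' utility) comparison remains directly observed at the arm level and is
#' reported with a warning, since arm-level comparison is the only analysis
#' that design supports.
#'
#' @param design a [design_spec()].
#' @return Character vector, a subset of
#'   `c("subgroup_effect", "differential_effect",
#'     "clinical_utility_comparative", "clinical_utility_experimental")`.
#'   For the enrichment design the `subgroup_effect` entry carries attribute
#'   `subgroup = 1` (positives only).
#' @export
identifiable_contrasts <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  switch(design$kind,
    enrichment = structure("subgroup_effect", subgroup = 1L),
    stratified = c("subgroup_effect", "differential_effect",
                   "clinical_utility_experimental"),
    strategy = "clinical_utility_comparative",
    modified_strategy = {
      if (design$test_marker_in_randomized_arm) {
        c("subgroup_effect", "differential_effect",
          "clinical_utility_experimental")
      } else {
        warning("modified design without marker testing: only the arm-level ",
                "directed-vs-randomized comparison (experimental clinical ",
                "utility) is available")
        "clinical_utility_experimental"
      }
    })
}

#' Stratified randomization probability matching a modified-strategy design
#'
#' In the modified biomarker-strategy design a positive patient receives
#' treatment B either via the biomarker-directed arm (probability `r_strat`)
#' or via further randomization within the randomized arm (probability
#' `(1 - r_strat) * r_pos2`).  Setting the stratified design's `r_pos1` to the
#' sum gives both designs identical assignment probabilities for positives.
#'
#' @param r_strat probability of the biomarker-directed arm.
#' @param r_pos2 probability of B within the randomized arm, positives.
#' @return `r_strat + (1 - r_strat) * r_pos2`.
#' @examples
#' matched_stratified_probability(0.5, 0.5)  # 0.75
#' @export
matched_stratified_probability <- function(r_strat, r_pos2) {
  if (any(c(r_strat, r_pos2) < 0) || any(c(r_strat, r_pos2) > 1))
    stop("inputs must be probabilities in [0,1]")
  r_strat + (1 - r_strat) * r_pos2
}

#' Exact joint (marker, treatment) probability table of a design
#'
#' Enumerates the assignment mechanism analytically; useful for verifying that
#' a stratified design with matched randomization probabilities reproduces a
#' modified-strategy design's joint law.  For the negative subgroup the
#' matched stratified probability is `(1 - r_strat) * r_neg2`, since the
#' directed rule never gives negatives treatment B.
#'
#' @param design a [design_spec()] (stratified or modified_strategy).
#' @param prevalence P(M = 1).
#' @param physician a [physician_model()] (strategy design only).
#' @return A 2 x 2 matrix of probabilities, rows `M=0`/`M=1`,
#'   columns `A`/`B`.
#' @export
design_joint_table <- function(design, prevalence,
                               physician = physician_model("ideal")) {
  stopifnot(inherits(design, "design_spec"),
            prevalence >= 0, prevalence <= 1)
  pB_pos <- switch(design$kind,
    enrichment = design$r_pos1,
    stratified = design$r_pos1,
    strategy = design$r_strat * 1 +
      (1 - design$r_strat) * physician$p_B_given_pos,
    modified_strategy = design$r_strat * 1 +
      (1 - design$r_strat) * design$r_pos2)
  pB_neg <- switch(design$kind,
    enrichment = NA_real_,
    stratified = design$r_neg1,
    strategy = (1 - design$r_strat) * physician$p_B_given_neg,
    modified_strategy = (1 - design$r_strat) * design$r_neg2)
  p1 <- if (design$kind == "enrichment") 1 else prevalence
  p0 <- 1 - p1
  out <- rbind(`M=0` = c(A = p0 * (1 - pB_neg), B = p0 * pB_neg),
               `M=1` = c(A = p1 * (1 - pB_pos), B = p1 * pB_pos))
  if (design$kind == "enrichment") out["M=0", ] <- 0
  out
}
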