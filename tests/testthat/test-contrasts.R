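make_cohort <- function(design, seed = 1, n_per_arm = 400, ...) {
  cfg <- scenario_config(design = design, n_per_arm = n_per_arm, ...)
  set.seed(seed)
  generate_cohort(cfg)
}

test_that("gatekeeping is total: every (design, contrast) pair estimates or
           raises an identifiability error", {
  designs <- c("enrichment", "stratified", "strategy", "modified_strategy")
  allowed <- list(
    enrichment = "subgroup_effect",
    stratified = c("subgroup_effect", "differential_effect"),
    strategy = "clinical_utility_comparative",
    modified_strategy = c("subgroup_effect", "differential_effect",
                          "clinical_utility_experimental"))
  for (d in designs) {
    co <- make_cohort(d, seed = 70)
    for (ct in c("subgroup_effect", "differential_effect",
                 "clinical_utility_comparative",
                 "clinical_utility_experimental")) {
      rq <- contrast_request(ct, "RMST")
      if (ct %in% allowed[[d]]) {
        expect_s3_class(estimate_contrast(co, rq), "pdt_fit")
      } else if (d == "stratified" && ct == "clinical_utility_experimental") {
        # identifiable in principle, but only via the modified design's arms
        expect_error(estimate_contrast(co, rq), "modified")
      } else {
        expect_error(estimate_contrast(co, rq),
                     class = "pdt_identifiability_error")
      }
    }
  }
  # the strategy design cannot give within-subgroup effects
  expect_error(estimate_contrast(make_cohort("strategy"),
                                 contrast_request("subgroup_effect", "HR")),
               class = "pdt_identifiability_error")
  # logrank cannot address the differential effect at all
  expect_error(contrast_request("differential_effect", "LR"),
               "differential")
})

test_that("contrast estimators route to the right working model", {
  set.seed(71)
  co <- make_cohort("stratified", seed = 71, n_per_arm = 2000,
                    medians = c(pos_A = 9, pos_B = 12, neg_A = 12, neg_B = 9))
  # subgroup HR(B vs A | M=1): truth 9/12 = 0.75
  f <- estimate_contrast(co, contrast_request("subgroup_effect", "HR",
                                              subgroup = 1))
  expect_lt(abs(f$estimate - 0.75), 0.07)
  # differential effect on the HR scale: (9/12) / (12/9) = 0.5625
  fd <- estimate_contrast(co, contrast_request("differential_effect", "HR"))
  expect_lt(abs(fd$estimate - 0.5625), 0.08)
  expect_named(fd$coefficients, c("trtB", "marker", "trtB_marker"))
  # RMST differential: the interaction coefficient of the pseudo-value model
  fr <- estimate_contrast(co, contrast_request("differential_effect", "RMST"))
  truth <- true_contrast_value(attr(co, "config"),
                               contrast_request("differential_effect", "RMST"))
  expect_lt(abs(fr$estimate - truth), 1.5)

  # comparative utility on a strategy trial reports the arm coefficient
  co2 <- make_cohort("strategy", seed = 72)
  fc <- estimate_contrast(co2, contrast_request("clinical_utility_comparative",
                                                "HR"))
  expect_named(fc$coefficients, "directed")
  expect_equal(fc$hr_reciprocal, 1 / fc$estimate)
})

test_that("analytic truths match closed forms", {
  cfg <- scenario_config()  # ideal physician
  # zero clinical utility by construction
  expect_identical(true_contrast_value(
    cfg, contrast_request("clinical_utility_comparative", "HR")), 1)
  expect_identical(true_contrast_value(
    cfg, contrast_request("clinical_utility_comparative", "RMST")), 0)
  expect_identical(true_contrast_value(
    cfg, contrast_request("clinical_utility_comparative", "SD")), 0)

  # subgroup HR for medians 9 (A) vs 12 (B): hazard ratio 9/12
  cfg2 <- scenario_config(medians = c(pos_A = 9, pos_B = 12,
                                      neg_A = 12, neg_B = 9))
  expect_equal(true_contrast_value(
    cfg2, contrast_request("subgroup_effect", "HR", subgroup = 1)), 0.75)
  lamB <- log(2) / 12; lamA <- log(2) / 9
  expect_equal(true_contrast_value(
    cfg2, contrast_request("subgroup_effect", "SD", subgroup = 1)),
    exp(-lamB * 36) - exp(-lamA * 36))
  expect_equal(true_contrast_value(
    cfg2, contrast_request("subgroup_effect", "RMST", subgroup = 1)),
    (1 - exp(-lamB * 36)) / lamB - (1 - exp(-lamA * 36)) / lamA)

  # non-ideal physician: utility truths from exponential mixtures
  cfg3 <- scenario_config(
    physician_model = physician_model("bernoulli", p_B_given_pos = 0.5,
                                      p_B_given_neg = 0.5),
    medians = c(pos_A = 9, pos_B = 21, neg_A = 12, neg_B = 9))
  sd_true <- true_contrast_value(
    cfg3, contrast_request("clinical_utility_comparative", "SD"))
  lam <- function(m) log(2) / m
  s <- function(m, t) exp(-lam(m) * t)
  directed <- 0.5 * s(21, 36) + 0.5 * s(12, 36)
  phys <- 0.5 * (0.5 * s(21, 36) + 0.5 * s(9, 36)) +
    0.5 * (0.5 * s(9, 36) + 0.5 * s(12, 36))
  expect_equal(sd_true, directed - phys)
  # mixtures are not proportional: no single true HR
  expect_warning(hr <- true_contrast_value(
    cfg3, contrast_request("clinical_utility_comparative", "HR")),
    "proportional")
  expect_true(is.na(hr))

  # experimental utility under 1:1 randomization, ideal-null medians
  cfg4 <- scenario_config(prevalence = 0.25)
  rm36 <- function(m) (1 - exp(-lam(m) * 36)) / lam(m)
  expect_equal(true_contrast_value(
    cfg4, contrast_request("clinical_utility_experimental", "RMST")),
    0.75 * (rm36(12) - 0.5 * rm36(9) - 0.5 * rm36(12)))
})

test_that("relative and absolute contrast forms agree in direction", {
  set.seed(73)
  co <- make_cohort("stratified", seed = 73, n_per_arm = 1500,
                    medians = c(pos_A = 9, pos_B = 21, neg_A = 12, neg_B = 9))
  hr <- estimate_contrast(co, contrast_request("subgroup_effect", "HR", 1))
  rm <- estimate_contrast(co, contrast_request("subgroup_effect", "RMST", 1))
  sd <- estimate_contrast(co, contrast_request("subgroup_effect", "SD", 1))
  expect_true(sign(log(hr$estimate)) == -sign(rm$estimate))
  expect_true(sign(rm$estimate) == sign(sd$estimate))
})
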