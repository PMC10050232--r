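test_that("Kaplan-Meier curve and functionals match hand-computed values", {
  # no censoring: empirical survival
  cu <- km_fit(c(2, 4, 6), c(1, 1, 1))
  expect_equal(survival_at(cu, 5), 1 / 3)
  expect_equal(survival_at(cu, 0), 1)
  # censoring at 4: product-limit 2/3 on [2,6), then drops to 0
  cc <- km_fit(c(2, 4, 6), c(1, 0, 1))
  expect_equal(survival_at(cc, 3), 2 / 3)
  expect_equal(survival_at(cc, 6), 0)
  # RMST of uncensored sample = mean of min(T, t)
  expect_equal(rmst(cu, 6), 4)
  expect_equal(rmst(cu, 1e-9), 1e-9, tolerance = 1e-6)
  expect_lte(rmst(cu, 5), 5)   # bounded by the horizon
  # monotone in t
  expect_true(all(diff(vapply(1:6, function(t) rmst(cu, t), 0)) >= 0))
  # beyond support: carry the last value, with a warning
  expect_warning(s <- survival_at(cu, 10), "carrying last value")
  expect_equal(s, 0)
})

test_that("Kaplan-Meier converges to the exponential truth", {
  set.seed(51)
  lam <- log(2) / 9
  x <- stats::rexp(1e4, lam)
  cu <- km_fit(x, rep(1, 1e4))
  grid <- seq(0.1, 30, length.out = 500)
  expect_lt(max(abs(survival_at(cu, grid) - exp(-lam * grid))), 0.02)
  expect_lt(abs(survival_at(cu, 9) - 0.5), 0.02)
  # closed-form RMST: (1 - exp(-lam t)) / lam
  lam12 <- log(2) / 12
  y <- stats::rexp(1e4, lam12)
  expect_lt(abs(rmst(km_fit(y, rep(1, 1e4)), 36) -
                  (1 - exp(-lam12 * 36)) / lam12), 0.15)
})

test_that("logrank equals the explicit hypergeometric tally and the Cox score", {
  tt <- c(1, 2, 3, 4)
  ev <- c(1, 1, 1, 1)
  gg <- c(1, 1, 2, 2)
  lr <- logrank_test(tt, ev, gg)
  expect_equal(lr$statistic, logrank_tally_oracle(tt, ev, gg))
  expect_equal(lr$p_value,
               stats::pchisq(lr$statistic, 1, lower.tail = FALSE))

  set.seed(52)
  d <- two_group_exp(60, 10, 16, admin = 24)
  lr2 <- logrank_test(d$time, d$event, d$group)
  expect_equal(lr2$statistic, logrank_tally_oracle(d$time, d$event, d$group))
  # logrank == Cox partial-likelihood score test on tie-free data
  cx <- cox_fit(d$time, d$event,
                treatment = ifelse(d$group == 1, "B", "A"), model = "treatment")
  expect_equal(lr2$statistic, cx$score_statistic, tolerance = 1e-6)

  expect_error(logrank_test(tt, ev, c(1, 1, 1, 1)), "two groups")
  expect_error(logrank_test(tt, c(0, 0, 0, 0), gg), "no events")
})

test_that("Cox fits recover generative hazard ratios", {
  set.seed(53)
  # true HR(B vs A) = rate ratio = median_A / median_B = 12 / 9
  d <- two_group_exp(5000, 12, 9)
  cx <- cox_fit(d$time, d$event,
                treatment = ifelse(d$group == 1, "B", "A"), model = "treatment")
  expect_lt(abs(cx$estimate - 12 / 9), 0.05)
  expect_lt(cx$p_value, 1e-6)

  # no interaction by construction -> exp(b2) near 1, and matches survival's
  # own coefficient
  set.seed(54)
  n <- 4000
  mk <- rep(0:1, each = n / 2)
  tB <- rep(c(0, 1), n / 2)
  lam <- log(2) / ifelse(tB == 1, 9, 12)   # equal effect in both subgroups
  tt <- stats::rexp(n, lam)
  cx2 <- cox_fit(tt, rep(1, n), treatment = ifelse(tB == 1, "B", "A"),
                 marker = mk, model = "interaction")
  expect_lt(abs(cx2$estimate - 1), 0.1)
  expect_gt(cx2$p_value, 0.01)

  # arm model is the same machinery on an arm indicator
  set.seed(55)
  d2 <- two_group_exp(500, 10, 10)
  cx3 <- cox_fit(d2$time, d2$event,
                 arm = ifelse(d2$group == 1, "directed", "physician"),
                 model = "arm")
  expect_named(cx3$coefficients, "directed")
})

test_that("pseudo-observations equal their uncensored transforms exactly", {
  set.seed(56)
  x <- stats::rexp(200, 0.08)
  ev <- rep(1, 200)
  for (t0 in c(5, 12, 30)) {
    ps <- pseudo_observations(x, ev, "survival", t0)
    expect_equal(ps$values, as.numeric(x > t0), tolerance = 1e-12)
    pr <- pseudo_observations(x, ev, "rmst", t0)
    expect_equal(pr$values, pmin(x, t0), tolerance = 1e-12)
  }
})

test_that("pseudo-observations equal the brute-force leave-one-out jackknife", {
  # 3-subject censored toy set, hand-checkable
  ps <- pseudo_observations(c(2, 4, 6), c(1, 0, 1), "survival", 5)
  expect_equal(ps$values, c(0, 1, 1), tolerance = 1e-12)
  expect_equal(ps$values,
               brute_force_pseudo(c(2, 4, 6), c(1, 0, 1), "survival", 5),
               tolerance = 1e-12)

  # randomized censored sets, with and without ties, both functionals
  set.seed(57)
  for (case in 1:6) {
    n <- sample(10:40, 1)
    tt <- stats::rexp(n, 0.1) + 0.01
    if (case %% 2 == 0) tt <- ceiling(tt)      # force ties
    ev <- stats::rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1
    t0 <- stats::quantile(tt, 0.7, names = FALSE)
    for (fun in c("survival", "rmst")) {
      expect_equal(pseudo_observations(tt, ev, fun, t0)$values,
                   brute_force_pseudo(tt, ev, fun, t0),
                   tolerance = 1e-12)
    }
  }

  # construction identity: mean of pseudo-values recovers n*theta-(n-1)*mean(loo)
  set.seed(58)
  tt <- stats::rexp(100, 0.1); ev <- stats::rbinom(100, 1, 0.7)
  ps <- pseudo_observations(tt, ev, "rmst", 10)
  loo <- vapply(seq_along(tt), function(i)
    km_value_oracle(tt[-i], ev[-i], "rmst", 10), 0)
  expect_equal(mean(ps$values), 100 * ps$theta_hat - 99 * mean(loo),
               tolerance = 1e-12)

  expect_error(pseudo_observations(c(1, 2), c(1, 1), "survival", 5),
               "exceeds the last observed time")
})

test_that("identity-link pseudo-value regression is exact least squares with
           sandwich variance", {
  set.seed(59)
  d <- two_group_exp(150, 9, 14, admin = 25)
  ps <- pseudo_observations(d$time, d$event, "survival", 12)
  Z <- cbind(intercept = 1, grp = d$group)
  fit <- glm_identity(ps, Z, "grp")
  # single binary regressor: slope is exactly the difference in group means
  expect_equal(fit$estimate,
               mean(ps$values[d$group == 1]) - mean(ps$values[d$group == 0]),
               tolerance = 1e-10)
  # sandwich (HC0) cross-check against the sandwich package
  lmfit <- stats::lm(ps$values ~ d$group)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(sandwich::vcovHC(lmfit, type = "HC0"))[2])),
               tolerance = 1e-8)
  # no censoring: SD model slope = difference in proportions alive at t, exactly
  set.seed(60)
  d2 <- two_group_exp(120, 9, 18)
  ps2 <- pseudo_observations(d2$time, d2$event, "survival", 12)
  f2 <- glm_identity(ps2, cbind(intercept = 1, grp = d2$group), "grp")
  expect_equal(f2$estimate,
               mean(d2$time[d2$group == 1] > 12) -
                 mean(d2$time[d2$group == 0] > 12),
               tolerance = 1e-12)

  expect_error(glm_identity(ps, cbind(1, d$group, d$group * 2), 2),
               "rank deficient")
})

test_that("estimators are invariant to row order", {
  set.seed(61)
  d <- two_group_exp(100, 9, 15, admin = 30)
  perm <- sample(nrow(d))
  p1 <- pseudo_observations(d$time, d$event, "rmst", 20)$values
  p2 <- pseudo_observations(d$time[perm], d$event[perm], "rmst", 20)$values
  expect_equal(p2, p1[perm], tolerance = 1e-12)
  l1 <- logrank_test(d$time, d$event, d$group)$statistic
  l2 <- logrank_test(d$time[perm], d$event[perm], d$group[perm])$statistic
  expect_equal(l1, l2, tolerance = 1e-10)
  c1 <- cox_fit(d$time, d$event, treatment = ifelse(d$group == 1, "B", "A"))
  c2 <- cox_fit(d$time[perm], d$event[perm],
                treatment = ifelse(d$group[perm] == 1, "B", "A"))
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-8)
})
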