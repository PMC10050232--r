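#' Kaplan-Meier curve
#'
#' Thin wrapper around [survival::survfit()] returning a plain step-function
#' container.  Censoring tied with an event time is ordered after the event
#' (the standard product-limit convention).
#'
#' @param times positive observed times (months).
#' @param events 0/1 event indicators.
#' @return An object of class `"pdt_km"`: list with `time` (all observed
#'   times, ascending), `surv`, `n_risk`, `n_event`, `n`, and `all_censored`
#'   flag.
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           se.fit = FALSE, conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = length(times),
                 all_censored = sum(events) == 0),
            class = "pdt_km")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation; before the first observed time
#' the curve is 1.  Beyond the last observed time the last value is carried
#' forward with a warning (the curve is not defined there; at the default
#' sample sizes this is rare but must be deterministic).
#'
#' @param curve a [km_fit()] object.
#' @param t evaluation time (months, >= 0); vectorized.
#' @return Survival probability/ies.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "pdt_km"), all(t >= 0))
  if (any(t > max(curve$time)))
    warning("evaluation beyond the last observed time; carrying last value")
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Exact area under the step function on `[0, t]`:
#' \eqn{RMST(t) = \int_0^t \hat S(u)\,du = E[\min(T, t)]} for uncensored data.
#'
#' @param curve a [km_fit()] object.
#' @param t horizon in months (> 0).
#' @return RMST in months.
#' @export
rmst <- function(curve, t) {
  stopifnot(inherits(curve, "pdt_km"), length(t) == 1L, t > 0)
  if (t > max(curve$time))
    warning("horizon beyond the last observed time; carrying last value")
  steps <- c(0, curve$time[curve$time < t], t)
  heights <- c(1, curve$surv[curve$time < t])
  sum(heights * diff(steps))
}

new_fit_result <- function(estimand, contrast, estimate, se, statistic,
                           p_value, coefficients = NULL, extra = NULL) {
  structure(c(list(estimand = estimand, contrast = contrast,
                   estimate = estimate, se = se, statistic = statistic,
                   p_value = p_value, coefficients = coefficients),
              extra),
            class = "pdt_fit")
}

#' @export
print.pdt_fit <- function(x, ...) {
  cat(sprintf("%s [%s]: estimate %.4g (se %.4g), statistic %.4g, p = %.4g\n",
              x$estimand, x$contrast %||% "raw", x$estimate, x$se,
              x$statistic, x$p_value))
  invisible(x)
}

#' Two-sample logrank test
#'
#' Standard (O - E)^2 / V chi-square statistic on 1 df via
#' [survival::survdiff()], with a two-sided p-value.  The logrank test only
#' addresses equality of two survival distributions; it carries no estimate of
#' the magnitude of a difference.
#'
#' @param times,events observed times and 0/1 indicators.
#' @param group two-level grouping vector.
#' @return A `"pdt_fit"` with `estimand = "LR"` and `estimate = NA`.
#' @export
logrank_test <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("logrank test requires exactly two groups")
  if (any(tabulate(g, 2L) == 0L)) stop("one group is empty")
  if (sum(events) < 1L) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  stat <- sd$chisq
  new_fit_result("LR", NULL, NA_real_, NA_real_, stat,
                 stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fits for the three working models
#'
#' Fits, by partial likelihood with the Efron tie correction, one of:
#' \describe{
#'   \item{`"treatment"`}{hazard ratio of B vs A within the supplied (usually
#'     subgroup-restricted) data; reports `exp(b0)` for the treatment
#'     indicator.}
#'   \item{`"interaction"`}{treatment, marker and their product; reports
#'     `exp(b2)` for the interaction, the ratio of subgroup hazard ratios
#'     (differential treatment effect).}
#'   \item{`"arm"`}{a single biomarker-directed-arm indicator; reports
#'     `exp(b0)`, the clinical-utility hazard ratio.}
#' }
#' Inference is a two-sided Wald test on the log scale.
#'
#' @param times,events observed times and 0/1 indicators.
#' @param treatment `"A"`/`"B"` vector (`"treatment"`/`"interaction"` models).
#' @param marker 0/1 vector (`"interaction"` model).
#' @param arm arm labels; `"directed"` is the indicator level (`"arm"` model).
#' @param model `"treatment"`, `"interaction"` or `"arm"`.
#' @return A `"pdt_fit"` with `estimand = "HR"`; `estimate` is the hazard
#'   ratio, `se` the standard error of its log.
#' @export
cox_fit <- function(times, events, treatment = NULL, marker = NULL,
                    arm = NULL, model = c("treatment", "interaction", "arm")) {
  model <- match.arg(model)
  x <- switch(model,
    treatment = cbind(trtB = as.integer(treatment == "B")),
    interaction = {
      tB <- as.integer(treatment == "B")
      cbind(trtB = tB, marker = as.integer(marker),
            trtB_marker = tB * as.integer(marker))
    },
    arm = cbind(directed = as.integer(arm == "directed")))
  df <- data.frame(time = times, event = events, x)
  fml <- stats::reformulate(colnames(x), response = "survival::Surv(time, event)")
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron", model = FALSE,
                    x = FALSE, y = FALSE),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) {
      # coxph warns on non-convergence / infinite coefficients (separation)
      stop("Cox fit unstable: ", conditionMessage(w))
    })
  target <- switch(model, treatment = "trtB", interaction = "trtB_marker",
                   arm = "directed")
  b <- stats::coef(fit)[target]
  se <- sqrt(diag(fit$var))[match(target, names(stats::coef(fit)))]
  if (!is.finite(b) || !is.finite(se))
    stop("Cox fit non-estimable (separation or no events in a group)")
  z <- b / se
  new_fit_result("HR", NULL, exp(unname(b)), unname(se), unname(z),
                 2 * stats::pnorm(-abs(z)),
                 coefficients = stats::coef(fit),
                 extra = list(score_statistic = unname(fit$score)))
}

## ---- pseudo-observations -------------------------------------------------

## Exact jackknife pseudo-values for KM functionals, computed without n refits.
## For subject i, the leave-one-out KM differs from the full-sample KM only
## through the risk/event counts at each event time t_j:
##   Y_j^{-i} = Y_j - 1{T_i >= t_j},   d_j^{-i} = d_j - 1{T_i = t_j, ev_i = 1}
## so at event time j the leave-one-out product-limit factor is one of three
## values shared by all subjects in the same position:
##   a_j = 1 - d_j/Y_j            subject not at risk at t_j (T_i < t_j)
##   b_j = 1 - d_j/(Y_j - 1)      at risk, not an event at t_j
##   c_j = 1 - (d_j - 1)/(Y_j-1)  an event at t_j
## (a factor over an empty reduced risk set is 1: only the deleted subject
## was there).  Every subject's leave-one-out curve is then
##   S^{-i} = [prefix of b] * [c at the subject's own event] * [suffix of a],
## so prefix/suffix cumulative products and width-weighted cumulative sums
## give all n leave-one-out functionals in O(n log n + k), identical to
## brute-force deletion to machine precision.

#' Jackknife pseudo-observations of Kaplan-Meier functionals
#'
#' Computes, for every subject, the exact leave-one-out pseudo-value
#' \eqn{\hat\theta_i = n\hat\theta - (n-1)\hat\theta^{-i}} of either the
#' survival probability at `t` (`f(T) = I(T > t)`) or the restricted mean
#' survival time at `t` (`f(T) = min(T, t)`), with \eqn{\hat\theta} the
#' pooled-sample Kaplan-Meier plug-in.  With no censoring the pseudo-values
#' reduce exactly to `I(T_i > t)` and `min(T_i, t)`.
#'
#' The leave-one-out estimates are obtained analytically from the full-sample
#' risk and event counts rather than by refitting, so the computation is
#' O(n x #event times) and agrees with brute-force deletion to machine
#' precision.
#'
#' @param times,events observed times and 0/1 indicators.
#' @param functional `"survival"` (probability of surviving past `t`) or
#'   `"rmst"` (restricted mean up to `t`).
#' @param t horizon in months; must be within follow-up.
#' @return An object of class `"pdt_pseudo"`: list with `values` (one per
#'   subject, input order), `theta_hat`, `functional`, `horizon`, `n`.
#' @export
pseudo_observations <- function(times, events,
                                functional = c("survival", "rmst"), t) {
  functional <- match.arg(functional)
  n <- length(times)
  stopifnot(n >= 2L, length(events) == n, all(times > 0),
            all(events %in% c(0, 1)), length(t) == 1L, t > 0)
  if (t > max(times))
    stop("horizon t = ", t, " exceeds the last observed time; ",
         "no risk set at t")

  ## risk/event counts at the full sample's unique event times <= t
  ev_times <- sort(unique(times[events == 1 & times <= t]))
  k <- length(ev_times)
  sorted <- sort(times)
  d <- tabulate(match(times[events == 1 & times <= t], ev_times), k)
  Y <- n - findInterval(ev_times, sorted, left.open = TRUE)  # #{T >= t_j}

  a <- 1 - d / Y
  b <- ifelse(Y > 1, 1 - d / (Y - 1), 1)          # Y==1 case never consumed
  cc <- ifelse(Y > 1, 1 - (d - 1) / (Y - 1), 1)   # 0/0 -> 1: lone subject
  Bpre <- cumprod(b)                               # prefix of b factors
  Asuf <- rev(cumprod(rev(a)))                     # suffix of a factors
  Bpre0 <- c(1, Bpre)
  Asuf0 <- c(Asuf, 1)                              # Asuf0[j] = prod a_{j..k}

  ## subject positions among event times
  m <- pmin(times, t)
  p <- findInterval(m, ev_times)                   # #{t_j <= min(T_i, t)}
  ev_in <- events == 1 & times <= t                # own event contributes

  pe <- pmax(p, 1L)   # p >= 1 wherever ev_in; guard keeps indexing aligned
  if (functional == "survival") {
    theta <- prod(a)
    loo <- ifelse(ev_in,
                  Bpre0[pe] * cc[pe] * Asuf0[pe + 1L],
                  Bpre0[p + 1L] * Asuf0[p + 1L])
  } else {
    width <- diff(c(0, ev_times, t))               # k + 1 segment widths
    theta <- width[1L] + if (k) sum(cumprod(a) * width[-1L]) else 0
    PBW <- c(0, if (k) cumsum(Bpre * width[-1L]) else NULL)
    SA <- numeric(k + 1L)                          # SA[j] = area from t_j on,
    if (k) for (j in k:1)                          # entering with survival 1
      SA[j] <- a[j] * (width[j + 1L] + SA[j + 1L])
    loo <- ifelse(ev_in,
                  width[1L] + PBW[pe] +
                    Bpre0[pe] * cc[pe] * (width[pe + 1L] + SA[pe + 1L]),
                  width[1L] + PBW[p + 1L] + Bpre0[p + 1L] * SA[p + 1L])
  }
  structure(list(values = n * theta - (n - 1) * loo,
                 theta_hat = theta, functional = functional,
                 horizon = t, n = n),
            class = "pdt_pseudo")
}

#' Identity-link regression of pseudo-observations with sandwich variance
#'
#' Solves the identity-link generalised estimating equations
#' \eqn{\theta_i = \beta^T Z_i} by least squares and reports
#' heteroscedasticity-robust (sandwich) standard errors with bread
#' \eqn{(Z^T Z)^{-1}} and meat \eqn{\sum_i Z_i r_i^2 Z_i^T}: pseudo-values
#' are not independent given the pooled estimate, so model-based variance is
#' not appropriate.  Two-sided Wald tests against zero.
#'
#' @param pseudo a [pseudo_observations()] result (or a numeric vector of
#'   pseudo-values).
#' @param Z design matrix including the intercept column; must be full rank.
#' @param target name (or index) of the coefficient reported as the contrast
#'   estimate, e.g. the treatment indicator (subgroup effect, clinical
#'   utility) or the treatment-by-marker product (differential effect).
#' @return A `"pdt_fit"` with `estimand` `"SD"` or `"RMST"` (months);
#'   `coefficients` holds the full beta vector.
#' @export
glm_identity <- function(pseudo, Z, target) {
  y <- if (inherits(pseudo, "pdt_pseudo")) pseudo$values else pseudo
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(y))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  bread <- solve(crossprod(Z))
  beta <- drop(bread %*% crossprod(Z, y))
  r <- y - drop(Z %*% beta)
  meat <- crossprod(Z * r)
  V <- bread %*% meat %*% bread
  se <- sqrt(diag(V))
  names(se) <- names(beta) <- colnames(Z)
  if (is.numeric(target)) target <- colnames(Z)[target]
  z <- beta[target] / se[target]
  estimand <- if (inherits(pseudo, "pdt_pseudo") &&
                  pseudo$functional == "rmst") "RMST" else "SD"
  new_fit_result(estimand, NULL, unname(beta[target]), unname(se[target]),
                 unname(z), 2 * stats::pnorm(-abs(unname(z))),
                 coefficients = beta, extra = list(vcov = V))
}
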