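## Independent oracles used to cross-check the package's estimators.  These
## deliberately take the slow, literal route (refitting survfit per deleted
## subject; tallying the hypergeometric contributions event time by event
## time) so they share no code with the implementations they verify.

km_value_oracle <- function(times, events, functional, t) {
  f <- survival::survfit(survival::Surv(times, events) ~ 1)
  if (functional == "survival") {
    i <- findInterval(t, f$time)
    c(1, f$surv)[i + 1]
  } else {
    steps <- c(0, f$time[f$time < t], t)
    heights <- c(1, f$surv[f$time < t])
    sum(heights * diff(steps))
  }
}

brute_force_pseudo <- function(times, events, functional, t) {
  n <- length(times)
  theta <- km_value_oracle(times, events, functional, t)
  vapply(seq_len(n), function(i) {
    n * theta - (n - 1) * km_value_oracle(times[-i], events[-i], functional, t)
  }, 0)
}

## classic logrank chi-square by explicit tally at each distinct event time
logrank_tally_oracle <- function(times, events, group) {
  g <- as.integer(factor(group)) == 1L
  ev_times <- sort(unique(times[events == 1]))
  OmE <- 0
  V <- 0
  for (u in ev_times) {
    at_risk <- times >= u
    nj <- sum(at_risk)
    n1 <- sum(at_risk & g)
    dj <- sum(times == u & events == 1)
    d1 <- sum(times == u & events == 1 & g)
    OmE <- OmE + d1 - dj * n1 / nj
    if (nj > 1)
      V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  OmE^2 / V
}

## quick two-group exponential cohort for estimator tests
two_group_exp <- function(n_per_group, median0, median1, admin = Inf) {
  grp <- rep(0:1, each = n_per_group)
  tt <- stats::rexp(2 * n_per_group,
                    rate = log(2) / ifelse(grp == 1, median1, median0))
  ev <- as.integer(tt <= admin)
  data.frame(time = pmin(tt, admin), event = ev, group = grp)
}
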