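# Independent brute-force oracles used across the suite.

# Day-by-day risk-set enumeration for integer event times: walks every day
# from 1 to max(time), maintaining the all-cause product-limit survival, the
# cause-1-only (competing cause censored) survival, and the Aalen-Johansen
# sums.  Deliberately sequential and scalar -- it shares no code path with
# the package's vectorized estimators.
brute_force_curves <- function(time, event, weight = rep(1, length(time))) {
  tmax <- max(time)
  S <- 1; S1only <- 1; aj1 <- 0; aj2 <- 0
  out <- data.frame(day = seq_len(tmax), S = NA_real_, naive1 = NA_real_,
                    aj1 = NA_real_, aj2 = NA_real_)
  for (day in seq_len(tmax)) {
    n <- sum(weight[time >= day])
    d1 <- sum(weight[time == day & event == 1])
    d2 <- sum(weight[time == day & event == 2])
    if (n > 0) {
      aj1 <- aj1 + S * (d1 / n)
      aj2 <- aj2 + S * (d2 / n)
      S <- S * (1 - (d1 + d2) / n)
      S1only <- S1only * (1 - d1 / n)
    }
    out$S[day] <- S
    out$naive1[day] <- 1 - S1only
    out$aj1[day] <- aj1
    out$aj2[day] <- aj2
  }
  out
}

# Random mini-cohort with integer times, both causes, censoring and integer
# weights; optionally two arms with at least two cause-1 events in each so
# that tiny Cox fits stay identifiable most of the time.
rand_mini_cohort <- function(seed, two_arm = FALSE) {
  set.seed(seed)
  n <- sample(3:12, 1)
  d <- data.frame(time = sample(1:25, n, replace = TRUE),
                  event = sample(c(0L, 1L, 1L, 2L), n, replace = TRUE),
                  arm = if (two_arm) sample(c("a", "b"), n, replace = TRUE)
                        else "a",
                  w = sample(1:3, n, replace = TRUE))
  if (two_arm) {
    # guarantee cause-1 events in both arms
    d$arm[1:2] <- c("a", "b")
    d$event[1:2] <- 1L
  }
  as_cohort(d, weight = "w", arm_levels = sort(unique(d$arm)))
}

# Package curves evaluated on the oracle's integer day grid.
package_curves <- function(cohort, weights = NULL) {
  rs <- build_risk_sets(cohort, weights)
  days <- seq_len(max(cohort$time))
  data.frame(day = days,
             S = step_at(km_survival(rs), days),
             naive1 = step_at(naive_km_cif(rs, 1), days),
             aj1 = step_at(competing_risks_cif(rs, 1), days),
             aj2 = step_at(competing_risks_cif(rs, 2), days))
}
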