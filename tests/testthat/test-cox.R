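# brute-force log partial likelihood (Breslow) for a single binary covariate,
# written directly from the definition; maximized by stats::optimize
brute_loglik <- function(time, status, x, w, beta) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (x[i] * beta - log(sum(w[risk] * exp(x[risk] * beta))))
  }
  ll
}

test_that("cause-specific Cox matches a brute-force likelihood search", {
  d <- data.frame(time = c(1, 2, 3, 4), event = 1L,
                  arm = c("b", "a", "b", "a"))
  co <- as_cohort(d)
  fit <- fit_cause_specific_cox(co, cause = 1)
  x <- as.numeric(d$arm == "b")
  opt <- optimize(function(b) brute_loglik(d$time, rep(1, 4), x, rep(1, 4), b),
                  c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-6)

  # weighted version against the same oracle
  dw <- data.frame(time = c(1, 2, 3, 5, 8), event = c(1L, 1L, 0L, 1L, 1L),
                   arm = c("b", "a", "b", "b", "a"), w = c(2, 1, 1, 3, 2))
  cow <- as_cohort(dw, weight = "w")
  fitw <- fit_cause_specific_cox(cow, cause = 1)
  xw <- as.numeric(dw$arm == "b")
  optw <- optimize(function(b) brute_loglik(dw$time, as.numeric(dw$event == 1),
                                            xw, dw$w, b),
                   c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fitw$coefficients), optw$maximum, tolerance = 1e-6)
})

test_that("coefficients and sandwich variance agree with coxph", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 250
  d <- data.frame(time = ceiling(rexp(n, 0.08)),
                  event = sample(c(0L, 1L, 1L, 2L), n, TRUE),
                  arm = sample(c("c", "t1", "t2"), n, TRUE),
                  x = rnorm(n), w = runif(n, 0.4, 2.5))
  co <- as_cohort(d, covariates = "x", weight = "w", reference = "c")

  fit <- fit_cause_specific_cox(co, cause = 1, adjust = "x")
  cf <- survival::coxph(survival::Surv(time, event == 1) ~ arm + x, data = d,
                        weights = d$w, ties = "breslow", robust = TRUE)
  expect_equal(unname(fit$coefficients), unname(coef(cf)), tolerance = 1e-8)
  expect_equal(unname(fit$robust_var), unname(cf$var), tolerance = 1e-8)
  expect_equal(unname(fit$naive_var), unname(cf$naive.var), tolerance = 1e-8)

  # Efron ties, unit weights
  d$w <- 1
  co1 <- as_cohort(d, covariates = "x", reference = "c")
  fe <- fit_cause_specific_cox(co1, cause = 1, adjust = "x", ties = "efron")
  ce <- survival::coxph(survival::Surv(time, event == 1) ~ arm + x, data = d,
                        ties = "efron", robust = TRUE)
  expect_equal(unname(fe$coefficients), unname(coef(ce)), tolerance = 1e-8)

  # with unit weights on well-behaved data, robust and model-based standard
  # errors agree within 20%
  fb <- fit_cause_specific_cox(co1, cause = 1, adjust = "x")
  ratio <- sqrt(diag(fb$robust_var)) / sqrt(diag(fb$naive_var))
  expect_true(all(ratio > 0.8 & ratio < 1.2))
})

test_that("integer-weight fits equal the row-replicated fit (Breslow)", {
  for (seed in 1:10) {
    coh <- rand_mini_cohort(seed, two_arm = TRUE)
    rep_rows <- rep(seq_len(nrow(coh)), coh$weight)
    drep <- data.frame(time = coh$time[rep_rows], event = coh$event[rep_rows],
                       arm = as.character(coh$arm)[rep_rows])
    f1 <- tryCatch(fit_cause_specific_cox(coh, cause = 1),
                   error = function(e) e)
    f2 <- tryCatch(
      fit_cause_specific_cox(as_cohort(drep, arm_levels = levels(coh$arm)),
                             cause = 1),
      error = function(e) e)
    if (inherits(f1, "error") || inherits(f2, "error")) {
      expect_true(inherits(f1, "error") && inherits(f2, "error"))
    } else {
      expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-8)
    }
  }
})

test_that("weight rescaling leaves estimates and robust errors unchanged", {
  set.seed(21)
  n <- 120
  d <- data.frame(time = ceiling(rexp(n, 0.1)),
                  event = sample(c(0L, 1L, 1L, 2L), n, TRUE),
                  arm = sample(c("c", "t"), n, TRUE),
                  w = runif(n, 0.5, 2))
  co <- as_cohort(d, weight = "w", reference = "c")
  f1 <- fit_cause_specific_cox(co, cause = 1)
  d2 <- d; d2$w <- d$w * 7.3
  f2 <- fit_cause_specific_cox(as_cohort(d2, weight = "w", reference = "c"),
                               cause = 1)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$robust_var, f2$robust_var, tolerance = 1e-9)
})

test_that("cause relabeling is symmetric", {
  set.seed(4)
  n <- 100
  d <- data.frame(time = ceiling(rexp(n, 0.1)),
                  event = sample(c(0L, 1L, 2L), n, TRUE),
                  arm = sample(c("c", "t"), n, TRUE))
  co <- as_cohort(d, reference = "c")
  dsw <- d; dsw$event <- c(0L, 2L, 1L)[d$event + 1L]
  cosw <- as_cohort(dsw, reference = "c")
  f1 <- fit_cause_specific_cox(co, cause = 1)
  f2 <- fit_cause_specific_cox(cosw, cause = 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$robust_var, f2$robust_var, tolerance = 1e-12)
})

test_that("exchangeable arms give a null hazard ratio", {
  d <- data.frame(time = rep(c(2, 5, 9, 12, 20), 2),
                  event = rep(c(1L, 1L, 0L, 1L, 2L), 2),
                  arm = rep(c("a", "b"), each = 5))
  fit <- fit_cause_specific_cox(as_cohort(d), cause = 1)
  expect_lt(abs(unname(fit$coefficients)), 1e-8)
  hr <- fit$hazard_ratios
  expect_true(hr$lower <= 1 && 1 <= hr$upper)
})

test_that("degenerate designs raise informative errors", {
  # no events of the requested cause
  d <- data.frame(time = 1:6, event = 0L, arm = rep(c("a", "b"), 3))
  expect_error(fit_cause_specific_cox(as_cohort(d), cause = 1), "no events")
  # monotone likelihood: all events in one arm before any in the other
  d2 <- data.frame(time = c(1:5, 101:105), event = 1L,
                   arm = rep(c("a", "b"), each = 5))
  expect_error(fit_cause_specific_cox(as_cohort(d2), cause = 1),
               "diverging|monotone")
  # single arm, no covariates
  d3 <- data.frame(time = 1:4, event = 1L, arm = "a")
  expect_error(fit_cause_specific_cox(as_cohort(d3), cause = 1),
               "nothing to fit")
})

test_that("hazard-ratio tables line up arms across model variants", {
  set.seed(10)
  n <- 200
  d <- data.frame(time = ceiling(rexp(n, 0.08)),
                  event = sample(c(0L, 1L, 1L, 2L), n, TRUE),
                  arm = sample(c("c", "t1", "t2", "t3"), n, TRUE),
                  w = runif(n, 0.5, 2))
  co <- as_cohort(d, weight = "w", reference = "c")
  fu <- fit_cause_specific_cox(co, cause = 1, weights = rep(1, n))
  fw <- fit_cause_specific_cox(co, cause = 1)
  tab <- hazard_ratio_table(list(unweighted = fu, weighted = fw))
  expect_equal(tab$arm, c("c", "t1", "t2", "t3"))
  expect_equal(tab$unweighted_hr[1], 1)     # reference row
  expect_true(is.na(tab$unweighted_lower[1]))
  expect_equal(tab$weighted_hr[-1],
               fw$hazard_ratios$hr[match(paste0("arm", c("t1", "t2", "t3")),
                                         fw$hazard_ratios$term)])
  expect_error(hazard_ratio_table(list()), "non-empty")
  co2 <- as_cohort(d[d$arm != "t3", ], reference = "c")
  f3 <- fit_cause_specific_cox(co2, cause = 1)
  expect_error(hazard_ratio_table(list(a = fu, b = f3)), "arm structure")
})
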