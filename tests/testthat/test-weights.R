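make_4subject <- function() {
  # 4 subjects, one binary covariate; cell treatment proportions 1/2 and 2/3
  # require 2 + 3 subjects, so use the canonical 5-subject saturated design
  as_cohort(data.frame(time = 1:5, event = 1L,
                       arm = c("t", "c", "t", "t", "c"),
                       x = c(0, 0, 1, 1, 1)),
            reference = "c", covariates = "x")
}

test_that("propensity fits reproduce empirical proportions", {
  # intercept-only MLE equals the sample proportion
  co <- as_cohort(data.frame(time = 1:4, event = 1L, arm = "A",
                             tr = c(0, 1, 1, 1)), covariates = "tr")
  fit <- fit_propensity(co, "tr")
  expect_equal(fit$prob_observed[co$tr == 1], rep(0.75, 3), tolerance = 1e-9)
  expect_equal(unname(fit$marginal), c(0.25, 0.75))

  # saturated logistic fit equals the cell means
  co2 <- make_4subject()
  fit2 <- fit_propensity(co2, "arm", "x")
  p_t <- fit2$probs[, "t"]
  expect_equal(unname(p_t[co2$x == 0]), rep(1 / 2, 2), tolerance = 1e-7)
  expect_equal(unname(p_t[co2$x == 1]), rep(2 / 3, 3), tolerance = 1e-7)

  # multinomial probabilities sum to one per subject
  co3 <- as_cohort(data.frame(time = 1:9, event = 1L,
                              arm = rep(c("a", "b", "c"), 3),
                              x = rep(c(-0.5, 0, 0.5), each = 3)),
                   covariates = "x")
  fit3 <- fit_propensity(co3, "arm", "x")
  expect_equal(fit3$model_kind, "multinomial-logistic")
  expect_equal(unname(rowSums(fit3$probs)), rep(1, 9), tolerance = 1e-10)
})

test_that("propensity fitting rejects degenerate designs", {
  set.seed(2)
  co <- as_cohort(data.frame(time = 1:6, event = 1L, arm = "A",
                             tr = rep(0:1, 3), x = rnorm(6)),
                  covariates = c("x", "tr"))
  co$x2 <- 2 * co$x
  expect_error(fit_propensity(co, "tr", c("x", "x2")), "collinear.*x2")
  # perfect separation
  co$sep <- as.numeric(co$tr == 1)
  expect_error(fit_propensity(co, "tr", "sep"), "separation")
  # outcome level empty after subsetting
  sub <- co[co$tr == 1, , drop = FALSE]
  expect_error(fit_propensity(sub, "tr"), "fewer than 2 observed levels")
})

test_that("stabilized weights follow the marginal-over-conditional rule", {
  # identical covariates: every weight is exactly 1
  co <- as_cohort(data.frame(time = 1:8, event = 1L, arm = "A",
                             tr = rep(0:1, 4), x = 1),
                  covariates = c("x", "tr"))
  w <- stabilized_weights(fit_propensity(co, "tr"), NULL, co)
  expect_equal(w$raw_weight, rep(1, 8))
  expect_equal(w$raw_weight, w$numerator_prob / w$denominator_prob,
               tolerance = 1e-12)

  # hand arithmetic: treated X=0 subject with cell propensity 0.5 and
  # marginal P(treated) = 0.6 gets 0.6/0.5 = 1.2
  co2 <- make_4subject()
  fit2 <- fit_propensity(co2, "arm", "x")
  w2 <- stabilized_weights(fit2, NULL, co2)
  treated_x0 <- which(co2$arm == "t" & co2$x == 0)
  expect_equal(w2$raw_weight[treated_x0], 0.6 / 0.5, tolerance = 1e-6)
  control_x1 <- which(co2$arm == "c" & co2$x == 1)
  expect_equal(w2$raw_weight[control_x1], 0.4 / (1 / 3), tolerance = 1e-6)
})

test_that("two-stage weights reduce to stage 1 for controls", {
  set.seed(31)
  n <- 200
  d <- data.frame(time = rexp(n) + 0.1, event = 1L,
                  status = sample(c("control", "case"), n, TRUE),
                  x = rnorm(n))
  d$arm <- ifelse(d$status == "case",
                  sample(c("t1", "t2"), n, TRUE), "none")
  co <- as_cohort(d, covariates = c("x", "status"),
                  arm_levels = c("none", "t1", "t2"))
  s1 <- fit_propensity(co, "status", "x")
  cases <- co[co$status == "case", , drop = FALSE]
  s2 <- fit_propensity(cases, "arm", "x")
  w12 <- stabilized_weights(s1, s2, co, case_level = "case")
  w1 <- stabilized_weights(s1, NULL, co)
  is_ctl <- co$status == "control"
  expect_equal(w12$raw_weight[is_ctl], w1$raw_weight[is_ctl])
  expect_false(isTRUE(all.equal(w12$raw_weight[!is_ctl],
                                w1$raw_weight[!is_ctl])))
  # case weight is the product of the two stabilized stages
  w2c <- stabilized_weights(s2, NULL, cases)
  expect_equal(w12$raw_weight[!is_ctl],
               w1$raw_weight[!is_ctl] * w2c$raw_weight, tolerance = 1e-12)
})

test_that("weight truncation follows the interpolated percentile rule", {
  co <- as_cohort(data.frame(time = 1:10, event = 1L,
                             arm = rep(c("a", "b"), 5)))
  w <- stabilized_weights(fit_propensity(co, "arm"), NULL, co)
  w$raw_weight <- w$final_weight <- c(rep(1, 9), 100)

  # hand computation, linear interpolation: h = (10-1)*0.9 + 1 = 9.1,
  # cutoff = 1 + 0.1*(100 - 1) = 10.9
  cap <- truncate_weights(w, 90, "cap")
  expect_equal(attr(cap, "truncation")$cutoff, 10.9)
  expect_equal(cap$final_weight, c(rep(1, 9), 10.9))
  expect_identical(cap$truncated, c(rep(FALSE, 9), TRUE))

  # cap-mode truncation is idempotent
  cap2 <- truncate_weights(cap, 90, "cap")
  expect_equal(cap2$final_weight, cap$final_weight)

  # delete mode removes exactly the subjects above the cutoff
  del <- truncate_weights(w, 90, "delete")
  expect_equal(nrow(del), 9L)
  expect_equal(nrow(attr(del, "removed")), 1L)
  expect_equal(attr(del, "removed")$raw_weight, 100)

  # equal weights are untouched in both modes
  w$raw_weight <- w$final_weight <- rep(2, 10)
  expect_equal(truncate_weights(w, 90, "cap")$final_weight, rep(2, 10))
  expect_equal(nrow(truncate_weights(w, 90, "delete")), 10L)

  expect_error(truncate_weights(w, 50), "percentile")
})

test_that("stabilized weights average 1 and balance a confounded cohort", {
  sim <- generate_cohort(sim_config(n = 5000, seed = 5))
  co <- sim$cohort
  cv <- c("z_age", "comorbidity", "baseline_event", "ses_low", "race")
  ps <- fit_propensity(co, "arm", cv)
  w <- stabilized_weights(ps, NULL, co)
  expect_lt(abs(mean(w$raw_weight) - 1), 0.02)

  # weighted arm totals over the total weight approximate the marginals
  wt <- tapply(w$final_weight, co$arm, sum) / sum(w$final_weight)
  expect_lt(max(abs(wt - table(co$arm) / nrow(co))), 0.02)

  wtr <- truncate_weights(w, 99, "cap")
  bal <- balance_diagnostics(co, wtr, cv)
  expect_lt(max(abs(bal$smd_weighted)), max(abs(bal$smd_unweighted)))

  # an intercept-only denominator model gives weight 1 exactly
  w0 <- stabilized_weights(fit_propensity(co, "arm"), NULL, co)
  expect_equal(w0$raw_weight, rep(1, nrow(co)), tolerance = 1e-12)
})

test_that("balance diagnostics respect identities and flag flat covariates", {
  set.seed(8)
  d <- data.frame(time = rexp(40) + 1, event = 1L,
                  arm = rep(c("a", "b"), 20),
                  x = rnorm(40), flat = 1,
                  g = sample(c("u", "v"), 40, TRUE))
  co <- as_cohort(d, covariates = c("x", "flat", "g"))
  ps <- fit_propensity(co, "arm")
  w <- stabilized_weights(ps, NULL, co)   # all weights 1
  bal <- balance_diagnostics(co, w, c("x", "flat", "g"))
  expect_equal(bal$smd_weighted, bal$smd_unweighted, tolerance = 1e-12)
  expect_true(all(bal$zero_variance[bal$term == "flat"]))
  expect_equal(bal$smd_unweighted[bal$term == "flat"], 0)
  ws <- attr(bal, "weight_summary")
  expect_equal(ws$ess, ws$n, tolerance = 1e-9)   # unit weights: ESS = n
  # identical distributions across arms: SMD near 0 for the duplicated cov
  d2 <- d; d2$x <- rep(d$x[1:20], 2); d2$arm <- rep(c("a", "b"), each = 20)
  co2 <- as_cohort(d2, covariates = "x")
  bal2 <- balance_diagnostics(co2, NULL, "x")
  expect_lt(max(abs(bal2$smd_unweighted)), 1e-9)
})
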