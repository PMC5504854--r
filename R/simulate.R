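#' Configuration for the synthetic multi-arm competing-risks cohort
#'
#' The simulator emulates the structure of a registry-based treatment
#' cohort: a control arm plus six active-treatment arms, baseline
#' confounders (age with minimum 66 years, a comorbidity score, a baseline
#' history of the event of interest, a low-socioeconomic-status indicator
#' and race), multinomial-logistic treatment assignment driven by those
#' confounders, two competing causes with constant (exponential)
#' cause-specific hazards of proportional-hazards form, independent
#' exponential censoring and administrative censoring at `t_max` days.
#'
#' With the default unit `weibull_shape` the cause-specific hazards are
#' constant, so the true cumulative incidence conditional on covariates has
#' the closed form implemented in [closed_form_cif()] and the true
#' cause-specific hazard ratios are known exactly -- the basis of the
#' package's recovery tests.
#'
#' The default assignment coefficients make healthier subjects (younger,
#' lower comorbidity, no baseline event, higher socioeconomic status) much
#' more likely to receive the surgical arms, while the same characteristics
#' lower both cause-specific hazards; this builds in strong measured
#' confounding (pre-weighting standardized mean differences above 0.25 on
#' several covariates).  `ses_low` and `race` influence assignment but not
#' the hazards, mirroring analyses whose propensity model is richer than
#' the outcome adjustment set.
#'
#' @param n number of subjects.
#' @param arms arm labels, reference (control) first.
#' @param assign_coef (A-1) x 7 matrix of multinomial-logistic assignment
#'   coefficients for the non-reference arms; columns `intercept`, `z_age`
#'   (standardized age, `(age - 70)/3`), `comorbidity` (0/1/2),
#'   `baseline_event` (0/1), `ses_low` (0/1), `race_black`, `race_other`.
#' @param hr1,hr2 true cause-specific hazard ratios per arm (reference 1)
#'   for the event of interest (cause 1) and the competing event (cause 2).
#' @param lambda10,lambda20 baseline (control, covariates at reference)
#'   cause-specific hazards per day.
#' @param beta1,beta2 log-hazard effects of `z_age`, `comorbidity` and
#'   `baseline_event` on each cause.
#' @param censor_rate rate (per day) of the independent exponential
#'   censoring time; 0 disables random censoring.
#' @param t_max administrative censoring horizon in days (10 years by the
#'   package's convention of 3650 days).
#' @param weibull_shape shape of the latent event-time distributions; 1
#'   (default) gives constant hazards and closed-form truth.
#' @param seed integer seed used by [generate_cohort()].
#' @return a validated `wcr_sim_config` list.
#' @export
sim_config <- function(n = 20000L,
                       arms = c("control", "EBRT", "BT", "BT+EBRT", "RP",
                                "RP+EBRT", "cryotherapy"),
                       assign_coef = NULL,
                       hr1 = c(1, 1.2, 1.6, 2.2, 2.8, 3.7, 1.75),
                       hr2 = c(1, 0.75, 0.45, 0.50, 0.40, 0.35, 0.30),
                       lambda10 = 1.3e-4, lambda20 = 1.8e-4,
                       beta1 = c(z_age = 0.15, comorbidity = 0.30,
                                 baseline_event = 0.80),
                       beta2 = c(z_age = 0.40, comorbidity = 0.50,
                                 baseline_event = 0.10),
                       censor_rate = 8e-5, t_max = 3650,
                       weibull_shape = 1, seed = 20170710L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  arms <- as.character(arms)
  A <- length(arms)
  if (A < 1L || anyDuplicated(arms)) stop("arms must be distinct labels")
  if (length(hr1) != A || length(hr2) != A)
    stop("hr1 and hr2 must have one entry per arm")
  if (hr1[1L] != 1 || hr2[1L] != 1)
    stop("the reference arm must have true hazard ratio 1 for both causes")
  if (any(hr1 < 0) || any(hr2 < 0) || lambda10 <= 0 || lambda20 < 0)
    stop("hazards must be positive (lambda20 may be 0)")
  if (censor_rate < 0 || t_max <= 0 || weibull_shape <= 0)
    stop("censor_rate must be >= 0, t_max and weibull_shape > 0")

  cols <- c("intercept", "z_age", "comorbidity", "baseline_event",
            "ses_low", "race_black", "race_other")
  if (is.null(assign_coef)) {
    assign_coef <- if (A == 1L) matrix(0, 0L, 7L) else
      rbind(                 #  int   z_age  comorb  base    ses   black  other
        EBRT          = c(-0.40,  0.15,  0.20,  0.20,  0.10, 0.10, 0.05),
        BT            = c(-0.55, -0.20, -0.30, -0.30, -0.40, -0.20, -0.20),
        `BT+EBRT`     = c(-0.55, -0.20, -0.30, -0.30, -0.50, -0.20, -0.20),
        RP            = c(-0.35, -0.35, -0.70, -0.85, -1.05, -0.35, -0.30),
        `RP+EBRT`     = c(-0.45, -0.30, -0.65, -0.75, -1.00, -0.35, -0.30),
        cryotherapy   = c(-0.60, -0.20, -0.30, -0.30, -0.50, -0.20, -0.20)
      )[seq_len(A - 1L), , drop = FALSE]
  }
  assign_coef <- as.matrix(assign_coef)
  if (nrow(assign_coef) != A - 1L || ncol(assign_coef) != 7L)
    stop("assign_coef must be a (number of arms - 1) x 7 matrix")
  colnames(assign_coef) <- cols
  rownames(assign_coef) <- arms[-1L]

  structure(list(n = n, arms = arms, assign_coef = assign_coef,
                 hr1 = setNames(hr1, arms), hr2 = setNames(hr2, arms),
                 lambda10 = lambda10, lambda20 = lambda20,
                 beta1 = beta1, beta2 = beta2,
                 censor_rate = censor_rate, t_max = t_max,
                 weibull_shape = weibull_shape, seed = as.integer(seed)),
            class = "wcr_sim_config")
}

#' Closed-form cumulative incidence under constant cause-specific hazards
#'
#' With constant hazards `lambda1` and `lambda2` the cumulative incidence
#' of cause 1 is `lambda1/(lambda1+lambda2) * (1 - exp(-(lambda1+lambda2)
#' t))`, the constant-hazard evaluation of
#' `I_1(t) = int_0^t lambda_1 S(x) dx`.
#'
#' @param lambda1,lambda2 non-negative cause-specific hazards (not both 0).
#' @param t evaluation time(s).
#' @return cumulative incidence of cause 1 at `t` (vectorized over `t`).
#' @examples
#' closed_form_cif(0.0002, 0.0004, 3650)
#' @export
closed_form_cif <- function(lambda1, lambda2, t) {
  if (any(lambda1 < 0) || any(lambda2 < 0)) stop("rates must be non-negative")
  if (any(lambda1 + lambda2 == 0)) stop("lambda1 and lambda2 must not both be 0")
  tot <- lambda1 + lambda2
  lambda1 / tot * (1 - exp(-tot * t))
}

#' Generate a synthetic confounded competing-risks cohort
#'
#' Draws confounders, assigns arms by the multinomial-logistic model, draws
#' latent cause-specific event times (exponential given arm and
#' confounders, or Weibull when `weibull_shape != 1`) and an independent
#' censoring time, and records the first of the latent times as the
#' observed time and event code (1 = event of interest, 2 = competing
#' event, 0 = censored).  Fully reproducible given `config$seed`.
#'
#' @param config a `wcr_sim_config`.
#' @return a list with elements `cohort` (a `wcr_cohort` with declared
#'   covariates `z_age`, `comorbidity`, `baseline_event`, `ses_low`, `race`
#'   plus a descriptive `age` column)
#'   and `truth` (true hazard ratios per cause, per-subject true hazards,
#'   assignment probabilities, marginal arm proportions, and `cif1(arm, t,
#'   z_age, comorbidity, baseline_event)`, the closed-form conditional
#'   cumulative incidence of cause 1 under unit shape).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "wcr_sim_config"))
  set.seed(config$seed)
  n <- config$n
  A <- length(config$arms)

  age <- 66 + rgamma(n, shape = 2, rate = 0.5)
  z_age <- (age - 70) / 3
  comorbidity <- sample(0:2, n, replace = TRUE, prob = c(0.55, 0.30, 0.15))
  baseline_event <- rbinom(n, 1L, 0.15)
  ses_low <- rbinom(n, 1L, 0.35)
  race <- factor(sample(c("white", "black", "other"), n, replace = TRUE,
                        prob = c(0.83, 0.10, 0.07)),
                 levels = c("white", "black", "other"))

  Z <- cbind(intercept = 1, z_age = z_age, comorbidity = comorbidity,
             baseline_event = baseline_event, ses_low = ses_low,
             race_black = as.numeric(race == "black"),
             race_other = as.numeric(race == "other"))
  eta <- cbind(0, Z %*% t(config$assign_coef))     # control column first
  eta <- eta - apply(eta, 1L, max)
  P <- exp(eta) / rowSums(exp(eta))
  if (A == 1L) {
    arm_idx <- rep(1L, n)
    runif(n)                                 # keep the draw count stable
  } else {
    cp <- t(apply(P, 1L, cumsum))
    arm_idx <- rowSums(runif(n) > cp) + 1L
  }
  arm <- factor(config$arms[arm_idx], levels = config$arms)

  lp1 <- log(config$hr1[arm_idx]) + drop(Z[, names(config$beta1)] %*% config$beta1)
  lp2 <- log(config$hr2[arm_idx]) + drop(Z[, names(config$beta2)] %*% config$beta2)
  lam1 <- config$lambda10 * exp(lp1)
  lam2 <- config$lambda20 * exp(lp2)

  shape <- config$weibull_shape
  draw_time <- function(rate) {
    tt <- rep(Inf, n)
    pos <- rate > 0
    e <- rexp(n)                             # one draw per subject, always
    tt[pos] <- (e[pos] / rate[pos])^(1 / shape)
    tt
  }
  T1 <- draw_time(lam1)
  T2 <- draw_time(lam2)
  C <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else rep(Inf, n)
  C <- pmin(C, config$t_max)

  time <- pmin(T1, T2, C)
  event <- integer(n)
  event[T1 <= time] <- 1L
  event[T2 <= time] <- 2L                    # continuous times: no cross ties
  event[C <= pmin(T1, T2)] <- 0L

  raw <- data.frame(time = time, event = event, arm = arm, age = age,
                    z_age = z_age, comorbidity = comorbidity,
                    baseline_event = baseline_event, ses_low = ses_low,
                    race = race)
  ## z_age (standardized) is the modeling covariate; raw age rides along as a
  ## descriptive column so the two never enter one design together
  cohort <- as_cohort(raw, covariates = c("z_age", "comorbidity",
                                          "baseline_event", "ses_low", "race"),
                      arm_levels = config$arms, causes = c(1L, 2L))
  cohort$age <- age

  p_event <- mean(1 - exp(-(lam1 + lam2) * config$t_max))
  if (p_event < 0.01)
    warning(sprintf("configuration yields expected event probability %.2f%% (< 1%%)",
                    100 * p_event))

  b1 <- config$beta1; b2 <- config$beta2
  truth <- list(
    hr1 = config$hr1, hr2 = config$hr2,
    lambda1 = lam1, lambda2 = lam2,
    assign_prob = P, arm_proportions = colMeans(P),
    expected_event_probability = p_event,
    cif1 = function(arm, t, z_age = 0, comorbidity = 0, baseline_event = 0) {
      if (shape != 1)
        stop("closed-form truth requires weibull_shape = 1")
      l1 <- config$lambda10 * config$hr1[arm] *
        exp(b1["z_age"] * z_age + b1["comorbidity"] * comorbidity +
            b1["baseline_event"] * baseline_event)
      l2 <- config$lambda20 * config$hr2[arm] *
        exp(b2["z_age"] * z_age + b2["comorbidity"] * comorbidity +
            b2["baseline_event"] * baseline_event)
      closed_form_cif(unname(l1), unname(l2), t)
    })
  list(cohort = cohort, truth = truth)
}

#' Small hand-checkable fixture cohort
#'
#' Emits a cohort of at most 12 subjects with integer times in 1..30, event
#' codes covering censoring and both causes, and simple rational weights
#' from \{0.5, 1, 1.5, 2\} -- sized so that every estimator in the package
#' can be verified by hand (or by day-by-day risk-set enumeration).  When
#' `file` is given, a companion text file tabulating the risk sets and the
#' resulting Kaplan-Meier, naive and Aalen-Johansen estimates is written
#' next to the data.
#'
#' @param size number of subjects (1..12).
#' @param seed integer seed.
#' @param file optional path for the companion worked-calculation file.
#' @return a `wcr_cohort` with a `weight` column.
#' @export
make_fixture_example <- function(size = 10L, seed = 1L, file = NULL) {
  size <- as.integer(size)
  if (size < 1L) stop("size must be at least 1")
  if (size > 12L) stop("the fixture example is meant to stay hand-checkable: size <= 12")
  set.seed(seed)
  time <- sort(sample(1:30, size, replace = FALSE))
  event <- sample(c(0L, 1L, 2L), size, replace = TRUE, prob = c(0.25, 0.45, 0.30))
  if (size >= 3L) { event[1L] <- 1L; event[2L] <- 2L; event[size] <- 0L }
  weight <- sample(c(0.5, 1, 1.5, 2), size, replace = TRUE)
  cohort <- as_cohort(data.frame(time = time, event = event, arm = "arm1",
                                 weight = weight),
                      weight = "weight")

  if (!is.null(file)) {
    rs <- build_risk_sets(cohort)
    km <- km_survival(rs)
    naive <- naive_km_cif(rs, 1L)
    aj1 <- competing_risks_cif(rs, 1L)
    aj2 <- competing_risks_cif(rs, 2L)
    tab <- data.frame(time = rs$time, n_risk = rs$n_risk,
                      d_1 = rs$d_1, d_2 = rs$d_2,
                      S_allcause = step_at(km, rs$time),
                      naive_cif1 = step_at(naive, rs$time),
                      aj_cif1 = step_at(aj1, rs$time),
                      aj_cif2 = step_at(aj2, rs$time))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(
      "Worked example: weighted risk sets and cumulative incidence",
      "subjects (time, event, weight):",
      paste(sprintf("  id %s: t=%g e=%d w=%g", cohort$subject_id,
                    cohort$time, cohort$event, cohort$weight),
            collapse = "\n"),
      "",
      "At each event time: n_risk = weight at risk, d_k = weighted cause-k events;",
      "S_allcause(t) = prod (1 - (d_1+d_2)/n);",
      "naive_cif1(t) = 1 - prod (1 - d_1/n)  (cause 2 censored);",
      "aj_cif1(t) = sum d_1/n * S_allcause(t-).", ""), con)
    write.table(format(tab, digits = 6), con, row.names = FALSE, quote = FALSE)
  }
  cohort
}
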