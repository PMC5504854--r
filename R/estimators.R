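## sequential cumulative product / sum with per-step double rounding, so the
## estimators are bit-identical to a step-by-step risk-set walk (base R's
## cumprod/cumsum accumulate in extended precision on x86)
cumprod_seq <- function(x) {
  acc <- 1
  for (i in seq_along(x)) { acc <- acc * x[i]; x[i] <- acc }
  x
}
cumsum_seq <- function(x) {
  acc <- 0
  for (i in seq_along(x)) { acc <- acc + x[i]; x[i] <- acc }
  x
}

#' Kaplan-Meier product-limit survival estimate
#'
#' `S(t) = prod_{t_j <= t} (1 - d_j / n_j)` over the distinct event times,
#' where `d_j` counts events whose cause lies in `cause_set` and `n_j` is
#' the number (or weight-sum) at risk.  Events of causes outside
#' `cause_set` contribute only to risk-set depletion, i.e. they are treated
#' as censored -- which is precisely what makes the resulting "naive"
#' cumulative incidence `1 - S` biased in the presence of competing events.
#'
#' The pointwise variance is Greenwood's formula
#' `S(t)^2 * sum d_j / (n_j (n_j - d_j))`; it is meaningful for unit
#' weights (for weighted curves use [bootstrap_ci()] instead).
#'
#' @param riskset a `wcr_riskset` from [build_risk_sets()].
#' @param cause_set causes counted as the event; defaults to all causes
#'   (all-cause, event-free survival).
#' @return a `wcr_step` of type `"survival"`.
#' @examples
#' co <- as_cohort(data.frame(time = c(2, 4, 5), event = c(1, 1, 0), arm = "A"))
#' km_survival(build_risk_sets(co))   # 1, 2/3 on [2,4), 1/3 on [4, Inf)
#' @export
km_survival <- function(riskset, cause_set = attr(riskset, "causes")) {
  stopifnot(inherits(riskset, "wcr_riskset"))
  causes <- attr(riskset, "causes")
  if (length(setdiff(cause_set, causes)) > 0L)
    stop("cause_set contains unknown cause(s): ",
         paste(setdiff(cause_set, causes), collapse = ", "))
  if (nrow(riskset) == 0L)
    return(new_step(numeric(0), numeric(0), origin = 1, type = "survival"))

  d <- rowSums(riskset[, paste0("d_", cause_set), drop = FALSE])
  n <- riskset$n_risk
  keep <- d > 0
  d <- d[keep]; n <- n[keep]
  if (length(d) == 0L)
    return(new_step(numeric(0), numeric(0), origin = 1, type = "survival"))
  s <- cumprod_seq(1 - d / n)
  gw <- ifelse(n > d, d / (n * (n - d)), NA_real_)
  new_step(riskset$time[keep], s, origin = 1, type = "survival",
           variance = s^2 * cumsum(gw))
}

#' Naive Kaplan-Meier cumulative incidence (competing events censored)
#'
#' Returns `1 - S_KM(t)` where the Kaplan-Meier estimate counts only
#' cause-`cause` events and censors all competing causes.  This estimator
#' overestimates the cumulative incidence whenever competing events occur;
#' it is provided deliberately for comparison with
#' [competing_risks_cif()].
#'
#' @inheritParams km_survival
#' @param cause the cause of interest.
#' @return a `wcr_step` of type `"cif"`.
#' @export
naive_km_cif <- function(riskset, cause = 1L) {
  s <- km_survival(riskset, cause_set = cause)
  new_step(s$time, 1 - s$value, origin = 0, type = "cif",
           variance = s$variance)
}

#' Aalen-Johansen competing-risks cumulative incidence
#'
#' The nonparametric cumulative incidence of cause `k`,
#' `I_k(t) = sum_{t_j <= t} (d_kj / n_j) * S(t_j-)`, where `S(t_j-)` is the
#' left-limit of the *all-cause* Kaplan-Meier survival estimate.  This is
#' the discrete analogue of `I_k(t) = int_0^t lambda_k(x) S(x) dx` and
#' correctly accounts for subjects removed from risk by competing events.
#' With weights, all counts are weight sums.
#'
#' @inheritParams naive_km_cif
#' @return a `wcr_step` of type `"cif"` (no analytic variance; use
#'   [bootstrap_ci()]).
#' @examples
#' co <- as_cohort(data.frame(time = c(1, 2), event = c(2, 1), arm = "A"))
#' rs <- build_risk_sets(co)
#' cif_at(competing_risks_cif(rs, 1), 2)  # 0.5; the naive estimate is 1
#' cif_at(naive_km_cif(rs, 1), 2)
#' @export
competing_risks_cif <- function(riskset, cause = 1L) {
  stopifnot(inherits(riskset, "wcr_riskset"))
  causes <- attr(riskset, "causes")
  if (!cause %in% causes) stop("unknown cause: ", cause)
  if (nrow(riskset) == 0L)
    return(new_step(numeric(0), numeric(0), origin = 0, type = "cif"))

  n <- riskset$n_risk
  dtot <- rowSums(riskset[, paste0("d_", causes), drop = FALSE])
  dk <- riskset[[paste0("d_", cause)]]
  s_all <- cumprod_seq(1 - dtot / n)
  s_prev <- c(1, s_all[-length(s_all)])
  inc <- (dk / n) * s_prev
  cif <- cumsum_seq(inc)
  keep <- inc > 0
  new_step(riskset$time[keep], cif[keep], origin = 0, type = "cif")
}

#' Percentile bootstrap confidence interval for a cohort-level statistic
#'
#' Resamples subjects with replacement, re-runs the full analysis pipeline
#' (including any weight re-estimation the `statistic` closure performs) on
#' each resample, and returns the percentile interval of the resulting
#' statistic.  Replicates on which the statistic is degenerate (returns
#' `NA`, e.g. no events of the target cause in the resample) are excluded
#' and counted.
#'
#' @param cohort a `wcr_cohort`.
#' @param statistic function taking a resampled `wcr_cohort` and returning
#'   a single numeric value (or `NA` for a degenerate resample).
#' @param reps number of bootstrap replicates (>= 2).
#' @param seed integer seed; the interval is reproducible given the seed.
#' @param level confidence level (default 0.95: the 2.5th and 97.5th
#'   percentiles).
#' @return a `wcr_boot` list: `estimate` (full-sample statistic), `lower`,
#'   `upper`, `level`, `reps`, `degenerate`, `replicates`.
#' @export
bootstrap_ci <- function(cohort, statistic, reps = 200L, seed = 1L,
                         level = 0.95) {
  stopifnot(inherits(cohort, "wcr_cohort"), is.function(statistic))
  if (reps < 2L) stop("reps must be at least 2")
  n <- nrow(cohort)
  est <- statistic(cohort)

  set.seed(seed)
  vals <- vapply(seq_len(reps), function(r) {
    statistic(resample_cohort(cohort, sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) stop("every bootstrap replicate was degenerate")
  alpha <- (1 - level) / 2
  qs <- quantile(vals[ok], c(alpha, 1 - alpha), type = 7, names = FALSE)
  structure(list(estimate = est, lower = qs[1L], upper = qs[2L],
                 level = level, reps = reps, degenerate = sum(!ok),
                 replicates = vals),
            class = "wcr_boot")
}

#' @export
print.wcr_boot <- function(x, ...) {
  cat(sprintf("<wcr_boot> estimate %.4g, %d%% percentile CI (%.4g, %.4g) from %d rep(s)",
              x$estimate, round(100 * x$level), x$lower, x$upper, x$reps))
  if (x$degenerate > 0L) cat(sprintf(" [%d degenerate excluded]", x$degenerate))
  cat("\n")
  invisible(x)
}

#' Export a step function to CSV
#'
#' Writes columns `time`, `value` and (when present) `variance`.
#'
#' @param fn a `wcr_step`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_step <- function(fn, path) {
  stopifnot(inherits(fn, "wcr_step"))
  write.csv(as.data.frame(fn), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
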