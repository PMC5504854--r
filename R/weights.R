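#' Stabilized inverse-probability-of-treatment weights
#'
#' Builds per-subject stabilized IPT weights from one or two propensity fits.
#' With a single fit, every subject receives
#' `P(observed level) / P(observed level | X)`, the marginal level proportion
#' over the fitted conditional propensity of the assignment actually
#' received.  With a two-stage design (a binary case/control membership model
#' fitted on the full cohort plus a treatment model fitted on cases only),
#' control subjects receive the stabilized inverse probability of membership
#' alone, and cases receive the product of the stabilized inverse membership
#' probability and the stabilized inverse probability of the treatment
#' received.
#'
#' Stabilization makes the weights average approximately 1, so the weighted
#' pseudo-population has (up to truncation) the size of the original cohort.
#'
#' @param stage1 a `wcr_propensity` fitted on the full cohort.
#' @param stage2 optional `wcr_propensity` fitted on the case subset
#'   (requires a binary `stage1`).
#' @param cohort the `wcr_cohort` both fits refer to.
#' @param case_level label of the `stage1` level identifying cases; defaults
#'   to the second (non-reference) level.
#' @param prob_floor denominator probabilities below this value are reported
#'   in the `flagged` attribute rather than silently used.
#' @return a `wcr_weights` data.frame with columns `subject_id`,
#'   `numerator_prob`, `denominator_prob`, `raw_weight`, `final_weight`,
#'   `truncated`, and attributes `truncation` (mode/percentile/cutoff),
#'   `flagged` (subject ids with tiny denominators) and `removed`.
#' @seealso [truncate_weights()], [balance_diagnostics()]
#' @export
stabilized_weights <- function(stage1, stage2 = NULL, cohort,
                               case_level = NULL, prob_floor = 1e-6) {
  stopifnot(inherits(stage1, "wcr_propensity"), inherits(cohort, "wcr_cohort"))
  if (!identical(stage1$subject_id, cohort$subject_id))
    stop("stage1 fit does not align with the cohort (subject ids differ)")

  num <- as.numeric(stage1$marginal[as.character(stage1$y)])
  den <- stage1$prob_observed

  if (!is.null(stage2)) {
    stopifnot(inherits(stage2, "wcr_propensity"))
    if (length(stage1$levels) != 2L)
      stop("two-stage weights require a binary stage1 (case/control membership)")
    case_level <- case_level %||% stage1$levels[2L]
    if (!case_level %in% stage1$levels)
      stop("case_level '", case_level, "' is not a stage1 level")
    is_case <- as.character(stage1$y) == case_level
    if (!identical(stage2$subject_id, cohort$subject_id[is_case]))
      stop("stage2 must be fitted on exactly the case subset of the cohort")
    num2 <- rep(1, nrow(cohort))
    den2 <- rep(1, nrow(cohort))
    num2[is_case] <- as.numeric(stage2$marginal[as.character(stage2$y)])
    den2[is_case] <- stage2$prob_observed
    num <- num * num2
    den <- den * den2
  }

  raw <- num / den
  out <- data.frame(subject_id = cohort$subject_id,
                    numerator_prob = num, denominator_prob = den,
                    raw_weight = raw, final_weight = raw,
                    truncated = FALSE, stringsAsFactors = FALSE)
  attr(out, "truncation") <- list(mode = "none", percentile = NA_real_,
                                  cutoff = NA_real_)
  attr(out, "flagged") <- cohort$subject_id[den < prob_floor]
  attr(out, "removed") <- out[0L, ]
  class(out) <- c("wcr_weights", "data.frame")
  out
}

#' Truncate extreme IPT weights at a percentile
#'
#' The cutoff is the requested percentile of the *raw* weights, computed with
#' linear interpolation between order statistics (R quantile type 7); basing
#' the cutoff on the raw weights makes cap-mode truncation idempotent.  Cap
#' mode replaces every weight above the cutoff by the cutoff; delete mode
#' removes those subjects and records the removals.
#'
#' @param weights a `wcr_weights`.
#' @param percentile percentile in (50, 100]; the conventional default is 99.
#' @param mode `"cap"` (default) or `"delete"`.
#' @return a `wcr_weights` with updated `final_weight`, `truncated` flags and
#'   `truncation`/`removed` attributes.
#' @export
truncate_weights <- function(weights, percentile = 99,
                             mode = c("cap", "delete")) {
  stopifnot(inherits(weights, "wcr_weights"))
  mode <- match.arg(mode)
  if (!is.numeric(percentile) || percentile <= 50 || percentile > 100)
    stop("percentile must lie in (50, 100]; a cutoff at or below the median ",
         "would discard most of the sample")

  cutoff <- unname(quantile(weights$raw_weight, percentile / 100,
                            type = 7, names = FALSE))
  above <- weights$raw_weight > cutoff
  out <- weights
  if (mode == "cap") {
    out$final_weight <- pmin(out$raw_weight, cutoff)
    out$truncated <- above
    attr(out, "removed") <- weights[0L, ]
  } else {
    removed <- as.data.frame(weights)[above, , drop = FALSE]
    out <- weights[!above, , drop = FALSE]
    out$final_weight <- out$raw_weight
    out$truncated <- FALSE
    attr(out, "flagged") <- attr(weights, "flagged")
    attr(out, "removed") <- removed
    class(out) <- c("wcr_weights", "data.frame")
  }
  attr(out, "truncation") <- list(mode = mode, percentile = percentile,
                                  cutoff = cutoff)
  out
}

#' Export a weight set to CSV
#'
#' @param weights a `wcr_weights`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "wcr_weights"))
  write.csv(as.data.frame(weights), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.wcr_weights <- function(x, ...) {
  tr <- attr(x, "truncation")
  cat(sprintf("<wcr_weights> %d subject(s); mean %.4f, max %.3f; truncation: %s",
              nrow(x), mean(x$final_weight), max(x$final_weight), tr$mode))
  if (!is.na(tr$percentile))
    cat(sprintf(" at p%.4g (cutoff %.4g)", tr$percentile, tr$cutoff))
  cat("\n")
  fl <- attr(x, "flagged")
  if (length(fl) > 0L)
    cat(sprintf("  %d subject(s) flagged for denominator probability below floor\n",
                length(fl)))
  rm <- attr(x, "removed")
  if (nrow(rm) > 0L) cat(sprintf("  %d subject(s) removed by truncation\n", nrow(rm)))
  invisible(x)
}

## weighted mean / variance with frequency-weight normalization so that unit
## weights reproduce mean()/var() exactly
wtd_mean <- function(x, w) sum(w * x) / sum(w)
wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / (sum(w) - 1)
}

#' Covariate balance diagnostics for IPT weights
#'
#' Standardized mean differences (SMD) of every covariate (categorical
#' covariates expanded to level indicators) between each arm and the
#' reference arm, before and after weighting.  The SMD is the difference of
#' (weighted) means over the pooled standard deviation
#' `sqrt((v_arm + v_ref)/2)`; a zero pooled variance yields SMD 0 with a
#' flag.  Weighted moments use the final (truncated) weights.
#'
#' @param cohort a `wcr_cohort` with at least two arms.
#' @param weights a `wcr_weights`, or `NULL` for unweighted diagnostics only.
#' @param covariates covariate columns to assess; defaults to the cohort's
#'   declared covariates.
#' @return a `wcr_balance` data.frame with columns `term`, `arm`,
#'   `smd_unweighted`, `smd_weighted`, `zero_variance`, and a
#'   `weight_summary` attribute (per-arm n, weight sum, mean, max and
#'   effective sample size).
#' @export
balance_diagnostics <- function(cohort, weights = NULL,
                                covariates = attr(cohort, "covariates")) {
  stopifnot(inherits(cohort, "wcr_cohort"))
  if (nlevels(droplevels(cohort$arm)) < 2L)
    stop("balance diagnostics require at least two arms")
  if (length(covariates) == 0L) stop("no covariates to assess")

  if (is.null(weights)) {
    w <- rep(1, nrow(cohort))
  } else {
    stopifnot(inherits(weights, "wcr_weights"))
    keep <- cohort$subject_id %in% weights$subject_id
    cohort <- cohort[keep, , drop = FALSE]
    w <- weights$final_weight[match(cohort$subject_id, weights$subject_id)]
  }

  ## expand covariates: numeric kept as-is, categorical to level indicators
  cols <- list()
  for (cv in covariates) {
    x <- cohort[[cv]]
    if (is.numeric(x)) {
      cols[[cv]] <- as.numeric(x)
    } else {
      x <- factor(x)
      for (lv in levels(x)) cols[[paste0(cv, ":", lv)]] <- as.numeric(x == lv)
    }
  }

  arm <- droplevels(cohort$arm)
  ref <- levels(arm)[1L]
  others <- levels(arm)[-1L]
  iref <- arm == ref

  res <- do.call(rbind, lapply(others, function(a) {
    ia <- arm == a
    do.call(rbind, lapply(names(cols), function(tm) {
      x <- cols[[tm]]
      smd1 <- smd(x[ia], x[iref], rep(1, sum(ia)), rep(1, sum(iref)))
      smd2 <- smd(x[ia], x[iref], w[ia], w[iref])
      data.frame(term = tm, arm = a,
                 smd_unweighted = smd1$d, smd_weighted = smd2$d,
                 zero_variance = smd1$flat && smd2$flat,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL

  ws <- do.call(rbind, lapply(levels(arm), function(a) {
    wa <- w[arm == a]
    data.frame(arm = a, n = length(wa), sum_weight = sum(wa),
               mean_weight = mean(wa), max_weight = max(wa),
               ess = sum(wa)^2 / sum(wa^2), stringsAsFactors = FALSE)
  }))
  attr(res, "weight_summary") <- ws
  class(res) <- c("wcr_balance", "data.frame")
  res
}

smd <- function(xa, xr, wa, wr) {
  pooled <- sqrt((wtd_var(xa, wa) + wtd_var(xr, wr)) / 2)
  if (!is.finite(pooled) || pooled == 0)
    return(list(d = 0, flat = TRUE))
  list(d = (wtd_mean(xa, wa) - wtd_mean(xr, wr)) / pooled, flat = FALSE)
}

#' @export
print.wcr_balance <- function(x, digits = 3, ...) {
  cat(sprintf("<wcr_balance> %d term(s) x %d arm(s); max |SMD| unweighted %.3f, weighted %.3f\n",
              length(unique(x$term)), length(unique(x$arm)),
              max(abs(x$smd_unweighted)), max(abs(x$smd_weighted))))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
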