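#' Run the full four-estimator comparison analysis
#'
#' Orchestrates the package pipeline on one cohort: propensity estimation
#' (a single multinomial model of arm membership, skipped when weights are
#' supplied), stabilized-weight construction and truncation, the four
#' per-arm cumulative-incidence variants at the reporting horizon
#' (unweighted and IPT-weighted naive Kaplan-Meier, unweighted and
#' IPT-weighted Aalen-Johansen competing-risks), unweighted and
#' IPT-weighted cause-specific Cox models, and covariate balance
#' diagnostics.
#'
#' @param cohort a `wcr_cohort` whose first arm level is the control arm.
#' @param propensity_covariates covariates of the propensity model;
#'   defaults to the cohort's declared covariates.
#' @param adjust adjustment covariates of the Cox models.
#' @param cause the cause of interest.
#' @param horizon reporting horizon in days (default 3650 = 10 years).
#' @param truncation_percentile,truncation_mode weight truncation settings,
#'   see [truncate_weights()].
#' @param ties tie handling for the Cox fits.
#' @param weights optional pre-computed `wcr_weights`; skips propensity
#'   estimation and truncation.
#' @param verbose log stage progress to stderr.
#' @return a `wcr_report` list: `cif` (per-arm data.frame with columns
#'   `km_unweighted`, `km_weighted`, `cr_unweighted`, `cr_weighted`),
#'   `hr` (per-arm hazard-ratio table for the unweighted and weighted Cox
#'   fits, or `NULL` with `hr_note` for a single-arm cohort), `fits`,
#'   `balance`, `weights`, `curves` (per arm and variant), `meta`.
#' @export
run_analysis <- function(cohort,
                         propensity_covariates = attr(cohort, "covariates"),
                         adjust = character(), cause = 1L, horizon = 3650,
                         truncation_percentile = 99,
                         truncation_mode = "cap",
                         ties = "breslow", weights = NULL, verbose = TRUE) {
  stopifnot(inherits(cohort, "wcr_cohort"))
  say <- function(...) if (verbose) message(sprintf(...))
  arm <- droplevels(cohort$arm)
  arms <- levels(arm)
  say("stage 1/4: weights (%d subjects, %d arms)", nrow(cohort), length(arms))

  if (is.null(weights)) {
    if (length(arms) > 1L) {
      ps <- fit_propensity(cohort, "arm", propensity_covariates)
      weights <- stabilized_weights(ps, NULL, cohort)
      weights <- truncate_weights(weights, truncation_percentile,
                                  truncation_mode)
    } else {
      ps <- NULL
      weights <- NULL   # single arm: weighting is a no-op, keep unit weights
    }
  } else {
    stopifnot(inherits(weights, "wcr_weights"))
    ps <- NULL
  }

  say("stage 2/4: cumulative incidence at %g days", horizon)
  wcohort <- if (is.null(weights)) cohort else {
    cohort[cohort$subject_id %in% weights$subject_id, , drop = FALSE]
  }
  curves <- list()
  cif <- do.call(rbind, lapply(arms, function(a) {
    sub_u <- cohort[cohort$arm == a, , drop = FALSE]
    rs_u <- build_risk_sets(sub_u, weights = rep(1, nrow(sub_u)))
    sub_w <- wcohort[wcohort$arm == a, , drop = FALSE]
    rs_w <- if (is.null(weights)) rs_u else build_risk_sets(sub_w, weights)
    cv <- list(km_unweighted = naive_km_cif(rs_u, cause),
               km_weighted = naive_km_cif(rs_w, cause),
               cr_unweighted = competing_risks_cif(rs_u, cause),
               cr_weighted = competing_risks_cif(rs_w, cause))
    curves[[a]] <<- cv
    data.frame(arm = a, n = nrow(sub_u),
               km_unweighted = cif_at(cv$km_unweighted, horizon),
               km_weighted = cif_at(cv$km_weighted, horizon),
               cr_unweighted = cif_at(cv$cr_unweighted, horizon),
               cr_weighted = cif_at(cv$cr_weighted, horizon),
               stringsAsFactors = FALSE)
  }))

  if (length(arms) > 1L) {
    say("stage 3/4: cause-specific Cox models (cause %d)", cause)
    fit_u <- fit_cause_specific_cox(cohort, cause = cause, adjust = adjust,
                                    ties = ties)
    fit_w <- fit_cause_specific_cox(cohort, cause = cause, adjust = adjust,
                                    weights = weights, ties = ties)
    hr <- hazard_ratio_table(list(unweighted = fit_u, weighted = fit_w))
    hr_note <- NULL
    fits <- list(unweighted = fit_u, weighted = fit_w)
    say("stage 4/4: balance diagnostics")
    balance <- if (length(propensity_covariates))
      balance_diagnostics(cohort, weights, propensity_covariates) else NULL
  } else {
    hr <- NULL
    hr_note <- "single-arm cohort: hazard ratios require a comparison arm"
    fits <- list()
    balance <- NULL
    say("stage 3/4 and 4/4 skipped: single arm")
  }

  structure(list(cif = cif, hr = hr, hr_note = hr_note, fits = fits,
                 balance = balance, weights = weights, curves = curves,
                 meta = list(horizon = horizon, cause = cause,
                             n = nrow(cohort), arms = arms,
                             truncation_percentile = truncation_percentile,
                             truncation_mode = truncation_mode, ties = ties,
                             package_version = as.character(utils::packageVersion("wcr")))),
            class = "wcr_report")
}

## the estimator-dominance invariant: within every arm and weighting
## variant the naive KM incidence is at least the competing-risks incidence
check_dominance <- function(report, tol = 1e-12) {
  cif <- report$cif
  bad <- cif$cr_unweighted > cif$km_unweighted + tol |
         cif$cr_weighted > cif$km_weighted + tol
  if (any(bad)) {
    print(cif[bad, ])
    stop("internal inconsistency: competing-risks cumulative incidence ",
         "exceeds the naive Kaplan-Meier incidence for the arm(s) above")
  }
  invisible(TRUE)
}

#' Render an analysis report
#'
#' `"text"` produces the four-block comparison layout (unweighted KM,
#' IPT-weighted KM, unweighted competing risks, IPT-weighted competing
#' risks; cumulative incidences as percentages to one decimal, hazard
#' ratios to two decimals with confidence interval).  `"csv"` produces one
#' tidy row per (arm, variant, statistic).  The estimator-dominance
#' invariant is asserted before rendering.
#'
#' @param report a `wcr_report`.
#' @param format `"text"` or `"csv"`.
#' @param file optional output path.
#' @return character vector (text) or data.frame (csv), invisibly when
#'   written to `file`.
#' @export
render_report <- function(report, format = c("text", "csv"), file = NULL) {
  stopifnot(inherits(report, "wcr_report"))
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown format '", format[1L], "'; supported formats: text, csv"))
  check_dominance(report)
  cif <- report$cif
  arms <- cif$arm

  if (format == "csv") {
    long <- do.call(rbind, lapply(c("km_unweighted", "km_weighted",
                                    "cr_unweighted", "cr_weighted"), function(v) {
      data.frame(arm = arms, variant = v, statistic = "cif_at_horizon",
                 value = cif[[v]], stringsAsFactors = FALSE)
    }))
    if (!is.null(report$hr)) {
      for (m in c("unweighted", "weighted")) {
        for (s in c("hr", "lower", "upper")) {
          long <- rbind(long, data.frame(
            arm = report$hr$arm, variant = paste0("cox_", m), statistic = s,
            value = report$hr[[paste0(m, "_", s)]], stringsAsFactors = FALSE))
        }
      }
    }
    out <- long
  } else {
    pct <- function(x) sprintf("%.1f", 100 * x)
    hrfmt <- function(h, l, u)
      ifelse(is.na(l), "1 (ref)", sprintf("%.2f (%.2f, %.2f)", h, l, u))
    w <- max(nchar(arms), 19L) + 2L
    pad <- function(x) formatC(x, width = w)
    row <- function(label, cells) paste0(formatC(label, width = -34), paste(pad(cells), collapse = ""))
    lines <- c(
      row("", arms),
      row("Subjects (n)", cif$n),
      "Un-weighted KM",
      row(sprintf("  10-yr cumulative incidence (%%)"), pct(cif$km_unweighted)),
      "IPT-weighted KM",
      row(sprintf("  10-yr cumulative incidence (%%)"), pct(cif$km_weighted)),
      "Un-weighted CR",
      row(sprintf("  10-yr cumulative incidence (%%)"), pct(cif$cr_unweighted)))
    if (!is.null(report$hr))
      lines <- c(lines, row("  HR (95% CI)",
                            hrfmt(report$hr$unweighted_hr,
                                  report$hr$unweighted_lower,
                                  report$hr$unweighted_upper)))
    lines <- c(lines, "IPT-weighted CR",
               row(sprintf("  10-yr cumulative incidence (%%)"), pct(cif$cr_weighted)))
    if (!is.null(report$hr))
      lines <- c(lines, row("  HR (95% CI)",
                            hrfmt(report$hr$weighted_hr,
                                  report$hr$weighted_lower,
                                  report$hr$weighted_upper)))
    if (!is.null(report$hr_note)) lines <- c(lines, "", report$hr_note)
    out <- lines
  }

  if (!is.null(file)) {
    if (format == "csv") write.csv(out, file, row.names = FALSE,
                                   fileEncoding = "UTF-8")
    else writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @export
print.wcr_report <- function(x, ...) {
  cat(paste(render_report(x, "text"), collapse = "\n"), "\n")
  invisible(x)
}
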