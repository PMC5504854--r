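#' Risk-set series at the distinct event times
#'
#' For each distinct time at which any event (of any cause) occurs, computes
#' the weight-sum at risk `n_j` (all subjects with follow-up time `>= t_j`;
#' subjects exit the risk set immediately after their event or censoring
#' time) and the per-cause weighted event counts `d_kj`.  Without weights,
#' counts are subject counts.  Tied times of different causes are pooled
#' into a single row.
#'
#' @param cohort a `wcr_cohort`.
#' @param weights per-subject weights: a `wcr_weights` (matched by subject
#'   id; delete-mode truncation drops the removed subjects), a numeric
#'   vector aligned with the cohort rows, or `NULL` for the cohort's
#'   `weight` column (all 1 if absent).
#' @return a `wcr_riskset` data.frame with columns `time`, `n_risk` and one
#'   `d_<k>` column per cause, plus attributes `causes` and `total_weight`.
#' @examples
#' co <- as_cohort(data.frame(time = 1:3, event = 1, arm = "A"))
#' build_risk_sets(co)   # n = 3,2,1; d_1 = 1,1,1
#' @export
build_risk_sets <- function(cohort, weights = NULL) {
  stopifnot(inherits(cohort, "wcr_cohort"))
  rw <- resolve_weights(cohort, weights)
  cohort <- rw$cohort
  w <- rw$w

  tvec <- cohort$time
  evec <- cohort$event
  causes <- attr(cohort, "causes") %||% sort(unique(evec[evec > 0]))

  ut <- sort(unique(tvec[evec %in% causes]))
  ## weight leaving the risk set at each distinct follow-up time
  uall <- sort(unique(tvec))
  removed <- rowsum(w, tvec)[, 1L]          # ordered by sort(unique(tvec))
  cum_removed <- cumsum(removed)
  total <- sum(w)
  ## n at ut_j = total - weight of subjects with time < ut_j
  pos <- match(ut, uall)
  n_risk <- total - c(0, cum_removed)[pos]

  out <- data.frame(time = ut, n_risk = n_risk)
  for (k in causes) {
    dk <- numeric(length(ut))
    sel <- evec == k
    if (any(sel)) {
      dk_s <- rowsum(w[sel], tvec[sel])[, 1L]
      dk[match(sort(unique(tvec[sel])), ut)] <- dk_s
    }
    out[[paste0("d_", k)]] <- dk
  }
  attr(out, "causes") <- causes
  attr(out, "total_weight") <- total
  class(out) <- c("wcr_riskset", "data.frame")
  out
}

## normalize the weights argument; restrict the cohort when a delete-mode
## weight set no longer covers every subject
resolve_weights <- function(cohort, weights) {
  if (is.null(weights)) {
    w <- if ("weight" %in% names(cohort)) cohort$weight else rep(1, nrow(cohort))
  } else if (inherits(weights, "wcr_weights")) {
    keep <- cohort$subject_id %in% weights$subject_id
    cohort <- cohort[keep, , drop = FALSE]
    w <- weights$final_weight[match(cohort$subject_id, weights$subject_id)]
  } else if (is.numeric(weights)) {
    if (length(weights) != nrow(cohort))
      stop("numeric weights must align with the cohort rows")
    w <- as.numeric(weights)
  } else stop("weights must be NULL, a numeric vector or a wcr_weights object")
  if (anyNA(w) || any(w <= 0)) stop("weights must be positive and non-missing")
  list(cohort = cohort, w = w)
}

#' @export
print.wcr_riskset <- function(x, ...) {
  cat(sprintf("<wcr_riskset> %d event time(s), %d cause(s), total weight %.4g\n",
              nrow(x), length(attr(x, "causes")), attr(x, "total_weight")))
  print.data.frame(head(x, 10L), ...)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
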