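#' Build a cohort table from a data frame
#'
#' A cohort table is the subject-level input of every estimator in the
#' package: one row per subject with a positive follow-up time in days, an
#' integer event code (0 = censored, 1 = event of interest, 2, ... =
#' competing causes), a treatment-arm label whose first level is the
#' reference (control) arm, optional baseline covariates and an optional
#' positive per-subject weight.
#'
#' @param data a data.frame holding the raw columns.
#' @param time,event,arm names of the follow-up time, event-code and arm
#'   columns in `data`.
#' @param id optional name of a subject-identifier column; defaults to the
#'   row sequence.
#' @param reference label of the reference (control) arm; defaults to the
#'   first arm level encountered.
#' @param covariates character vector of baseline covariate columns to
#'   carry along (used by propensity models and balance diagnostics).
#' @param weight optional name of a pre-computed weight column.
#' @param arm_levels optional explicit arm level order (reference first after
#'   releveling); useful to preserve a declared order across CSV round trips.
#' @param causes integer vector of admissible non-zero event codes.
#'   Default `c(1, 2)`: event of interest and one competing cause.
#' @return a `wcr_cohort` data.frame with canonical columns `subject_id`,
#'   `time`, `event`, `arm`, the covariates, and optionally `weight`.
#' @examples
#' d <- data.frame(t = c(2, 4, 5), e = c(1, 2, 0), g = "A")
#' as_cohort(d, time = "t", event = "e", arm = "g")
#' @export
as_cohort <- function(data, time = "time", event = "event", arm = "arm",
                      id = NULL, reference = NULL, covariates = character(),
                      weight = NULL, arm_levels = NULL, causes = c(1L, 2L)) {
  stopifnot(is.data.frame(data))
  need <- c(time, event, arm, covariates, id, weight)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L)
    stop("column(s) not found in data: ", paste(miss, collapse = ", "))

  n <- nrow(data)
  tm <- data[[time]]
  if (!is.numeric(tm)) {
    raw <- as.character(tm)
    tm <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(tm) & !is.na(raw) & nzchar(raw))
    if (length(bad) > 0L)
      stop("unparseable time value in row(s): ",
           paste(head(bad, 5L), collapse = ", "))
  }
  if (anyNA(tm)) stop("missing time in row(s): ",
                      paste(head(which(is.na(tm)), 5L), collapse = ", "))
  if (any(tm <= 0)) stop("non-positive time in row(s): ",
                         paste(head(which(tm <= 0), 5L), collapse = ", "))

  ev <- data[[event]]
  if (!is.numeric(ev)) ev <- suppressWarnings(as.numeric(as.character(ev)))
  if (anyNA(ev) || any(ev != floor(ev)))
    stop("event codes must be non-missing integers (0 = censored)")
  ev <- as.integer(ev)
  causes <- sort(unique(as.integer(causes)))
  bad <- which(!ev %in% c(0L, causes))
  if (length(bad) > 0L)
    stop("event code outside {0, ", paste(causes, collapse = ", "),
         "} in row(s): ", paste(head(bad, 5L), collapse = ", "))

  a <- data[[arm]]
  if (anyNA(a)) stop("missing arm label in row(s): ",
                     paste(head(which(is.na(a)), 5L), collapse = ", "))
  a <- if (is.null(arm_levels)) factor(as.character(a))   # sorted levels
       else factor(as.character(a), levels = arm_levels)
  if (anyNA(a)) stop("arm label outside the declared arm_levels")
  if (!is.null(reference)) {
    if (!reference %in% levels(a))
      stop("reference arm '", reference, "' not present among arm labels")
    a <- stats::relevel(a, ref = reference)
  }

  sid <- if (is.null(id)) as.character(seq_len(n)) else as.character(data[[id]])
  if (anyDuplicated(sid)) stop("subject ids are not unique")

  out <- data.frame(subject_id = sid, time = as.numeric(tm), event = ev,
                    arm = a, stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- data[[cv]]
  if (!is.null(weight)) {
    w <- data[[weight]]
    if (!is.numeric(w) || anyNA(w) || any(w <= 0))
      stop("weights must be positive and non-missing")
    out$weight <- as.numeric(w)
  }
  attr(out, "covariates") <- covariates
  attr(out, "causes") <- causes
  class(out) <- c("wcr_cohort", "data.frame")
  out
}

#' Read a cohort table from a CSV file
#'
#' Comma-separated, header row required, UTF-8; missing values are not
#' permitted in the required columns.  Column names are mapped through the
#' same schema arguments as [as_cohort()].
#'
#' @inheritParams as_cohort
#' @param path path to a CSV file.
#' @return a `wcr_cohort`.
#' @export
read_cohort <- function(path, time = "time", event = "event", arm = "arm",
                        id = NULL, reference = NULL,
                        covariates = character(), weight = NULL,
                        arm_levels = NULL, causes = c(1L, 2L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_cohort(raw, time = time, event = event, arm = arm, id = id,
            reference = reference, covariates = covariates, weight = weight,
            arm_levels = arm_levels, causes = causes)
}

#' Write a cohort table to CSV
#'
#' @param cohort a `wcr_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "wcr_cohort"))
  out <- as.data.frame(cohort)
  out$arm <- as.character(out$arm)
  for (cv in names(out)) if (is.factor(out[[cv]])) out[[cv]] <- as.character(out[[cv]])
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the cohort invariants and returns findings instead of raising:
#' positive times, admissible event codes, presence of the reference arm,
#' positive weights, no missing required values.
#'
#' @param cohort a `wcr_cohort` (or plain data.frame with canonical columns).
#' @param reference reference arm label; defaults to the first arm level.
#' @return character vector of findings; empty when all invariants hold.
#' @export
validate_cohort <- function(cohort, reference = NULL) {
  findings <- character()
  req <- c("subject_id", "time", "event", "arm")
  miss <- setdiff(req, names(cohort))
  if (length(miss) > 0L)
    return(paste("missing required column(s):", paste(miss, collapse = ", ")))

  if (anyNA(cohort$time))
    findings <- c(findings, sprintf("missing time in %d row(s)", sum(is.na(cohort$time))))
  bad <- sum(cohort$time <= 0, na.rm = TRUE)
  if (bad > 0L)
    findings <- c(findings, sprintf("non-positive time in %d row(s)", bad))

  causes <- attr(cohort, "causes") %||% sort(unique(cohort$event[cohort$event > 0]))
  bad <- sum(!cohort$event %in% c(0L, causes), na.rm = TRUE)
  if (bad > 0L || anyNA(cohort$event))
    findings <- c(findings, sprintf("unknown or missing event code in %d row(s)",
                                    bad + sum(is.na(cohort$event))))

  arm <- factor(cohort$arm)
  ref <- reference %||% levels(arm)[1L]
  if (!ref %in% as.character(cohort$arm))
    findings <- c(findings, sprintf("reference arm '%s' has no subjects", ref))

  if ("weight" %in% names(cohort)) {
    bad <- sum(is.na(cohort$weight) | cohort$weight <= 0)
    if (bad > 0L)
      findings <- c(findings, sprintf("non-positive or missing weight in %d row(s)", bad))
  }
  findings
}

#' @export
print.wcr_cohort <- function(x, ...) {
  cat(sprintf("<wcr_cohort> %d subjects, %d arm(s) (reference '%s')\n",
              nrow(x), nlevels(x$arm), levels(x$arm)[1L]))
  ev <- table(factor(x$event, levels = c(0L, attr(x, "causes"))))
  cat("  events:", paste(sprintf("code %s: %d", names(ev), ev), collapse = ", "), "\n")
  cv <- attr(x, "covariates")
  if (length(cv) > 0L) cat("  covariates:", paste(cv, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.wcr_cohort` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("subject_id", "time", "event", "arm") %in% names(out))) {
    attr(out, "covariates") <- intersect(attr(x, "covariates"), names(out))
    attr(out, "causes") <- attr(x, "causes")
    class(out) <- c("wcr_cohort", "data.frame")
  }
  out
}

## subject-level resample used by the bootstrap; fresh ids so that duplicated
## subjects stay distinct when weights are re-estimated and matched by id
resample_cohort <- function(cohort, idx) {
  out <- cohort[idx, , drop = FALSE]
  out$subject_id <- as.character(seq_along(idx))
  rownames(out) <- NULL
  out
}
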