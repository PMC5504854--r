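#' Fit a propensity model for treatment assignment or cohort membership
#'
#' Maximum-likelihood logistic regression when the outcome has two levels,
#' multinomial logistic regression (one joint model, not one-vs-rest) when it
#' has three or more.  The fitted object carries, for every subject, the
#' estimated probability of the assignment level actually received, plus the
#' marginal (intercept-only) level proportions used as the stabilizing
#' numerator by [stabilized_weights()].
#'
#' @param cohort a `wcr_cohort`.
#' @param outcome name of the column in `cohort` holding the assignment or
#'   membership label (for example `"arm"`, or a case/control indicator).
#' @param covariates character vector of covariate columns; empty for an
#'   intercept-only model.
#' @param maxit maximum optimizer iterations for the multinomial fit.
#' @return a `wcr_propensity` list with elements `model_kind`, `model`,
#'   `levels`, `outcome`, `covariates`, `probs` (n x K matrix of level
#'   probabilities), `prob_observed`, `marginal`, `subject_id`, `y`.
#' @examples
#' co <- as_cohort(data.frame(time = 1:4, event = 1, arm = "A",
#'                            z = c(0, 0, 1, 1), tr = c(0, 1, 1, 1)),
#'                 covariates = c("z", "tr"))
#' fit <- fit_propensity(co, "tr")          # intercept-only: P(tr = 1) = 3/4
#' fit$marginal
#' @export
fit_propensity <- function(cohort, outcome, covariates = character(),
                           maxit = 500L) {
  if (!outcome %in% names(cohort)) stop("outcome column '", outcome, "' not found")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0L)
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))

  y <- droplevels(factor(cohort[[outcome]]))
  if (anyNA(y)) stop("missing values in outcome '", outcome, "'")
  if (nlevels(y) < 2L)
    stop("outcome '", outcome,
         "' has fewer than 2 observed levels (a level of size 0 after subsetting?)")

  dat <- data.frame(.y = y, cohort[covariates], check.names = FALSE)
  if (anyNA(dat)) stop("missing covariate values; propensity models require complete data")

  ## design rank check, naming the collinear columns
  mm <- model.matrix(reformulate(if (length(covariates)) covariates else "1"), dat)
  qd <- qr(mm)
  if (qd$rank < ncol(mm)) {
    alias <- colnames(mm)[qd$pivot[(qd$rank + 1L):ncol(mm)]]
    stop("rank-deficient propensity design; collinear column(s): ",
         paste(alias, collapse = ", "))
  }

  fml <- reformulate(if (length(covariates)) covariates else "1", response = ".y")
  n <- nrow(dat)
  if (length(covariates) == 0L) {
    ## intercept-only MLE is the vector of sample proportions, exactly
    marg <- as.numeric(table(y)) / n
    probs <- matrix(marg, n, nlevels(y), byrow = TRUE,
                    dimnames = list(NULL, levels(y)))
    fit <- NULL
    kind <- if (nlevels(y) == 2L) "binary-logistic" else "multinomial-logistic"
  } else if (nlevels(y) == 2L) {
    fit <- glm(fml, family = binomial(), data = dat)
    p2 <- fitted(fit)
    probs <- cbind(1 - p2, p2)
    colnames(probs) <- levels(y)
    kind <- "binary-logistic"
  } else {
    fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = maxit,
                          reltol = 1e-12)
    probs <- predict(fit, newdata = dat, type = "probs")
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = n)
    colnames(probs) <- levels(y)
    kind <- "multinomial-logistic"
  }
  eps <- 1e-10
  pobs <- probs[cbind(seq_len(n), as.integer(y))]
  if (any(pobs < eps) || any(probs > 1 - eps & probs < 1))
    stop("fitted probabilities numerically at 0 or 1: perfect (or quasi-perfect) ",
         "separation; consider coarsening covariates or penalized estimation")

  structure(list(model_kind = kind, model = fit, levels = levels(y),
                 outcome = outcome, covariates = covariates,
                 probs = probs, prob_observed = as.numeric(pobs),
                 marginal = setNames(as.numeric(table(y)) / n, levels(y)),
                 subject_id = cohort$subject_id, y = y),
            class = "wcr_propensity")
}

#' @export
print.wcr_propensity <- function(x, ...) {
  cat(sprintf("<wcr_propensity> %s model of '%s' (%d levels) on %d subject(s)\n",
              x$model_kind, x$outcome, length(x$levels), length(x$prob_observed)))
  cat("  covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(intercept only)",
      "\n")
  cat("  marginal proportions:",
      paste(sprintf("%s %.3f", names(x$marginal), x$marginal), collapse = ", "), "\n")
  invisible(x)
}
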