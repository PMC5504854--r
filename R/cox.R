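## Newton-Raphson maximization of the (weighted) Cox partial likelihood.
##
## Risk-set aggregates are computed by rowsum() over the distinct follow-up
## times and reverse cumulative sums, so each iteration is O(n p^2) after an
## initial sort.  Breslow handles tied event times by using the full risk
## set for every tied event; Efron subtracts the tied deaths fractionally.
cox_engine <- function(time, status, X, w, ties = "breslow",
                       max_iter = 100L, tol = 1e-9) {
  n <- length(time)
  p <- ncol(X)
  uall <- sort(unique(time))

  ## per distinct event time: weighted death count and death x sums
  is_ev <- status > 0
  ut <- sort(unique(time[is_ev]))
  g_of_t <- match(time, ut)                  # event-time index, NA if none <=
  ev_rows <- which(is_ev)
  gi <- match(time[ev_rows], ut)
  D <- rowsum(w[ev_rows], gi)[, 1L]
  m_tied <- rowsum(rep(1, length(ev_rows)), gi)[, 1L]
  sum_wx_ev <- colSums(w[ev_rows] * X[ev_rows, , drop = FALSE])

  ## map: for each ut, position in uall (for reverse cumsums over risk sets)
  pos <- match(ut, uall)

  revcum_at_events <- function(values) {
    ## values: n x q matrix of per-subject quantities; returns, for each
    ## distinct event time, the sum over subjects with time >= that time
    by_t <- rowsum(values, time)             # ordered by sort(unique(time))
    rc <- apply(by_t, 2L, function(cl) rev(cumsum(rev(cl))))
    rc <- matrix(rc, nrow = length(uall))
    rc[pos, , drop = FALSE]
  }

  ## symmetric p x p index pairs stored as columns
  pr <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  unpack_sym <- function(v) {
    m <- matrix(0, p, p)
    m[pr] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }

  loglik_score_info <- function(beta) {
    eta <- drop(X %*% beta)
    r <- w * exp(eta)
    rx <- r * X
    rxx <- rx[, pr[, 1L], drop = FALSE] * X[, pr[, 2L], drop = FALSE]
    S0 <- revcum_at_events(matrix(r, ncol = 1L))[, 1L]
    S1 <- revcum_at_events(X * r)
    S2 <- revcum_at_events(rxx)

    if (ties == "efron") {
      ll <- sum(w[ev_rows] * eta[ev_rows])
      U <- sum_wx_ev
      I <- matrix(0, p, p)
      for (g in seq_along(ut)) {
        rows <- ev_rows[gi == g]
        m <- m_tied[g]
        wbar <- D[g] / m
        S0d <- sum(r[rows]); S1d <- colSums(rx[rows, , drop = FALSE])
        S2d <- unpack_sym(colSums(rxx[rows, , drop = FALSE]))
        S2g <- unpack_sym(S2[g, ])
        for (j in seq_len(m) - 1L) {
          f <- j / m
          s0 <- S0[g] - f * S0d
          s1 <- S1[g, ] - f * S1d
          s2 <- S2g - f * S2d
          ll <- ll - wbar * log(s0)
          U <- U - wbar * s1 / s0
          I <- I + wbar * (s2 / s0 - tcrossprod(s1 / s0))
        }
      }
      list(ll = ll, U = U, I = I,
           S0 = S0, S1 = S1, eta = eta, r = r)
    } else {
      ll <- sum(w[ev_rows] * eta[ev_rows]) - sum(D * log(S0))
      xbar <- S1 / S0
      U <- sum_wx_ev - colSums(D * xbar)
      I <- matrix(0, p, p)
      Iv <- colSums(D * (S2 / S0 - xbar[, pr[, 1L], drop = FALSE] *
                                    xbar[, pr[, 2L], drop = FALSE]))
      I <- unpack_sym(Iv)
      list(ll = ll, U = U, I = I, S0 = S0, S1 = S1, eta = eta, r = r)
    }
  }

  beta <- rep(0, p)
  cur <- loglik_score_info(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e)
      stop("singular information matrix in the partial likelihood; ",
           "check the design for collinearity"))
    cand <- beta + step
    nxt <- loglik_score_info(cand)
    halvings <- 0L
    while (!is.finite(nxt$ll) || nxt$ll < cur$ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      cand <- beta + step / 2^halvings
      nxt <- loglik_score_info(cand)
    }
    delta <- cand - beta
    ll_change <- abs(nxt$ll - cur$ll)
    beta <- cand
    if (max(abs(beta)) > 20)
      stop("diverging coefficients (monotone partial likelihood / infinite ",
           "hazard ratio); consider penalization or pooling sparse arms")
    done <- max(abs(delta)) < tol ||
      ll_change < 1e-12 * (abs(cur$ll) + 1e-12)
    cur <- nxt
    if (done) { converged <- TRUE; break }
    if (iter >= max_iter)
      stop(sprintf(paste0("partial likelihood did not converge in %d ",
                          "iterations (last |update| %.3e, loglik %.6f)"),
                   max_iter, max(abs(delta)), cur$ll))
  }

  ## robust (sandwich) pieces: per-subject score residuals at beta-hat.
  ## Residuals use Breslow-style hazard increments dL0 = D_g / S0_g; with no
  ## tied event times this coincides with Efron.
  xbar <- cur$S1 / cur$S0
  dL0 <- D / cur$S0
  cumL <- cumsum(dL0)
  cumG <- apply(xbar * dL0, 2L, cumsum)
  cumG <- matrix(cumG, nrow = length(ut))
  idx <- findInterval(time, ut)              # number of event times <= time_i
  H <- c(0, cumL)[idx + 1L]
  G <- rbind(0, cumG)[idx + 1L, , drop = FALSE]
  ehat <- exp(cur$eta)
  sres <- -ehat * (X * H - G)
  ev_x <- X[ev_rows, , drop = FALSE] - xbar[gi, , drop = FALSE]
  sres[ev_rows, ] <- sres[ev_rows, , drop = FALSE] + ev_x

  Iinv <- solve(cur$I)
  dfbeta <- (w * sres) %*% Iinv
  list(coefficients = beta, loglik = cur$ll, iter = iter,
       converged = converged, info = cur$I, naive_var = Iinv,
       robust_var = crossprod(dfbeta), dfbeta = dfbeta)
}

#' Cause-specific Cox proportional hazards model, optionally IPT-weighted
#'
#' Maximizes the (weighted) partial likelihood in which events of causes
#' other than `cause` are treated as censored at their event time -- the
#' cause-specific hazard formulation.  Newton-Raphson starts from beta = 0
#' and stops when the largest coefficient update falls below `1e-9` or the
#' relative log-likelihood change falls below `1e-12`.  Reported confidence
#' intervals always use the robust (sandwich) variance with subjects as
#' independent units: under IPT weighting the model-based variance is
#' invalid.
#'
#' @param cohort a `wcr_cohort`.
#' @param cause the cause of interest (events of other causes are censored).
#' @param adjust character vector of adjustment covariate columns entering
#'   linearly alongside the arm indicators.
#' @param weights a `wcr_weights` (final, truncated weights matched by
#'   subject id), a numeric vector, or `NULL` (cohort `weight` column or 1).
#' @param ties `"breslow"` (default, matching common practice for weighted
#'   fits) or `"efron"`.
#' @param include_arm set `FALSE` to drop the arm indicators (covariates
#'   only).
#' @param level confidence level for the hazard-ratio intervals.
#' @return a `wcr_coxfit`: `coefficients` (log hazard ratios),
#'   `robust_var`, `naive_var`, `hazard_ratios` (term, beta, robust SE, HR,
#'   CI), `n`, `n_events` (unweighted count and weight sum), `iter`,
#'   `converged`, `ties`, `cause`, `arm_levels`, `loglik`.
#' @examples
#' sim <- generate_cohort(sim_config(n = 600, seed = 7))
#' fit <- fit_cause_specific_cox(sim$cohort, cause = 1,
#'                               adjust = c("age", "comorbidity"))
#' fit$hazard_ratios
#' @export
fit_cause_specific_cox <- function(cohort, cause = 1L, adjust = character(),
                                   weights = NULL,
                                   ties = c("breslow", "efron"),
                                   include_arm = TRUE, level = 0.95) {
  stopifnot(inherits(cohort, "wcr_cohort"))
  ties <- match.arg(ties)
  rw <- resolve_weights(cohort, weights)
  cohort <- rw$cohort
  w <- rw$w

  causes <- attr(cohort, "causes")
  if (!cause %in% causes) stop("unknown cause: ", cause)
  status <- as.numeric(cohort$event == cause)
  if (sum(status) == 0) stop("no events of cause ", cause, " in the cohort")

  arm <- droplevels(cohort$arm)
  terms <- c(if (include_arm && nlevels(arm) > 1L) "arm", adjust)
  if (length(terms) == 0L)
    stop("nothing to fit: single arm and no adjustment covariates")
  miss <- setdiff(adjust, names(cohort))
  if (length(miss) > 0L)
    stop("adjustment covariate(s) not found: ", paste(miss, collapse = ", "))

  mf <- as.data.frame(cohort)
  mf$arm <- arm
  mm <- model.matrix(reformulate(terms), mf)
  X <- mm[, -1L, drop = FALSE]
  qd <- qr(X)
  if (qd$rank < ncol(X))
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]], collapse = ", "))

  eng <- cox_engine(cohort$time, status, X, w, ties = ties)
  beta <- setNames(eng$coefficients, colnames(X))
  se <- sqrt(diag(eng$robust_var))
  z <- qnorm(1 - (1 - level) / 2)
  hr <- data.frame(term = colnames(X), beta = as.numeric(beta),
                   se_robust = se, hr = exp(as.numeric(beta)),
                   lower = exp(as.numeric(beta) - z * se),
                   upper = exp(as.numeric(beta) + z * se),
                   stringsAsFactors = FALSE)
  rownames(hr) <- NULL

  structure(list(coefficients = beta, robust_var = eng$robust_var,
                 naive_var = eng$naive_var, hazard_ratios = hr,
                 n = nrow(cohort), n_events = sum(status),
                 n_events_weighted = sum(w * status),
                 iter = eng$iter, converged = eng$converged, ties = ties,
                 cause = cause, arm_levels = levels(arm),
                 include_arm = include_arm && nlevels(arm) > 1L,
                 adjust = adjust, level = level, loglik = eng$loglik),
            class = "wcr_coxfit")
}

#' @export
print.wcr_coxfit <- function(x, digits = 3, ...) {
  cat(sprintf("<wcr_coxfit> cause %d, %d subject(s), %d event(s) (weighted %.1f), %s ties\n",
              x$cause, x$n, x$n_events, x$n_events_weighted, x$ties))
  print(x$hazard_ratios, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Side-by-side hazard-ratio table for several model variants
#'
#' Rows are treatment arms (the reference arm printed with HR 1 and no
#' interval); columns are the hazard ratio and confidence bounds of each
#' supplied fit, e.g. an unweighted and an IPT-weighted cause-specific
#' model.
#'
#' @param fits named list of `wcr_coxfit` objects sharing the same arm
#'   structure.
#' @return a data.frame with one row per arm and `<name>_hr`,
#'   `<name>_lower`, `<name>_upper` columns per fit.
#' @export
hazard_ratio_table <- function(fits) {
  if (!is.list(fits) || length(fits) == 0L)
    stop("fits must be a non-empty list of wcr_coxfit objects")
  stopifnot(all(vapply(fits, inherits, logical(1), "wcr_coxfit")))
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  arms <- fits[[1L]]$arm_levels
  for (f in fits) {
    if (!identical(f$arm_levels, arms))
      stop("fits do not share the same arm structure")
    if (!f$include_arm) stop("fit without arm terms cannot be tabulated by arm")
  }
  out <- data.frame(arm = arms, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    hr <- fits[[nm]]$hazard_ratios
    rows <- match(paste0("arm", arms), hr$term)
    out[[paste0(nm, "_hr")]] <- ifelse(is.na(rows), 1, hr$hr[rows])
    out[[paste0(nm, "_lower")]] <- hr$lower[rows]
    out[[paste0(nm, "_upper")]] <- hr$upper[rows]
  }
  out
}

#' Export a Cox fit summary
#'
#' Writes the per-term summary (beta, robust SE, HR, CI) together with the
#' sample and event counts as CSV or JSON.
#'
#' @param fit a `wcr_coxfit`.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (JSON requires the jsonlite package).
#' @return `path`, invisibly.
#' @export
write_coxfit <- function(fit, path, format = c("csv", "json")) {
  stopifnot(inherits(fit, "wcr_coxfit"))
  format <- match.arg(format)
  tab <- fit$hazard_ratios
  tab$n <- fit$n
  tab$n_events <- fit$n_events
  tab$n_events_weighted <- fit$n_events_weighted
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON export requires the jsonlite package")
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
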