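#' Right-continuous step function (survival curve or CIF)
#'
#' Internal constructor for the piecewise-constant estimates produced by
#' [km_survival()], [naive_km_cif()] and [competing_risks_cif()]: strictly
#' increasing jump times, the function value on each interval
#' `[t_j, t_{j+1})`, the value on `[0, t_1)`, and optionally a pointwise
#' variance at the jump times.
#'
#' @param time strictly increasing jump times.
#' @param value function value from each jump time onward.
#' @param origin value on `[0, first jump)`.
#' @param type `"survival"` (non-increasing from 1) or `"cif"`
#'   (non-decreasing from 0).
#' @param variance optional pointwise variance at the jump times.
#' @return a `wcr_step` object.
#' @keywords internal
new_step <- function(time, value, origin, type = c("survival", "cif"),
                     variance = NULL) {
  type <- match.arg(type)
  stopifnot(length(time) == length(value),
            is.null(variance) || length(variance) == length(time))
  if (is.unsorted(time, strictly = TRUE) && length(time) > 1L)
    stop("jump times must be strictly increasing")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 origin = as.numeric(origin), type = type,
                 variance = if (is.null(variance)) NULL else as.numeric(variance)),
            class = "wcr_step")
}

#' Evaluate a step function
#'
#' Right-continuous evaluation: `step_at(fn, t)` returns the value on the
#' interval containing `t`, the origin value before the first jump, and the
#' last value beyond the last jump.  `cif_at()` is an alias named for its
#' typical use, reading a cumulative incidence at a reporting horizon.
#'
#' @param fn a `wcr_step`.
#' @param t vector of non-negative evaluation times.
#' @return numeric vector of function values.
#' @examples
#' s <- competing_risks_cif(build_risk_sets(
#'   as_cohort(data.frame(time = c(1, 2), event = c(2, 1), arm = "A"))), cause = 1)
#' cif_at(s, c(1.99, 2, 1e6))
#' @export
step_at <- function(fn, t) {
  stopifnot(inherits(fn, "wcr_step"))
  if (any(t < 0)) stop("evaluation times must be non-negative")
  idx <- findInterval(t, fn$time)
  c(fn$origin, fn$value)[idx + 1L]
}

#' @rdname step_at
#' @export
cif_at <- function(fn, t) step_at(fn, t)

#' @export
as.data.frame.wcr_step <- function(x, ...) {
  out <- data.frame(time = x$time, value = x$value)
  if (!is.null(x$variance)) out$variance <- x$variance
  out
}

#' @export
print.wcr_step <- function(x, ...) {
  cat(sprintf("<wcr_step> %s with %d jump(s); value %.4g on [0, %s), %.4g at the end\n",
              x$type, length(x$time), x$origin,
              if (length(x$time)) format(x$time[1L]) else "Inf",
              if (length(x$value)) x$value[length(x$value)] else x$origin))
  invisible(x)
}

#' @export
plot.wcr_step <- function(x, xlab = "time (days)",
                          ylab = if (x$type == "survival") "survival probability"
                                 else "cumulative incidence",
                          ylim = c(0, 1), ...) {
  tt <- c(0, x$time)
  vv <- c(x$origin, x$value)
  plot(tt, vv, type = "s", xlab = xlab, ylab = ylab, ylim = ylim, ...)
  invisible(x)
}

#' @export
lines.wcr_step <- function(x, ...) {
  lines(c(0, x$time), c(x$origin, x$value), type = "s", ...)
  invisible(x)
}
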