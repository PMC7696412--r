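#' Interval relative growth rate (simple-ratio form)
#'
#' Growth of a trait over a time interval relative to its initial value:
#' `RGR = unit_scale * (w2 - w1) / (w1 * (t2 - t1))`. With `unit_scale = 1000`
#' a per-day fraction is expressed as mg g^-1 d^-1; with `unit_scale = 1` an
#' area ratio is expressed as mm^2 mm^-2 d^-1. The result is negative when
#' the trait shrinks.
#'
#' This simple-ratio form is the convention used for destructive interval
#' tables; see [classical_rgr()] for the log-difference alternative implied by
#' the compound-interest law. The two agree to first order for small relative
#' increments.
#'
#' @param w1,w2 Trait values at the start and end of the interval; `w1 > 0`.
#' @param t1,t2 Interval endpoints in days, `t2 > t1`.
#' @param unit_scale Multiplier applied to the per-day fraction (default 1).
#' @return The interval RGR as a numeric scalar.
#' @examples
#' interval_rgr(920, 2290, 21, 25, unit_scale = 1000) # 372.3 mg g-1 d-1
#' @export
interval_rgr <- function(w1, w2, t1, t2, unit_scale = 1) {
  if (!is.finite(w1) || w1 <= 0)
    pg_error("initial value w1 must be positive: RGR baseline undefined", "pg_undefined_baseline")
  if (t2 <= t1) pg_error("interval must have t2 > t1", "pg_bad_interval")
  unit_scale * (w2 - w1) / (w1 * (t2 - t1))
}

#' Interval RGR table over consecutive time points
#'
#' For an ordered trait series with `n` time points, computes the `n - 1`
#' interval RGRs between consecutive pairs.
#'
#' @param dap Strictly increasing vector of sampling times (days after
#'   planting), or a data frame with `dap` and `value` columns.
#' @param values Trait values at each time (ignored when `dap` is a data
#'   frame).
#' @param unit_scale Passed to [interval_rgr()].
#' @param trait,genotype Optional labels carried into the output.
#' @return Data frame with one row per interval: `trait`, `genotype`,
#'   `dap_start`, `dap_end`, `rgr`.
#' @examples
#' ldw <- c(720, 1610, 3010, 3630, 4090, 4930, 5280, 5690)
#' rgr_table(c(21, 25, 30, 35, 39, 44, 49, 53), ldw, unit_scale = 1000)
#' @export
rgr_table <- function(dap, values = NULL, unit_scale = 1,
                      trait = NA_character_, genotype = NA_character_) {
  if (is.data.frame(dap)) {
    values <- dap$value
    dap <- dap$dap
  }
  if (length(dap) < 2L)
    pg_error("at least two time points are needed for interval RGR", "pg_insufficient_data")
  if (any(diff(dap) <= 0))
    pg_error("time points must be strictly increasing", "pg_bad_input")
  if (length(values) != length(dap))
    pg_error("dap and values must have equal length", "pg_bad_input")
  n <- length(dap)
  rgr <- vapply(seq_len(n - 1L), function(i)
    interval_rgr(values[i], values[i + 1L], dap[i], dap[i + 1L], unit_scale),
    numeric(1))
  data.frame(trait = trait, genotype = genotype,
             dap_start = dap[-n], dap_end = dap[-1L], rgr = rgr)
}

#' Classical (log-difference) relative growth rate
#'
#' `(ln w2 - ln w1) / (t2 - t1)`, the mean relative growth rate implied by
#' exponential growth `W(t) = W0 * exp(r t)`. Provided as an explicit
#' alternative to the simple-ratio [interval_rgr()]; the two converge as the
#' relative increment shrinks.
#'
#' @inheritParams interval_rgr
#' @return Per-day fractional growth rate.
#' @export
classical_rgr <- function(w1, w2, t1, t2) {
  if (!is.finite(w1) || !is.finite(w2) || w1 <= 0 || w2 <= 0)
    pg_error("classical RGR requires positive weights", "pg_domain")
  if (t2 <= t1) pg_error("interval must have t2 > t1", "pg_bad_interval")
  (log(w2) - log(w1)) / (t2 - t1)
}

#' Fit the compound-interest growth law
#'
#' Fits `W(t) = W0 * exp(r t)` by least squares on the log scale: `ln W` is
#' regressed on `t`, giving `W0 = exp(intercept)` and `r = slope` (the
#' efficiency index of dry-weight production, per day). With exactly two
#' points the fit interpolates, so `r = ln(W2/W1) / (t2 - t1)` exactly.
#'
#' @param dap Sampling times in days, or a data frame with `dap` and `value`.
#' @param values Positive trait values at each time.
#' @return A `growth_fit` list with `W0`, `r`, `log_r2` (R^2 of the log-scale
#'   regression), `n`, and the underlying `lm` fit.
#' @examples
#' t <- c(21, 25, 30, 35, 39, 44, 49, 53)
#' fit <- fit_compound_interest(t, 500 * exp(0.2 * t))
#' c(fit$W0, fit$r)
#' @export
fit_compound_interest <- function(dap, values = NULL) {
  if (is.data.frame(dap)) {
    values <- dap$value
    dap <- dap$dap
  }
  if (length(dap) < 2L)
    pg_error("at least two time points are needed to fit the growth law", "pg_insufficient_data")
  if (any(!is.finite(values)) || any(values <= 0))
    pg_error("the compound-interest law is defined for positive values only", "pg_domain")
  fit <- stats::lm(log(values) ~ dap)
  co <- stats::coef(fit)
  r2 <- if (length(dap) > 2L) summary(fit)$r.squared else 1
  structure(list(W0 = unname(exp(co[1L])), r = unname(co[2L]),
                 log_r2 = r2, n = length(dap), fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Compound-interest growth fit: W(t) = %.4g * exp(%.4g t)  [n = %d, log-scale R2 = %.4f]\n",
              x$W0, x$r, x$n, x$log_r2))
  invisible(x)
}

#' Predict from a compound-interest fit
#'
#' @param object A `growth_fit`.
#' @param t Times (days) at which to evaluate `W0 * exp(r t)`.
#' @param ... Unused.
#' @return Predicted trait values.
#' @export
predict.growth_fit <- function(object, t, ...) object$W0 * exp(object$r * t)
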