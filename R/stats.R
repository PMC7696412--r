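#' Simple linear regression with SPA-style validation summaries
#'
#' Ordinary least squares of one response on one predictor, returning the
#' quantities used to judge an image-based surrogate: slope, intercept,
#' coefficient of determination and Pearson correlation (whose square equals
#' R^2 in simple regression).
#'
#' @param x Predictor values (e.g. side-projected area).
#' @param y Response values (e.g. a destructively measured trait).
#' @return A `regression_result` list: `slope`, `intercept`, `r2` (fraction),
#'   `pearson_r`, `n`, `p_value` (slope t-test), and the underlying `lm` fit.
#' @examples
#' res <- ols_simple(1:8, 2 * (1:8) + 1)
#' c(res$slope, res$intercept, res$r2)
#' @export
ols_simple <- function(x, y) {
  if (length(x) != length(y)) pg_error("x and y must have equal length", "pg_bad_input")
  if (length(x) < 3L) pg_error("at least 3 points are required", "pg_insufficient_data")
  if (stats::sd(x) == 0) pg_error("constant predictor: regression undefined", "pg_degenerate_predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(fit)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r2 = sm$r.squared, pearson_r = r, n = length(x),
                 p_value = sm$coefficients[2L, 4L], fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g   R2 = %.3f (r = %.3f, n = %d, p = %.3g)\n",
              x$slope, x$intercept, x$r2, x$pearson_r, x$n, x$p_value))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: both inputs must vary and
#' hold at least three pairs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) pg_error("x and y must have equal length", "pg_bad_input")
  if (length(x) < 3L) pg_error("at least 3 pairs are required", "pg_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    pg_error("constant input: correlation undefined", "pg_degenerate_predictor")
  stats::cor(x, y)
}

#' Balanced two-way ANOVA with interaction
#'
#' Decomposes a trait measured over a crossed time-point x genotype design
#' with equal replication into main-effect, interaction and residual sums of
#' squares (sequential SS; order-invariant under balance), with F tests
#' against the residual mean square and the model R^2
#' `(SS_time + SS_geno + SS_interaction) / SS_total`. Unbalanced designs are
#' rejected rather than silently approximated.
#'
#' @param data Data frame of individual-plant records.
#' @param value,time,genotype Column names (strings) of the response, the
#'   time-point factor and the genotype factor.
#' @return An `anova_table` list: `table` (rows time, genotype, interaction,
#'   residual with df, sum_sq, mean_sq, f, p) and `r2`.
#' @export
two_way_anova <- function(data, value = "value", time = "dap", genotype = "genotype") {
  for (col in c(value, time, genotype))
    if (!col %in% names(data))
      pg_error(sprintf("column '%s' not found", col), "pg_bad_input")
  tp <- factor(data[[time]])
  gn <- factor(data[[genotype]])
  y <- data[[value]]
  if (nlevels(tp) < 2L || nlevels(gn) < 2L)
    pg_error("each factor needs at least two levels", "pg_bad_design")
  counts <- table(tp, gn)
  if (any(counts == 0L)) pg_error("empty design cells: unbalanced designs are rejected", "pg_unbalanced")
  if (length(unique(as.vector(counts))) != 1L)
    pg_error("unequal cell sizes: unbalanced designs are rejected", "pg_unbalanced")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("all responses identical: variance ratio undefined, reporting zero table", call. = FALSE)
    n <- length(y)
    tab <- data.frame(
      source = c("time", "genotype", "interaction", "residual"),
      df = c(nlevels(tp) - 1L, nlevels(gn) - 1L,
             (nlevels(tp) - 1L) * (nlevels(gn) - 1L),
             n - nlevels(tp) * nlevels(gn)),
      sum_sq = 0, mean_sq = 0, f = c(0, 0, 0, NA), p = c(NA, NA, NA, NA))
    return(structure(list(table = tab, r2 = 0, fit = NULL), class = "anova_table"))
  }
  fit <- stats::lm(y ~ tp * gn)
  an <- stats::anova(fit)
  tab <- data.frame(
    source = c("time", "genotype", "interaction", "residual"),
    df = an$Df, sum_sq = an$`Sum Sq`, mean_sq = an$`Mean Sq`,
    f = an$`F value`, p = an$`Pr(>F)`)
  r2 <- sum(tab$sum_sq[1:3]) / sum(tab$sum_sq)
  structure(list(table = tab, r2 = r2, fit = fit), class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("model R2 = %.4f\n", x$r2))
  invisible(x)
}

#' Exponential predictor fit
#'
#' Fits `y = a * exp(b * x)`, the alternative to a linear surrogate model
#' when the response accelerates relative to the predictor (as biomass does
#' against silhouette area once spikes begin to fill). A log-linear
#' regression of `ln y` on `x` provides closed-form starting values, which
#' are then refined by nonlinear least squares on the original scale so the
#' fit minimizes the same residual sum of squares a linear competitor is
#' judged on (pure log-scale fitting down-weights the largest plants and can
#' lose to a straight line on the original scale). If the nonlinear
#' refinement cannot improve on the start — e.g. on exactly exponential,
#' zero-residual data — the log-linear estimates are kept.
#'
#' Reports R^2 of the log-scale regression and a pseudo-R^2 on the original
#' scale (`1 - SS_res/SS_tot` of the exponential predictions), the number
#' comparable with a linear fit's R^2.
#'
#' @param x Predictor values.
#' @param y Positive response values.
#' @return An `exp_predictor` list: `a`, `b`, `log_r2`, `pseudo_r2`, `n`.
#' @export
fit_exponential_predictor <- function(x, y) {
  if (length(x) != length(y)) pg_error("x and y must have equal length", "pg_bad_input")
  if (any(!is.finite(y)) || any(y <= 0))
    pg_error("exponential fit requires positive responses", "pg_domain")
  if (length(x) < 2L) pg_error("at least 2 points are required", "pg_insufficient_data")
  fit <- stats::lm(log(y) ~ x)
  co <- stats::coef(fit)
  a <- unname(exp(co[1L]))
  b <- unname(co[2L])
  nl <- tryCatch(
    suppressWarnings(stats::nls(y ~ a * exp(b * x),
                                start = list(a = a, b = b),
                                control = stats::nls.control(maxiter = 200,
                                                             warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(nl)) {
    ss_start <- sum((y - a * exp(b * x))^2)
    if (sum(stats::residuals(nl)^2) <= ss_start) {
      a <- unname(stats::coef(nl)["a"])
      b <- unname(stats::coef(nl)["b"])
    }
  }
  yhat <- a * exp(b * x)
  ss_tot <- sum((y - mean(y))^2)
  pseudo <- if (ss_tot == 0) 1 else 1 - sum((y - yhat)^2) / ss_tot
  log_r2 <- if (length(x) > 2L) summary(fit)$r.squared else 1
  structure(list(a = a, b = b, log_r2 = log_r2, pseudo_r2 = pseudo,
                 n = length(x), fit = fit),
            class = "exp_predictor")
}

#' @export
print.exp_predictor <- function(x, ...) {
  cat(sprintf("y = %.4g * exp(%.4g x)   log-scale R2 = %.3f, pseudo-R2 = %.3f (n = %d)\n",
              x$a, x$b, x$log_r2, x$pseudo_r2, x$n))
  invisible(x)
}
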