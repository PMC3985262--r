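#' Parameter-fit result
#'
#' Light-weight container for a single estimated kinetic parameter with
#' its residual diagnostics.
#'
#' @param parameter_name label of the estimated quantity.
#' @param estimate point estimate.
#' @param unit unit of the estimate.
#' @param stderr standard error (same unit; `NA` where not defined).
#' @param residual_ss residual sum of squares on the fitted scale.
#' @param n_points number of observations used.
#' @param converged logical; `FALSE` flags an optimum pinned at a search
#'   bound.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(parameter_name, estimate, unit, stderr = NA_real_,
                       residual_ss = NA_real_, n_points = NA_integer_,
                       converged = TRUE) {
  structure(
    list(parameter_name = parameter_name, estimate = estimate, unit = unit,
         stderr = stderr, residual_ss = residual_ss,
         n_points = as.integer(n_points), converged = converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$parameter_name, " = ",
      format(x$estimate, digits = 6), " ", x$unit, sep = "")
  if (is.finite(x$stderr)) cat("  (se ", format(x$stderr, digits = 3), ")",
                               sep = "")
  cat("\n  RSS =", format(x$residual_ss, digits = 4),
      " on", x$n_points, "points")
  if (!x$converged) cat("  [NOT CONVERGED: estimate at search bound]")
  cat("\n")
  invisible(x)
}

#' Estimate the elimination constant from post-removal decay
#'
#' After the final patch removal the model predicts pure first-order
#' decay, so the log concentration falls linearly in time with slope
#' `-k_elim`. This fits ordinary least squares of `log(C)` on `t`
#' (unweighted, the conventional terminal-slope linearisation) and
#' returns the negated slope.
#'
#' @param decay_series a [conc_series()] of strictly positive
#'   concentrations sampled after removal; at least 2 points.
#' @return A [fit_result()] for `k_elim` in 1/h; `residual_ss` is on the
#'   log scale.
#' @examples
#' tt <- c(0, 12, 24, 48, 72)
#' s <- conc_series(tt, 2 * exp(-0.0244 * tt), "ng/mL")
#' fit_kelim(s)
#' @export
fit_kelim <- function(decay_series) {
  stopifnot(inherits(decay_series, "conc_series"))
  if (length(decay_series$times) < 2L) {
    stop("need at least 2 observations to fit a slope", call. = FALSE)
  }
  if (any(decay_series$values <= 0)) {
    stop("all concentrations must be strictly positive to take logs",
         call. = FALSE)
  }
  tt <- decay_series$times
  fit <- stats::lm(log(values) ~ times,
                   data = data.frame(times = tt,
                                     values = decay_series$values))
  rss <- sum(stats::residuals(fit)^2)
  n <- length(tt)
  # slope standard error computed directly (summary.lm warns on exact
  # fits, which are routine here when testing against noiseless data)
  se <- if (n > 2L) sqrt(rss / (n - 2L) / sum((tt - mean(tt))^2))
        else NA_real_
  fit_result(
    parameter_name = "k_elim",
    estimate = -unname(stats::coef(fit)[["times"]]),
    unit = "1/h",
    stderr = se,
    residual_ss = rss,
    n_points = n
  )
}

#' Fit the absorption attenuation constant to observed concentrations
#'
#' The attenuation constant (the \eqn{\alpha}/\eqn{\beta} of the model) is
#' the only free parameter once the release rate, clearance and
#' elimination constant are fixed from independent sources. It is
#' estimated by bounded one-dimensional least squares: the residual sum of
#' squares between the observations and the closed-form model trajectory
#' is minimised over `[0, upper]` with Brent's method
#' ([stats::optimize()]), which is deterministic for given inputs. An
#' optimum within a half-tolerance of either bound is flagged
#' `converged = FALSE`.
#'
#' Duplicated observation times are allowed and treated as independent
#' replicates. The fit is scale-invariant: rescaling all observations
#' together with `k_o` leaves the estimate unchanged.
#'
#' @param observed a [conc_series()] of observations; times must lie
#'   within the regimen horizon and the unit must match `params`.
#' @param params a [drug_params()] supplying every fixed constant and the
#'   starting-point convention for the search bound.
#' @param reg the [regimen()] under which the data were collected.
#' @param upper upper search bound in `params$decay_unit`; default 10
#'   times the preset value (or 0.1 if the preset value is 0).
#' @param c0 initial concentration of the generating trajectory.
#' @return A [fit_result()] for the attenuation constant in
#'   `params$decay_unit`.
#' @export
fit_decay_const <- function(observed, params, reg,
                            upper = NULL, c0 = 0) {
  stopifnot(inherits(observed, "conc_series"),
            inherits(params, "drug_params"), inherits(reg, "regimen"))
  if (length(observed$times) == 0L) {
    stop("no observations to fit", call. = FALSE)
  }
  if (!identical(observed$unit, params$conc_unit)) {
    stop("observation unit ", observed$unit, " does not match parameter ",
         "unit ", params$conc_unit, call. = FALSE)
  }
  if (max(observed$times) > reg$horizon) {
    stop("observation times extend beyond the regimen horizon",
         call. = FALSE)
  }
  if (is.null(upper)) {
    upper <- if (params$decay_const > 0) 10 * params$decay_const else 0.1
  }

  with_decay <- function(d) {
    p <- params
    p$decay_const <- d
    p$decay_h <- if (p$decay_unit == "1/day") d / 24 else d
    p
  }
  obj <- function(d) {
    pred <- predict_analytic(with_decay(d), reg, observed$times, c0 = c0)
    sum((observed$values - pred)^2)
  }

  opt <- stats::optimize(obj, interval = c(0, upper), tol = 1e-10)
  est <- opt$minimum
  # Brent never evaluates exactly at the bounds; compare against them
  at_bound <- (est < 1e-4 * upper && obj(0) <= opt$objective) ||
    (upper - est < 1e-4 * upper && obj(upper) <= opt$objective)
  if (obj(0) < opt$objective) {
    est <- 0
    opt$objective <- obj(0)
  }
  if (obj(upper) < opt$objective) {
    est <- upper
    opt$objective <- obj(upper)
  }

  fit_result(
    parameter_name = paste0("decay_const(", params$name, ")"),
    estimate = est,
    unit = params$decay_unit,
    residual_ss = opt$objective,
    n_points = length(observed$times),
    converged = !at_bound && est > 0 && est < upper
  )
}

# Observations sampled at duplicated times are fine for both fitters:
# lm() and the RSS objective treat rows independently.
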