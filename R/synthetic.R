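#' Sparse clinical sampling design
#'
#' Describes how synthetic "observed" serum concentrations are drawn from
#' the model: which times are sampled, how much multiplicative assay
#' noise is applied, and under which seed. Concentration assays have
#' errors roughly proportional to the measured level, so noise is
#' lognormal with mean 1 and a prescribed coefficient of variation.
#'
#' @param params a [drug_params()] generating the underlying trajectory.
#' @param reg the [regimen()] being sampled.
#' @param sample_times sampling times (h) within the regimen horizon;
#'   default [default_sampling_times()] for the regimen.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise, `>= 0`; default 0.05 (a typical well-run immunoassay).
#' @param seed integer seed; the same design and seed always reproduce
#'   the same series.
#' @param c0 initial concentration of the generating trajectory.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(params, reg, sample_times = NULL,
                            noise_cv = 0.05, seed = 1L, c0 = 0) {
  stopifnot(inherits(params, "drug_params"), inherits(reg, "regimen"))
  if (is.null(sample_times)) sample_times <- default_sampling_times(reg)
  if (!is.numeric(sample_times) || length(sample_times) == 0L ||
      any(!is.finite(sample_times))) {
    stop("`sample_times` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(sample_times < 0) || any(sample_times > reg$horizon)) {
    stop("`sample_times` must lie within [0, horizon]", call. = FALSE)
  }
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0) {
    stop("`noise_cv` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(params = params, regimen = reg,
         sample_times = sort(sample_times),
         noise_cv = noise_cv, seed = as.integer(seed), c0 = c0),
    class = "sampling_design"
  )
}

#' Default sampling schedule for a regimen
#'
#' Mimics the resolution of weekly-cycle clinical PK studies: a sample
#' every 12 h while a patch is scheduled (through the final removal) and
#' every 6 h during the post-removal decay phase, where the terminal
#' slope is estimated.
#'
#' @param reg a [regimen()].
#' @return Sorted vector of sampling times (h).
#' @export
default_sampling_times <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  ev <- reg$events
  removal <- if (any(ev$kind == "remove")) {
    max(ev$time[ev$kind == "remove"])
  } else {
    reg$horizon
  }
  wear <- seq(0, removal, by = 12)
  decay <- if (removal < reg$horizon) {
    seq(removal + 6, reg$horizon, by = 6)
  } else {
    numeric(0)
  }
  c(wear, decay)
}

#' Draw noisy observations from a sampling design
#'
#' Evaluates the exact model trajectory at the design's sampling times
#' and multiplies each value by an independent lognormal factor with mean
#' 1 and coefficient of variation `noise_cv` (so the observations are
#' unbiased for the model curve). The draw is made under the design's
#' seed in an isolated RNG scope: results are reproducible and the
#' caller's RNG state is untouched.
#'
#' @param design a [sampling_design()].
#' @return A [conc_series()] of observations at the design times.
#' @examples
#' pars <- pk_preset()$NGMN
#' d <- sampling_design(pars, standard_cycle(), noise_cv = 0.05, seed = 42)
#' obs <- generate_observations(d)
#' @export
generate_observations <- function(design) {
  stopifnot(inherits(design, "sampling_design"))
  mu <- predict_analytic(design$params, design$regimen,
                         design$sample_times, c0 = design$c0)
  if (design$noise_cv > 0) {
    sdlog <- sqrt(log1p(design$noise_cv^2))
    eps <- withr::with_seed(
      design$seed,
      stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    )
    mu <- mu * eps
  }
  conc_series(design$sample_times, pmax(mu, 0),
              unit = design$params$conc_unit,
              hormone = design$params$name)
}
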