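#' Simulation grid
#'
#' Uniform integration grid for the forward-difference scheme: step `dt`
#' (h, at most 1 h — the explicit scheme is comfortably stable there for
#' contraceptive-hormone elimination constants) and end time `horizon`,
#' which must be a whole number of steps.
#'
#' @param dt integration step (h), `0 < dt <= 1`.
#' @param horizon end time (h), a non-negative multiple of `dt` (0 gives
#'   the degenerate single-point grid).
#' @return An object of class `sim_grid` with fields `dt`, `horizon`,
#'   `times` (the grid `0, dt, ..., horizon`).
#' @examples
#' sim_grid(0.1, 504)
#' @export
sim_grid <- function(dt = 0.1, horizon = 600) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) ||
      dt <= 0 || dt > 1) {
    stop("`dt` must satisfy 0 < dt <= 1 h", call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon < 0) {
    stop("`horizon` must be non-negative", call. = FALSE)
  }
  # horizon 0 is the degenerate no-op simulation: a single point at t = 0
  n <- round(horizon / dt)
  if (abs(n * dt - horizon) > 1e-8 * max(1, horizon)) {
    stop("`horizon` must be a whole number of steps `dt`", call. = FALSE)
  }
  structure(list(dt = dt, horizon = horizon, times = dt * (0:n)),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat("<sim_grid> dt =", x$dt, "h, horizon =", x$horizon, "h (",
      length(x$times), "points )\n")
  invisible(x)
}

#' Instantaneous absorption rate from the patch
#'
#' The model's entry stream: the patch releases hormone at an
#' exponentially attenuating rate, lumping depletion of the reservoir and
#' gradual saturation of the stratum corneum into a single decay constant.
#' Scaled by the attached area fraction (partial detachment reduces the
#' delivering contact area proportionally).
#'
#' @param params a [drug_params()].
#' @param patch_age time since the worn patch was applied (h), `>= 0`.
#' @param area_fraction attached fraction of contact area, in `[0, 1]`;
#'   0 means no patch is delivering.
#' @return Absorption rate in concentration-unit per hour:
#'   `area_fraction * (k_o / V_d) * exp(-decay * patch_age)`.
#' @examples
#' ngmn <- pk_preset()$NGMN
#' absorption_rate(ngmn, patch_age = 0)   # zero-age rate k_o / V_d
#' absorption_rate(ngmn, patch_age = 168) # after a week of wear
#' @export
absorption_rate <- function(params, patch_age, area_fraction = 1) {
  stopifnot(inherits(params, "drug_params"))
  if (any(!is.finite(patch_age)) || any(patch_age < 0)) {
    stop("`patch_age` must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(area_fraction)) ||
      any(area_fraction < 0 | area_fraction > 1)) {
    stop("`area_fraction` must lie in [0, 1]", call. = FALSE)
  }
  area_fraction * params$k0_rate * exp(-params$decay_h * patch_age)
}

#' Instantaneous elimination rate
#'
#' Magnitude of the first-order loss term, `k_elim * C`.
#'
#' @param params a [drug_params()].
#' @param concentration serum concentration (`params$conc_unit`), `>= 0`.
#' @return Elimination rate in concentration-unit per hour.
#' @examples
#' elimination_rate(pk_preset()$NGMN, 1) # 0.0244 ng/mL/h
#' @export
elimination_rate <- function(params, concentration) {
  stopifnot(inherits(params, "drug_params"))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("`concentration` must be non-negative", call. = FALSE)
  }
  params$k_elim * concentration
}

#' Simulate a regimen by the forward-difference scheme
#'
#' Steps the one-compartment balance
#' \deqn{C(t + \Delta t) = C(t) + \left[f(t)\,\frac{k_o}{V_d}
#'   e^{-\lambda\,a(t)} - k_{elim} C(t)\right] \Delta t}
#' over the grid, where `f(t)` is the attached area fraction and `a(t)`
#' the age of the worn patch (time since its `apply_new`/`replace` event —
#' the zero-age release rate is restored each time the patch is replaced;
#' a reattached patch keeps its age). This mirrors the model's native
#' difference-equation formulation; [simulate_analytic()] provides the
#' exact solution of the underlying ODE for accuracy checks.
#'
#' @param params a [drug_params()].
#' @param reg a [regimen()].
#' @param grid a [sim_grid()]; its horizon must not exceed the regimen's.
#' @param c0 initial concentration (default 0: drug-naive at cycle start).
#' @return A [conc_series()] on the grid times.
#' @examples
#' ngmn <- pk_preset()$NGMN
#' s <- simulate_difference(ngmn, standard_cycle(), sim_grid(0.1, 600))
#' max(s$values)
#' @export
simulate_difference <- function(params, reg, grid, c0 = 0) {
  stopifnot(inherits(params, "drug_params"), inherits(reg, "regimen"),
            inherits(grid, "sim_grid"))
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0) {
    stop("`c0` must be a single non-negative number", call. = FALSE)
  }
  if (grid$horizon > reg$horizon + 1e-9) {
    stop("grid horizon exceeds regimen horizon", call. = FALSE)
  }
  k <- params$k_elim
  if (grid$dt * k >= 1) {
    stop("unstable step: dt = ", grid$dt, " h exceeds 1/k_elim = ",
         format(1 / k, digits = 3), " h; the explicit scheme would ",
         "produce negative concentrations", call. = FALSE)
  }

  tt <- grid$times
  n <- length(tt) - 1L
  # rates evaluated at the left endpoint of each step
  st <- wear_state(reg, tt[seq_len(n)])
  a <- st$fraction * params$k0_rate * exp(-params$decay_h * st$age)

  # linear recurrence C[i+1] = (1 - k dt) C[i] + a[i] dt
  if (n > 0L) {
    values <- c(c0, stats::filter(a * grid$dt, 1 - k * grid$dt,
                                  method = "recursive", init = c0))
  } else {
    values <- c0
  }
  values <- as.numeric(values)

  if (any(values < 0)) {
    if (min(values) < -1e-9 * max(abs(values), 1)) {
      stop("integration produced substantially negative concentrations; ",
           "reduce `dt`", call. = FALSE)
    }
    warning("clipping tiny negative concentrations to 0 (round-off)")
    values[values < 0] <- 0
  }

  conc_series(tt, values, unit = params$conc_unit, hormone = params$name)
}

# Exact concentration at arbitrary (sorted or unsorted) times, obtained by
# chaining the closed-form solution of C' = f A0 exp(-lambda (s0+tau)) - k C
# across inter-event segments. Shared by simulate_analytic(), the decay
# fitter and the synthetic-data generator.
predict_analytic <- function(params, reg, times, c0 = 0) {
  k <- params$k_elim
  lam <- params$decay_h
  seg <- regimen_segments(reg)
  m <- nrow(seg)

  # advance the exact solution over one segment of length tau
  step_exact <- function(C0, frac, age0, tau) {
    if (frac == 0) return(C0 * exp(-k * tau))
    A <- frac * params$k0_rate * exp(-lam * age0)
    if (abs(k - lam) < 1e-8 * max(k, lam)) {
      C0 * exp(-k * tau) + A * tau * exp(-k * tau)
    } else {
      C0 * exp(-k * tau) + A * (exp(-lam * tau) - exp(-k * tau)) / (k - lam)
    }
  }

  # concentration at every segment start
  Cstart <- numeric(m)
  Cstart[1L] <- c0
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      age0 <- if (is.na(seg$age_origin[i])) 0 else
        seg$start[i] - seg$age_origin[i]
      Cstart[i + 1L] <- step_exact(Cstart[i], seg$fraction[i], age0,
                                   seg$end[i] - seg$start[i])
    }
  }

  idx <- findInterval(times, seg$start)
  idx[idx < 1L] <- 1L
  out <- numeric(length(times))
  for (j in seq_along(times)) {
    i <- idx[j]
    age0 <- if (is.na(seg$age_origin[i])) 0 else
      seg$start[i] - seg$age_origin[i]
    out[j] <- step_exact(Cstart[i], seg$fraction[i], age0,
                         times[j] - seg$start[i])
  }
  out
}

#' Closed-form trajectory of the continuous-time model
#'
#' Evaluates the exact solution of the underlying linear ODE
#' \deqn{C' = f\,\frac{k_o}{V_d} e^{-\lambda s} - k_{elim} C}
#' piecewise between regimen events on the same grid as
#' [simulate_difference()]. Between events the wear state is constant and
#' the solution over an interval of length \eqn{\tau} starting with
#' concentration \eqn{C_0} and patch age \eqn{s_0} is
#' \deqn{C_0 e^{-k\tau} + f\,\frac{k_o}{V_d} e^{-\lambda s_0}
#'   \frac{e^{-\lambda\tau} - e^{-k\tau}}{k - \lambda},}
#' with the limiting form \eqn{f (k_o/V_d) e^{-\lambda s_0}\,\tau
#' e^{-k\tau}} used when \eqn{k} and \eqn{\lambda} coincide to within
#' round-off. Serves as the accuracy oracle for the first-order difference
#' scheme.
#'
#' @inheritParams simulate_difference
#' @return A [conc_series()] on the grid times.
#' @examples
#' ngmn <- pk_preset()$NGMN
#' g <- sim_grid(0.1, 600)
#' a <- simulate_analytic(ngmn, standard_cycle(), g)
#' d <- simulate_difference(ngmn, standard_cycle(), g)
#' max(abs(a$values - d$values)) # first-order in dt
#' @export
simulate_analytic <- function(params, reg, grid, c0 = 0) {
  stopifnot(inherits(params, "drug_params"), inherits(reg, "regimen"),
            inherits(grid, "sim_grid"))
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0) {
    stop("`c0` must be a single non-negative number", call. = FALSE)
  }
  if (grid$horizon > reg$horizon + 1e-9) {
    stop("grid horizon exceeds regimen horizon", call. = FALSE)
  }
  values <- predict_analytic(params, reg, grid$times, c0 = c0)
  values[values < 0 & values > -1e-12] <- 0
  conc_series(grid$times, values, unit = params$conc_unit,
              hormone = params$name)
}
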