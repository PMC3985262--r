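#' Area under the concentration-time curve
#'
#' Trapezoidal integral of a piecewise-linear trajectory over
#' `[start, end]`. Endpoints falling between grid points are linearly
#' interpolated, which makes the integral exactly additive over abutting
#' intervals.
#'
#' @param series a [conc_series()].
#' @param start,end integration bounds (h), `start < end`, both within
#'   the series' time range.
#' @return AUC in concentration-unit times hours.
#' @examples
#' s <- conc_series(0:168, rep(2, 169), "ng/mL")
#' auc(s, 0, 168) # 336
#' @export
auc <- function(series, start, end) {
  stopifnot(inherits(series, "conc_series"))
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L ||
      length(end) != 1L || !is.finite(start) || !is.finite(end)) {
    stop("`start` and `end` must be single finite numbers", call. = FALSE)
  }
  if (start >= end) {
    stop("`start` must be strictly less than `end`", call. = FALSE)
  }
  tt <- series$times
  if (start < tt[1L] || end > tt[length(tt)]) {
    stop("[start, end] must lie within the series time range [",
         tt[1L], ", ", tt[length(tt)], "]", call. = FALSE)
  }
  keep <- tt > start & tt < end
  xs <- c(start, tt[keep], end)
  ys <- c(
    stats::approx(tt, series$values, xout = start)$y,
    series$values[keep],
    stats::approx(tt, series$values, xout = end)$y
  )
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
}

#' Plateau ("steady-state") concentration
#'
#' Time-average of the trajectory over a window, i.e. the trapezoidal
#' integral divided by the window length. The default window is the third
#' wear week (hours 336-504), by which time the weekly concentration
#' pattern is fully established.
#'
#' @param series a [conc_series()].
#' @param window length-2 numeric `c(start, end)` (h); default
#'   `c(336, 504)`.
#' @return Mean concentration over the window, in the series unit.
#' @examples
#' s <- conc_series(seq(0, 504, 0.5), rep(0.8, 1009), "ng/mL")
#' css(s) # 0.8
#' @export
css <- function(series, window = c(336, 504)) {
  if (!is.numeric(window) || length(window) != 2L) {
    stop("`window` must be c(start, end)", call. = FALSE)
  }
  auc(series, window[1L], window[2L]) / (window[2L] - window[1L])
}

#' Weekly AUCs over a multi-week cycle
#'
#' Convenience wrapper returning the AUC of each consecutive 168 h wear
#' week and their mean — the per-week exposure figure conventionally
#' quoted as AUC over 0-168 h.
#'
#' @param series a [conc_series()] covering at least `n_weeks * 168` h.
#' @param n_weeks number of weeks (default 3).
#' @return List with `weekly` (numeric vector of per-week AUCs) and
#'   `mean` (their average).
#' @export
weekly_auc <- function(series, n_weeks = 3) {
  w <- vapply(seq_len(n_weeks), function(i) {
    auc(series, 168 * (i - 1), 168 * i)
  }, numeric(1))
  list(weekly = w, mean = mean(w))
}

#' Therapeutic-window statistics of a trajectory
#'
#' Locates, by linear interpolation between grid points, every interval
#' on which the trajectory lies below `low` (sub-therapeutic "risk
#' windows"), above `high` (overexposure), or inside the band, and sums
#' the time spent in each state. Interval classification is consistent
#' with the piecewise-linear reading of the series, so the three
#' durations partition the analysed span exactly; values equal to a bound
#' count as in range.
#'
#' @param series a [conc_series()].
#' @param low,high therapeutic band bounds in the series unit,
#'   `low < high`.
#' @param span optional `c(start, end)` restricting the analysis (h);
#'   default the full series range.
#' @return An object of class `range_report`: list with data frames
#'   `risk_windows` and `over_windows` (columns `start`, `end`, disjoint
#'   and ordered) and scalars `time_in_range`, `time_below`,
#'   `time_above`, `span`.
#' @examples
#' s <- conc_series(c(0, 50, 150, 200), c(1, 0.9, 0.3, 0.8), "ng/mL")
#' range_crossings(s, 0.6, 1.2)
#' @export
range_crossings <- function(series, low, high, span = NULL) {
  stopifnot(inherits(series, "conc_series"))
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    stop("`low` must be strictly less than `high`", call. = FALSE)
  }
  tt <- series$times
  vv <- series$values
  if (is.null(span)) span <- range(tt)
  if (span[1L] < tt[1L] || span[2L] > tt[length(tt)] ||
      span[1L] >= span[2L]) {
    stop("`span` must be an increasing interval within the series range",
         call. = FALSE)
  }

  n <- length(tt)
  crossings <- function(thr) {
    i <- which((vv[-n] - thr) * (vv[-1L] - thr) < 0)
    tt[i] + (thr - vv[i]) * (tt[i + 1L] - tt[i]) / (vv[i + 1L] - vv[i])
  }
  bp <- sort(unique(c(span, tt[tt > span[1L] & tt < span[2L]],
                      crossings(low), crossings(high))))
  bp <- bp[bp >= span[1L] & bp <= span[2L]]

  mids <- (bp[-length(bp)] + bp[-1L]) / 2
  vmid <- stats::approx(tt, vv, xout = mids)$y
  state <- ifelse(vmid < low, "below", ifelse(vmid > high, "above", "in"))

  # merge consecutive sub-intervals sharing a state
  runs <- rle(state)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, ends_idx[-length(ends_idx)] + 1L)
  iv <- data.frame(start = bp[starts_idx], end = bp[ends_idx + 1L],
                   state = runs$values)

  pick <- function(s) {
    out <- iv[iv$state == s, c("start", "end"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
  dur <- function(d) if (nrow(d)) sum(d$end - d$start) else 0

  below <- pick("below")
  above <- pick("above")
  structure(
    list(
      risk_windows = below,
      over_windows = above,
      time_below = dur(below),
      time_above = dur(above),
      time_in_range = (span[2L] - span[1L]) - dur(below) - dur(above),
      span = span
    ),
    class = "range_report"
  )
}

#' @export
print.range_report <- function(x, ...) {
  cat("<range_report> span [", x$span[1L], ",", x$span[2L], "] h\n")
  cat("  in range :", format(x$time_in_range, digits = 5), "h\n")
  cat("  below    :", format(x$time_below, digits = 5), "h in",
      nrow(x$risk_windows), "window(s)\n")
  cat("  above    :", format(x$time_above, digits = 5), "h in",
      nrow(x$over_windows), "window(s)\n")
  invisible(x)
}

#' Summary pharmacokinetics of a simulated cycle
#'
#' Bundles the quantities conventionally reported for the patch: plateau
#' concentration (third-week time average), per-week and mean weekly AUC,
#' elimination half-life implied by `k_elim`, and therapeutic-window
#' statistics over the wear period.
#'
#' @param series a [conc_series()] covering the wear period.
#' @param params the [drug_params()] the series was simulated with
#'   (supplies the therapeutic band and `k_elim`).
#' @param css_window plateau averaging window (h), default `c(336, 504)`.
#' @param wear_window window for the therapeutic-range analysis (h),
#'   default `c(0, 504)`.
#' @param n_weeks number of wear weeks for the AUC breakdown.
#' @return An object of class `pk_summary`: list with `hormone`, `unit`,
#'   `c_ss`, `auc_weekly`, `auc_0_168` (mean weekly AUC), `t_half`,
#'   `time_in_range`, `risk_windows`, `over_windows`.
#' @examples
#' ngmn <- pk_preset()$NGMN
#' s <- simulate_difference(ngmn, standard_cycle(), sim_grid(0.1, 600))
#' pk_summary(s, ngmn)
#' @export
pk_summary <- function(series, params, css_window = c(336, 504),
                       wear_window = c(0, 504), n_weeks = 3) {
  stopifnot(inherits(series, "conc_series"), inherits(params, "drug_params"))
  if (!identical(series$unit, params$conc_unit)) {
    stop("series unit ", series$unit, " does not match parameter unit ",
         params$conc_unit, call. = FALSE)
  }
  wk <- weekly_auc(series, n_weeks)
  rng <- range_crossings(series, params$therapeutic_low,
                         params$therapeutic_high, span = wear_window)
  structure(
    list(
      hormone = params$name,
      unit = params$conc_unit,
      c_ss = css(series, css_window),
      auc_weekly = wk$weekly,
      auc_0_168 = wk$mean,
      t_half = half_life(params$k_elim),
      time_in_range = rng$time_in_range,
      risk_windows = rng$risk_windows,
      over_windows = rng$over_windows
    ),
    class = "pk_summary"
  )
}

#' @export
print.pk_summary <- function(x, ...) {
  cat("<pk_summary>", x$hormone, "\n")
  cat("  C_ss          ", format(x$c_ss, digits = 4), x$unit, "\n")
  cat("  AUC/week      ", paste(format(x$auc_weekly, digits = 5),
                                collapse = ", "),
      " (mean ", format(x$auc_0_168, digits = 5), " ", x$unit, "*h)\n",
      sep = "")
  cat("  t_half        ", format(x$t_half, digits = 4), "h\n")
  cat("  time in range ", format(x$time_in_range, digits = 5), "h;",
      nrow(x$risk_windows), "risk window(s),",
      nrow(x$over_windows), "overexposure window(s)\n")
  invisible(x)
}
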