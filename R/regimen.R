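#' Patch wear events and regimens
#'
#' A regimen is the event timeline of one contraceptive cycle: patch
#' applications, scheduled replacements, (partial) detachments,
#' reattachments, and the final removal, together with a simulation
#' horizon. Events carry the fraction of patch contact area attached
#' *after* the event, which scales the absorption rate proportionally.
#'
#' Event semantics:
#' \describe{
#'   \item{`apply_new`}{a fresh patch is applied; patch age (the clock
#'     driving absorption attenuation) restarts at 0. Allowed only when no
#'     patch is attached. `area_fraction` is normally 1.}
#'   \item{`replace`}{the worn patch is swapped for a fresh one; patch age
#'     restarts at 0.}
#'   \item{`detach`}{part (or all) of the contact area detaches;
#'     `area_fraction` drops below 1 (0 = total detachment). Patch age
#'     keeps running: the patch keeps depleting whether or not it is
#'     fully adhered.}
#'   \item{`reattach`}{the same patch is pressed back on
#'     (`area_fraction` back up, usually to 1); patch age continues, it
#'     does not reset — only a fresh patch restores the zero-age release
#'     rate.}
#'   \item{`remove`}{the patch is taken off for good (end of cycle);
#'     absorption stops, leaving pure first-order decay.}
#' }
#'
#' @param time event time since cycle start (h), in `[0, horizon]`.
#' @param kind one of `"apply_new"`, `"replace"`, `"detach"`,
#'   `"reattach"`, `"remove"`.
#' @param area_fraction fraction of contact area attached after the event,
#'   in `[0, 1]`. Defaults to 1 for apply/replace/reattach, 0 for remove.
#' @return `patch_event()`: a one-row data frame with columns `time`,
#'   `kind`, `area_fraction`.
#' @examples
#' reg <- regimen(
#'   rbind(
#'     patch_event(0, "apply_new"),
#'     patch_event(168, "replace"),
#'     patch_event(336, "replace"),
#'     patch_event(504, "remove")
#'   ),
#'   horizon = 600
#' )
#' reg
#' @export
patch_event <- function(time, kind = c("apply_new", "replace", "detach",
                                       "reattach", "remove"),
                        area_fraction = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0) {
    stop("event `time` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(area_fraction)) {
    area_fraction <- if (kind == "remove") 0 else 1
  }
  if (!is.numeric(area_fraction) || length(area_fraction) != 1L ||
      is.na(area_fraction) || area_fraction < 0 || area_fraction > 1) {
    stop("`area_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (kind == "remove" && area_fraction != 0) {
    stop("a `remove` event must have area_fraction 0", call. = FALSE)
  }
  if (kind %in% c("apply_new", "replace") && area_fraction == 0) {
    stop("`", kind, "` must attach a positive area fraction", call. = FALSE)
  }
  data.frame(time = time, kind = kind, area_fraction = area_fraction,
             stringsAsFactors = FALSE)
}

#' @rdname patch_event
#' @param events data frame of events (rows from [patch_event()]); sorted
#'   by time on construction. The first event must be an `apply_new` and at
#'   most one patch may be attached at any instant (an `apply_new` while a
#'   patch is on is an overlapping-patch error; swapping goes through
#'   `replace`).
#' @param horizon total simulated time (h), > 0; all event times must lie
#'   in `[0, horizon]`.
#' @return `regimen()`: an object of class `regimen` — a list with the
#'   validated `events` data frame and `horizon`.
#' @export
regimen <- function(events, horizon) {
  if (!is.data.frame(events) ||
      !all(c("time", "kind", "area_fraction") %in% names(events)) ||
      nrow(events) == 0L) {
    stop("`events` must be a non-empty data frame with columns ",
         "time, kind, area_fraction", call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0) {
    stop("`horizon` must be a single positive number of hours", call. = FALSE)
  }
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  if (any(events$time < 0) || any(events$time > horizon)) {
    stop("event times must lie within [0, horizon]", call. = FALSE)
  }
  if (anyDuplicated(events$time)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  if (events$kind[1L] != "apply_new") {
    stop("the first event must be an `apply_new`", call. = FALSE)
  }

  # replay the state machine once to reject impossible sequences
  attached <- FALSE   # a patch is on the skin (possibly partially detached)
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    frac <- events$area_fraction[i]
    switch(kind,
      apply_new = {
        if (attached) {
          stop("overlapping patches: `apply_new` at t = ", events$time[i],
               " h while a patch is still attached (use `replace` or ",
               "`remove` first)", call. = FALSE)
        }
        attached <- TRUE
      },
      replace = {
        if (!attached) {
          stop("`replace` at t = ", events$time[i],
               " h with no patch to replace", call. = FALSE)
        }
      },
      detach = {
        if (!attached) {
          stop("`detach` at t = ", events$time[i],
               " h with no patch attached", call. = FALSE)
        }
        if (frac == 0) attached <- FALSE
      },
      reattach = {
        # pressing back a fully detached patch is allowed as long as it
        # was detached (not removed) and no new patch was applied since
      },
      remove = {
        attached <- FALSE
      }
    )
    if (kind == "reattach") attached <- TRUE
  }

  structure(list(events = events, horizon = horizon), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("<regimen> horizon ", x$horizon, " h, ", nrow(x$events),
      " events\n", sep = "")
  print(x$events, row.names = FALSE)
  invisible(x)
}

# Piecewise-constant wear state between events.
#
# Returns a data frame with one row per inter-event interval:
#   start, end        interval bounds (h); last row ends at the horizon
#   fraction          attached area fraction over the interval
#   age_origin        time at which the currently-worn patch was applied
#                     (NA when no patch has been applied / after removal)
# Absorption over an interval is
#   fraction * k0_rate * exp(-decay_h * (t - age_origin)).
regimen_segments <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  ev <- reg$events
  n <- nrow(ev)
  starts <- ev$time
  ends <- c(ev$time[-1L], reg$horizon)

  fraction <- numeric(n)
  age_origin <- rep(NA_real_, n)
  cur_origin <- NA_real_
  for (i in seq_len(n)) {
    kind <- ev$kind[i]
    if (kind %in% c("apply_new", "replace")) cur_origin <- ev$time[i]
    if (kind == "remove") cur_origin <- NA_real_
    fraction[i] <- if (kind == "remove") 0 else ev$area_fraction[i]
    age_origin[i] <- cur_origin
  }
  seg <- data.frame(start = starts, end = ends, fraction = fraction,
                    age_origin = age_origin)
  # leading no-patch interval if the first application is after t = 0
  if (seg$start[1L] > 0) {
    seg <- rbind(
      data.frame(start = 0, end = seg$start[1L], fraction = 0,
                 age_origin = NA_real_),
      seg
    )
  }
  seg[seg$end > seg$start, , drop = FALSE]
}

# Attached fraction and patch age evaluated at arbitrary times.
# Returns list(fraction, age); age is 0 where no patch is worn (the
# fraction is 0 there, so the absorption term vanishes regardless).
wear_state <- function(reg, times) {
  seg <- regimen_segments(reg)
  idx <- findInterval(times, seg$start)
  idx[idx < 1L] <- 1L
  frac <- seg$fraction[idx]
  origin <- seg$age_origin[idx]
  age <- ifelse(is.na(origin), 0, times - origin)
  frac[is.na(origin)] <- 0
  list(fraction = frac, age = age)
}
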