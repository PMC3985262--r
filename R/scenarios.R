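#' Standard three-week patch cycle
#'
#' One patch per week for three weeks: application at 0 h, scheduled
#' replacements at 168 h and 336 h, removal at 504 h, followed by a
#' patch-free observation window that exposes the terminal elimination
#' phase (used for estimating `k_elim` from the post-removal log-slope).
#'
#' @param decay_window extra patch-free time simulated after removal (h),
#'   `>= 0`; default 96 h.
#' @return A [regimen()].
#' @examples
#' standard_cycle()
#' @export
standard_cycle <- function(decay_window = 96) {
  stopifnot(is.numeric(decay_window), length(decay_window) == 1L,
            decay_window >= 0)
  regimen(
    rbind(
      patch_event(0, "apply_new"),
      patch_event(168, "replace"),
      patch_event(336, "replace"),
      patch_event(504, "remove")
    ),
    horizon = 504 + decay_window
  )
}

#' Delayed (or missed) second replacement
#'
#' Non-compliance scenario in which the user forgets to replace the patch
#' at the scheduled 336 h (day 14) and keeps the old patch for
#' `delay_days` more days before applying a fresh one. The absorption rate
#' of the retained patch keeps attenuating over the extra wear, so serum
#' concentrations sag until the late replacement restores the zero-age
#' release rate. The third patch is then worn a full week before removal.
#' A missed replacement is the same timeline with the delay running until
#' whenever a patch is finally applied.
#'
#' @param delay_days whole days of delay past the scheduled 336 h
#'   replacement, `>= 0`; 0 reduces to [standard_cycle()].
#' @param decay_window patch-free tail after the final removal (h).
#' @return A [regimen()].
#' @examples
#' delayed_replacement(3) # patch kept until day 17
#' @export
delayed_replacement <- function(delay_days, decay_window = 96) {
  if (!is.numeric(delay_days) || length(delay_days) != 1L ||
      !is.finite(delay_days) || delay_days < 0) {
    stop("`delay_days` must be a non-negative number of days", call. = FALSE)
  }
  if (delay_days == 0) return(standard_cycle(decay_window))
  t_late <- 336 + 24 * delay_days
  regimen(
    rbind(
      patch_event(0, "apply_new"),
      patch_event(168, "replace"),
      patch_event(t_late, "replace"),
      patch_event(t_late + 168, "remove")
    ),
    horizon = t_late + 168 + decay_window
  )
}

#' Partial or total patch detachment
#'
#' Inserts a detachment into the standard cycle: at `detach_time` the
#' attached contact area drops to `area_fraction` (0 = complete
#' detachment), and after `duration` hours the wearer either presses the
#' same patch back on (`reattach_as_new = FALSE`; the patch has kept
#' aging, so its release rate does not recover) or applies a fresh patch
#' (`reattach_as_new = TRUE`; patch age resets — what the manufacturer
#' instructs after a prolonged total detachment).
#'
#' @param detach_time detachment time (h); must fall within a
#'   patch-wearing interval of the standard cycle, and the detachment must
#'   end before the next scheduled event.
#' @param area_fraction contact-area fraction remaining attached, in
#'   `[0, 1]`; 1 is a no-op (returns [standard_cycle()]).
#' @param duration detachment length (h), `>= 0`; 0 is a no-op.
#' @param reattach_as_new logical; `TRUE` models applying a fresh patch at
#'   the end of the detachment instead of reattaching the old one.
#' @param decay_window patch-free tail after the final removal (h).
#' @return A [regimen()].
#' @examples
#' # half the contact area lost at the end of day 3, for a day
#' detachment(72, area_fraction = 0.5, duration = 24)
#' # complete detachment for 24 h in week 2, then a fresh patch
#' detachment(192, area_fraction = 0, duration = 24, reattach_as_new = TRUE)
#' @export
detachment <- function(detach_time, area_fraction, duration = 24,
                       reattach_as_new = FALSE, decay_window = 96) {
  stopifnot(is.numeric(detach_time), length(detach_time) == 1L,
            is.numeric(area_fraction), length(area_fraction) == 1L,
            is.numeric(duration), length(duration) == 1L, duration >= 0)
  if (area_fraction < 0 || area_fraction > 1) {
    stop("`area_fraction` must lie in [0, 1]", call. = FALSE)
  }
  base <- standard_cycle(decay_window)
  if (area_fraction == 1 || duration == 0) return(base)

  sched <- base$events$time # 0, 168, 336, 504
  if (detach_time <= 0 || detach_time >= 504) {
    stop("`detach_time` must fall while a patch is worn (0 < t < 504 h)",
         call. = FALSE)
  }
  wear_end <- sched[findInterval(detach_time, sched) + 1L]
  t_back <- detach_time + duration
  if (detach_time %in% sched || t_back >= wear_end) {
    stop("the detachment interval must lie strictly inside one wear week ",
         "(ends before the next scheduled event at ", wear_end, " h)",
         call. = FALSE)
  }

  back_kind <- if (reattach_as_new) {
    if (area_fraction > 0) {
      stop("`reattach_as_new = TRUE` requires a total detachment ",
           "(area_fraction = 0): a fresh patch cannot overlap one still ",
           "partially attached", call. = FALSE)
    }
    "apply_new"
  } else {
    "reattach"
  }

  regimen(
    rbind(
      base$events,
      patch_event(detach_time, "detach", area_fraction),
      patch_event(t_back, back_kind, 1)
    ),
    horizon = base$horizon
  )
}
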