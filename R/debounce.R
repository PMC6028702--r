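# Sensor debouncing: the ball-lift sensor fires on every lift, but a revisit
# only counts if the animal visited another hole in between, or if at least
# 10 s elapsed between successive lifts at the same hole.

#' Debounce a stream of ball-lift events into visits
#'
#' Collapses consecutive lifts of the same hole that occur within
#' `window` seconds with no other hole visited in between into a single
#' visit carrying the first lift's timestamp. The window is closed on the
#' left and open on the right: a second lift at exactly `window` seconds
#' counts as a new visit. All other lifts pass through; order is preserved.
#'
#' @param hole Integer vector of hole indices (0-15), one per lift.
#' @param t Numeric vector of lift times in seconds from arena entry,
#'   nondecreasing, nonnegative.
#' @param window Debounce window in seconds (default 10).
#' @return A data frame with columns `hole` and `t`, one row per visit.
#' @examples
#' debounce_events(c(3, 3, 5), c(1, 4, 9))   # second lift collapsed
#' debounce_events(c(3, 3), c(1, 12))        # gap >= 10 s: a revisit
#' debounce_events(c(3, 5, 3), c(1, 3, 5))   # intervening hole: a revisit
#' @export
debounce_events <- function(hole, t, window = 10) {
  if (length(hole) != length(t))
    stop("hole and t must have equal length")
  if (length(t) == 0L)
    return(data.frame(hole = integer(0), t = numeric(0)))
  if (any(is.na(hole)) || any(is.na(t)))
    stop("missing values in lift events")
  bad <- which(t < 0)
  if (length(bad))
    stop(sprintf("negative timestamp at lift %d (t = %g)", bad[1], t[bad[1]]))
  bad <- which(diff(t) < 0)
  if (length(bad))
    stop(sprintf("non-monotone timestamps at lift %d (t = %g after %g)",
                 bad[1] + 1L, t[bad[1] + 1L], t[bad[1]]))
  hole <- as.integer(hole)
  n <- length(hole)
  # a lift is suppressed iff it repeats the immediately preceding lift's hole
  # within the window; suppressed lifts extend the open visit, so comparing
  # against the previous *lift* (not the previous kept visit) implements the
  # chain rule and makes the operation idempotent.
  keep <- c(TRUE, !(hole[-1L] == hole[-n] & (t[-1L] - t[-n]) < window))
  data.frame(hole = hole[keep], t = t[keep])
}
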