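#' Goal-difference timeline of a game
#'
#' Builds the piecewise-constant goal difference (GD) function `d(t)` over
#' the game clock from the list of goal events.  GD is the observed
#' team's score minus the opponent's, clipped segment-wise to
#' `{-2, -1, 0, 1, 2}`: being two or more goals up (or down) is treated
#' as a single state.  Segments are right-open, so the GD changes exactly
#' at the goal minute and an interval starting at a goal minute already
#' carries the new value.
#'
#' @param events A data frame with columns `minute` (game minute, real,
#'   in `[0, duration]`) and `side` (`"for"` = goal scored by the team,
#'   `"against"` = goal conceded), or `NULL`/zero rows for a goalless game.
#' @param duration Total game duration in minutes (stoppage time included).
#'
#' @return An object of class `"gd_timeline"`: a list with `breakpoints`
#'   (segment start minutes, first is 0), `values` (clipped GD per
#'   segment), `raw_values` (unclipped running score margins, kept for
#'   audit) and `duration`.
#'
#' @examples
#' tl <- build_gd_timeline(data.frame(minute = c(10, 25, 70),
#'                                    side = c("for", "for", "against")), 90)
#' gd_at(tl, c(5, 10, 30, 80))  # 0 1 2 1
#' @export
build_gd_timeline <- function(events, duration) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("'duration' must be a single positive number of minutes")
  }
  if (is.null(events) || nrow(events) == 0L) {
    return(structure(list(breakpoints = 0, values = 0L, raw_values = 0L,
                          duration = duration),
                     class = "gd_timeline"))
  }
  if (!all(c("minute", "side") %in% names(events))) {
    stop("'events' needs columns 'minute' and 'side'")
  }
  if (!all(events$side %in% c("for", "against"))) {
    stop("goal 'side' must be \"for\" or \"against\"")
  }
  if (any(events$minute < 0 | events$minute > duration)) {
    stop("goal event outside the game duration")
  }
  events <- events[order(events$minute), , drop = FALSE]
  raw <- cumsum(ifelse(events$side == "for", 1L, -1L))
  bps <- c(0, events$minute)
  raw <- c(0L, raw)
  # two goals at the same minute collapse into one segment (last wins)
  keep <- !duplicated(bps, fromLast = TRUE)
  structure(
    list(breakpoints = bps[keep],
         values = pmax(pmin(raw[keep], 2L), -2L),
         raw_values = raw[keep],
         duration = duration),
    class = "gd_timeline"
  )
}

#' Goal difference at given game minutes
#'
#' Evaluates the piecewise-constant GD function at the supplied minutes
#' (right-open convention: at a goal minute the new GD applies).
#'
#' @param timeline A [build_gd_timeline()] object.
#' @param t Vector of game minutes.
#' @return Integer vector of clipped GD values.
#' @export
gd_at <- function(timeline, t) {
  stopifnot(inherits(timeline, "gd_timeline"))
  timeline$values[findInterval(t, timeline$breakpoints)]
}

#' @export
print.gd_timeline <- function(x, ...) {
  n <- length(x$breakpoints)
  seg_end <- c(x$breakpoints[-1L], x$duration)
  cat(sprintf("GD timeline over [0, %g) min, %d segment(s):\n", x$duration, n))
  for (i in seq_len(n)) {
    cat(sprintf("  [%6.2f, %6.2f): GD %+d\n", x$breakpoints[i], seg_end[i],
                x$values[i]))
  }
  invisible(x)
}
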