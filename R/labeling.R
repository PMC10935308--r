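#' Label energy intervals with goal difference and expectation
#'
#' Joins a player's measured 5-minute energy records with the game's GD
#' timeline and pre-game expectation, restricted to the player's stint.
#' Records flagged as non-playing time (warm-up before kickoff, the
#' dressing-room window around halftime) are discarded, as are records
#' that do not overlap the stint by at least `min_overlap` minutes.
#'
#' @param intervals Data frame of energy records with columns `start_min`,
#'   `end_min` (game minutes, nominally 5 apart), `energy` (J/kg) and
#'   `playing_flag` (logical, `FALSE` marks records to discard); extra
#'   columns (`player_id`, `game_id`, ...) are carried through.
#' @param timeline A [build_gd_timeline()] object for the game.
#' @param stint List or one-row data frame with entry/exit minutes `t_s`
#'   and `t_e` (half-open stint `[t_s, t_e)`).
#' @param expectation An [compute_expectation()] object or `"f"`/`"nf"`.
#' @param min_overlap Minimum overlap (minutes) with the stint for a
#'   record to be kept.  The default `NULL` requires full containment
#'   (`t_s <= start_min` and `end_min <= t_e`), which for 5-minute
#'   records is a 5-minute overlap and avoids rescaling energies.
#'
#' @return A data frame of kept records with added columns `gd` (clipped
#'   GD at `start_min`), `expectation` (`"f"`/`"nf"`) and `tau_start`
#'   (playing-time minute at `start_min`, i.e. `start_min - t_s`).
#'   May have zero rows.
#'
#' @details The GD label is the timeline value at the record's start
#'   minute even when a goal falls inside the record; the 1-minute
#'   forward model ([simulate_energy()]) does track mid-record GD
#'   changes, labels are only used for baselines and the minutes ledger.
#' @export
label_intervals <- function(intervals, timeline, stint, expectation,
                            min_overlap = NULL) {
  stopifnot(inherits(timeline, "gd_timeline"))
  needed <- c("start_min", "end_min", "energy", "playing_flag")
  if (!all(needed %in% names(intervals))) {
    stop("'intervals' needs columns ", paste(needed, collapse = ", "))
  }
  t_s <- stint$t_s
  t_e <- stint$t_e
  if (is.null(t_s) || is.null(t_e) || t_s < 0 || t_s >= t_e) {
    stop("invalid stint: need 0 <= t_s < t_e")
  }
  e <- .model_class(expectation)
  iv <- intervals[order(intervals$start_min), , drop = FALSE]

  if (is.null(min_overlap)) {
    keep <- iv$start_min >= t_s & iv$end_min <= t_e
  } else {
    ov <- pmax(0, pmin(iv$end_min, t_e) - pmax(iv$start_min, t_s))
    keep <- ov >= min_overlap & ov > 0
  }
  keep <- keep & as.logical(iv$playing_flag)
  out <- iv[keep, , drop = FALSE]
  out$gd <- if (nrow(out)) gd_at(timeline, out$start_min) else integer(0)
  out$expectation <- rep(e, nrow(out))
  out$tau_start <- out$start_min - t_s
  rownames(out) <- NULL
  out
}
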