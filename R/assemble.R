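#' Read the four pipeline input CSVs
#'
#' Expects `fixtures.csv` (`game_id, p_win, p_draw, p_lose, duration`),
#' `goals.csv` (`game_id, minute, side`), `stints.csv`
#' (`player_id, game_id, t_s, t_e`) and `energy.csv`
#' (`player_id, game_id, start_min, end_min, energy_jkg, playing_flag`),
#' UTF-8 with a header row and dot decimal separator.
#'
#' @param dir Directory containing the four files.
#' @return List with data frames `fixtures`, `goals`, `stints`,
#'   `energy` (energy column renamed to `energy`).
#' @export
read_match_inputs <- function(dir) {
  files <- c(fixtures = "fixtures.csv", goals = "goals.csv",
             stints = "stints.csv", energy = "energy.csv")
  paths <- file.path(dir, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing input file(s): ", paste(files[missing], collapse = ", "))
  }
  out <- lapply(paths, utils::read.csv)
  names(out) <- names(files)
  names(out$energy)[names(out$energy) == "energy_jkg"] <- "energy"
  out$energy$playing_flag <- as.logical(out$energy$playing_flag)
  out
}

#' Assemble one player's games for fitting
#'
#' Joins fixtures, goal events, stints and energy records into the
#' per-player games list consumed by [cost_function()],
#' [fit_nelder_mead()] and [predict_intervals()]: one entry per game the
#' player appeared in, holding the labeled intervals, the GD timeline,
#' the stint and the expectation class.
#'
#' @param fixtures,goals,stints,energy Data frames as read by
#'   [read_match_inputs()] (or the fields of a synthetic dataset).
#' @param player_id The player to assemble.
#' @param min_overlap Passed to [label_intervals()].
#' @return List of games (possibly with zero-row interval frames for
#'   games where everything was discarded).
#' @export
assemble_player_games <- function(fixtures, goals, stints, energy, player_id,
                                  min_overlap = NULL) {
  st <- stints[stints$player_id == player_id, , drop = FALSE]
  if (nrow(st) == 0L) stop("no stints for player ", player_id)
  lapply(seq_len(nrow(st)), function(i) {
    row <- st[i, ]
    fx <- fixtures[fixtures$game_id == row$game_id, , drop = FALSE]
    if (nrow(fx) != 1L) stop("fixture not found for game ", row$game_id)
    tl <- build_gd_timeline(goals[goals$game_id == row$game_id, , drop = FALSE],
                            fx$duration)
    ex <- if (fx$p_win == 0 && fx$p_lose == 0) {
      "nf"  # degenerate certain-draw odds: clearly not the favorite
    } else {
      compute_expectation(fx$p_win, fx$p_lose, fx$p_draw)
    }
    iv <- energy[energy$player_id == player_id &
                   energy$game_id == row$game_id, , drop = FALSE]
    list(intervals = label_intervals(iv, tl, row, ex, min_overlap = min_overlap),
         timeline = tl,
         stint = list(player_id = player_id, game_id = row$game_id,
                      t_s = row$t_s, t_e = row$t_e),
         expectation = ex)
  })
}

#' @rdname assemble_player_games
#' @param dataset A [generate_dataset()] result.
#' @export
dataset_player_games <- function(dataset, player_id, min_overlap = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  assemble_player_games(dataset$fixtures, dataset$goals, dataset$stints,
                        dataset$energy, player_id, min_overlap = min_overlap)
}
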