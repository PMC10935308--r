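#' Win/draw/lose probabilities of two independent Poisson scorers
#'
#' The generator's odds model: given expected goal counts for the team
#' and its opponent over the game, the match outcome probabilities are
#' those of two independent Poisson counts (the difference follows a
#' Skellam distribution).  Tying the betting odds to the same rates that
#' drive the simulated goal times makes favorite games skew the GD
#' distribution positive, as in a real favorite-heavy schedule.
#'
#' @param rate_for,rate_against Expected goals for the team and the
#'   opponent over the full game.
#' @param max_goals Truncation of the Poisson support (default 20).
#' @return Named vector `c(p_win, p_draw, p_lose)` summing to ~1.
#' @export
match_outcome_probs <- function(rate_for, rate_against, max_goals = 20) {
  stopifnot(rate_for >= 0, rate_against >= 0)
  pf <- stats::dpois(0:max_goals, rate_for)
  pa <- stats::dpois(0:max_goals, rate_against)
  M <- outer(pf, pa)
  d <- outer(0:max_goals, 0:max_goals, "-")
  c(p_win = sum(M[d > 0]), p_draw = sum(M[d == 0]), p_lose = sum(M[d < 0]))
}

#' Configuration of the synthetic match/trace generator
#'
#' Defaults emulate the shape of a single-team season of GPS external
#' load data: 33 games, 19 players, a favorite-heavy schedule (about
#' two-thirds of games have an odds ratio of 2 or more), left-skewed GD
#' minutes, 5-minute energy records with additive noise, and occasional
#' substitutions.  All randomness flows from `seed`.
#'
#' @param n_players,n_games Season size (defaults 19 and 33).
#' @param games_per_player Games sampled per player (capped at
#'   `n_games`).
#' @param duration Game length in minutes; must be a multiple of 5.
#' @param team_rate,opp_rate Ranges (length 2) for the per-game expected
#'   goals (per 90 min) of the team and opponent; defaults
#'   `c(1.0, 2.6)` and `c(0.5, 1.5)` give a favorite share near 21/33.
#' @param p_sub Probability a player's stint is a substitution rather
#'   than the full game.
#' @param sub_on_window,sub_off_window Minute windows for entry of a
#'   substitute / exit of a replaced starter (snapped to the 5-min grid).
#' @param power_range Range the true powers are drawn from (inside the
#'   `[200, 800]` fitting box).
#' @param eta90_range Range of the true endurance coefficient.
#' @param expectation_contrast Guaranteed gap `|P_f - P_nf|` (J/kg/min)
#'   imposed at `contrast_gds` randomly chosen GD levels, so that
#'   expectation has a real effect for the model to find.
#' @param contrast_gds How many GD levels receive the contrast.
#' @param noise_sd Gaussian noise s.d. per 5-minute record (J/kg),
#'   truncated so energies stay non-negative.
#' @param flagged_windows List of `c(start, end)` game-minute windows
#'   whose records are flagged as non-playing time (warm-up and the
#'   halftime dressing room); default `[0,5)` and `[45,50)`.
#' @param scripted_games Optional list of scripted games (see
#'   [coverage_schedule()]), each `list(p_win, p_draw, p_lose, goals)`;
#'   recycled over `n_games` instead of random schedules.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_players = 19, n_games = 33,
                             games_per_player = 10, duration = 90,
                             team_rate = c(1.0, 2.6), opp_rate = c(0.5, 1.5),
                             p_sub = 0.25, sub_on_window = c(45, 75),
                             sub_off_window = c(60, 85),
                             power_range = c(250, 750),
                             eta90_range = c(0.6, 0.85),
                             expectation_contrast = 150, contrast_gds = 2,
                             noise_sd = 150,
                             flagged_windows = list(c(0, 5), c(45, 50)),
                             scripted_games = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (duration %% 5 != 0 || duration <= 0) {
    stop("'duration' must be a positive multiple of 5 minutes")
  }
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (any(team_rate < 0) || any(opp_rate < 0)) stop("goal rates must be >= 0")
  if (power_range[1] < 200 || power_range[2] > 800 ||
      power_range[1] > power_range[2]) {
    stop("'power_range' must lie inside [200, 800]")
  }
  if (eta90_range[1] < 0.5 || eta90_range[2] > 1 ||
      eta90_range[1] > eta90_range[2]) {
    stop("'eta90_range' must lie inside [0.5, 1]")
  }
  for (w in list(sub_on_window, sub_off_window)) {
    if (w[1] < 0 || w[2] > duration || w[1] >= w[2]) {
      stop("substitution window outside the game")
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Scripted game schedule covering every (GD, expectation) state
#'
#' Four deterministic game scripts - favorite and non-favorite versions
#' of a "fall two behind then recover" and a "go two up then get pegged
#' back" scoreline - that together visit every GD in `{-2..2}` under
#' both expectation classes.  One cycle yields, per expectation class,
#' 50 labeled minutes at GD 0, 40 at GD +/-1 and 15 at GD +/-2 (after
#' the default warm-up/halftime records are discarded), so two cycles
#' (8 games) give every cell at least 20 minutes: the coverage needed
#' for full parameter-recovery studies.
#'
#' @param duration Game length (multiple of 5).
#' @return List of 4 scripted games for `scripted_games` in
#'   [synthetic_config()].
#' @export
coverage_schedule <- function(duration = 90) {
  down_up <- data.frame(minute = c(20, 40, 60, 80),
                        side = c("against", "against", "for", "for"))
  up_down <- data.frame(minute = c(20, 40, 60, 80),
                        side = c("for", "for", "against", "against"))
  fav <- c(p_win = 0.6, p_draw = 0.2, p_lose = 0.2)    # e = 3  -> favorite
  nf <- c(p_win = 0.3, p_draw = 0.3, p_lose = 0.4)     # e = 0.75 -> close/nf
  list(
    list(p_win = fav[[1]], p_draw = fav[[2]], p_lose = fav[[3]], goals = down_up),
    list(p_win = fav[[1]], p_draw = fav[[2]], p_lose = fav[[3]], goals = up_down),
    list(p_win = nf[[1]], p_draw = nf[[2]], p_lose = nf[[3]], goals = down_up),
    list(p_win = nf[[1]], p_draw = nf[[2]], p_lose = nf[[3]], goals = up_down)
  )
}

# True parameters for one player: powers uniform in power_range, with a
# guaranteed favorite/non-favorite contrast at `contrast_gds` GD levels.
.sample_truth <- function(config) {
  P <- matrix(stats::runif(10, config$power_range[1], config$power_range[2]),
              5, 2)
  if (config$contrast_gds > 0 && config$expectation_contrast > 0) {
    rows <- sample(5, min(config$contrast_gds, 5))
    for (i in rows) {
      P[i, 2] <- if (P[i, 1] + config$expectation_contrast <= 800) {
        P[i, 1] + config$expectation_contrast
      } else {
        P[i, 1] - config$expectation_contrast
      }
    }
  }
  player_parameters(P, eta90 = stats::runif(1, config$eta90_range[1],
                                            config$eta90_range[2]))
}

.snap5 <- function(w) seq(ceiling(w[1] / 5) * 5, floor(w[2] / 5) * 5, by = 5)

#' Generate a synthetic season with known ground truth
#'
#' Draws a schedule (odds tied to Poisson goal rates, or scripted
#' games), true player parameters, stints and 5-minute energy records
#' equal to the forward model's noiseless interval energies plus
#' truncated Gaussian noise.  Records in the flagged warm-up/halftime
#' windows carry `playing_flag = FALSE` (and suppressed energies, as a
#' dressing-room record would).
#'
#' @param config A [synthetic_config()].
#' @return Object of class `"synthetic_dataset"`: data frames
#'   `fixtures` (with audit columns `score_for`/`score_against`, the raw
#'   unclipped final margin), `goals`, `stints`, `energy`; plus
#'   `ground_truth` (true [player_parameters()] per player),
#'   `noiseless` (noise-free energies) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  duration <- config$duration

  fixtures <- NULL
  goals <- NULL
  for (j in seq_len(config$n_games)) {
    gid <- sprintf("G%02d", j)
    if (!is.null(config$scripted_games)) {
      sc <- config$scripted_games[[(j - 1L) %% length(config$scripted_games) + 1L]]
      probs <- c(sc$p_win, sc$p_draw, sc$p_lose)
      ev <- sc$goals
    } else {
      lt <- stats::runif(1, config$team_rate[1], config$team_rate[2]) * duration / 90
      lo <- stats::runif(1, config$opp_rate[1], config$opp_rate[2]) * duration / 90
      probs <- match_outcome_probs(lt, lo)
      n_for <- stats::rpois(1, lt)
      n_against <- stats::rpois(1, lo)
      ev <- data.frame(minute = stats::runif(n_for + n_against, 0, duration),
                       side = rep(c("for", "against"), c(n_for, n_against)))
      ev <- ev[order(ev$minute), , drop = FALSE]
    }
    n_for <- sum(ev$side == "for")
    n_against <- sum(ev$side == "against")
    fixtures <- rbind(fixtures, data.frame(
      game_id = gid, p_win = probs[[1]], p_draw = probs[[2]],
      p_lose = probs[[3]], duration = duration,
      score_for = n_for, score_against = n_against))
    if (nrow(ev)) {
      goals <- rbind(goals, data.frame(game_id = gid, minute = ev$minute,
                                       side = ev$side))
    }
  }
  if (is.null(goals)) {
    goals <- data.frame(game_id = character(0), minute = numeric(0),
                        side = character(0))
  }

  players <- sprintf("athlete%02d", seq_len(config$n_players))
  ground_truth <- stats::setNames(lapply(players, function(p) .sample_truth(config)),
                                  players)

  gpp <- min(config$games_per_player, config$n_games)
  stints <- NULL
  for (p in players) {
    gsel <- sort(sample(config$n_games, gpp))
    for (j in gsel) {
      if (stats::runif(1) < config$p_sub) {
        if (stats::runif(1) < 0.5) {   # replaced starter
          t_s <- 0
          t_e <- sample(.snap5(config$sub_off_window), 1)
        } else {                        # substitute coming on
          t_s <- sample(.snap5(config$sub_on_window), 1)
          t_e <- duration
        }
      } else {
        t_s <- 0
        t_e <- duration
      }
      stints <- rbind(stints, data.frame(player_id = p,
                                         game_id = sprintf("G%02d", j),
                                         t_s = t_s, t_e = t_e))
    }
  }

  timelines <- lapply(seq_len(config$n_games), function(j) {
    gid <- sprintf("G%02d", j)
    build_gd_timeline(goals[goals$game_id == gid, , drop = FALSE], duration)
  })
  names(timelines) <- fixtures$game_id
  exp_class <- vapply(seq_len(config$n_games), function(j) {
    if (fixtures$p_win[j] == 0 && fixtures$p_lose[j] == 0) {
      "nf"  # degenerate certain draw (both rates zero)
    } else {
      compute_expectation(fixtures$p_win[j], fixtures$p_lose[j])$model_class
    }
  }, "")
  names(exp_class) <- fixtures$game_id

  energy <- NULL
  noiseless <- NULL
  for (i in seq_len(nrow(stints))) {
    st <- stints[i, ]
    truth <- ground_truth[[st$player_id]]
    tr <- simulate_energy(truth, timelines[[st$game_id]], st,
                          exp_class[[st$game_id]], dt = 1)
    bounds <- seq(st$t_s, st$t_e, by = 5)
    iv <- data.frame(start_min = bounds[-length(bounds)], end_min = bounds[-1L])
    clean <- interval_energies(tr, iv, st)
    flagged <- rep(FALSE, nrow(iv))
    for (w in config$flagged_windows) {
      flagged <- flagged | (iv$start_min < w[2] & iv$end_min > w[1])
    }
    noisy <- pmax(0, clean + stats::rnorm(nrow(iv), 0, config$noise_sd))
    # dressing-room records carry suppressed, meaningless energies
    noisy[flagged] <- noisy[flagged] * stats::runif(sum(flagged), 0.1, 0.5)
    energy <- rbind(energy, data.frame(
      player_id = st$player_id, game_id = st$game_id,
      start_min = iv$start_min, end_min = iv$end_min,
      energy = noisy, playing_flag = !flagged))
    noiseless <- rbind(noiseless, data.frame(
      player_id = st$player_id, game_id = st$game_id,
      start_min = iv$start_min, end_min = iv$end_min, energy = clean))
  }

  structure(list(fixtures = fixtures, goals = goals, stints = stints,
                 energy = energy, ground_truth = ground_truth,
                 noiseless = noiseless, config = config),
            class = "synthetic_dataset")
}

#' Labeled minutes per goal difference in a dataset
#'
#' Labels every player's records and sums the kept minutes per GD level,
#' the synthetic counterpart of a season's GD-minutes distribution (a
#' favorite-heavy schedule skews it toward positive GD).
#'
#' @param dataset A [generate_dataset()] result.
#' @param min_overlap Passed to [label_intervals()].
#' @return Named numeric vector of minutes over GD `-2..2`.
#' @export
summarize_gd_minutes <- function(dataset, min_overlap = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  out <- stats::setNames(numeric(5), .GD_LEVELS)
  for (p in unique(dataset$stints$player_id)) {
    games <- assemble_player_games(dataset$fixtures, dataset$goals,
                                   dataset$stints, dataset$energy, p,
                                   min_overlap = min_overlap)
    for (g in games) {
      iv <- g$intervals
      if (nrow(iv) == 0L) next
      len <- iv$end_min - iv$start_min
      for (d in .GD_LEVELS) {
        out[d] <- out[d] + sum(len[iv$gd == as.integer(d)])
      }
    }
  }
  out
}

#' Write a synthetic dataset as the pipeline's input CSVs
#'
#' Emits `fixtures.csv`, `goals.csv`, `stints.csv`, `energy.csv` (the
#' preprocessing input contract), `ground_truth.json` and a
#' `manifest.json` recording the generator configuration.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$fixtures, file.path(dir, "fixtures.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$goals, file.path(dir, "goals.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$stints, file.path(dir, "stints.csv"),
                   row.names = FALSE)
  en <- dataset$energy
  names(en)[names(en) == "energy"] <- "energy_jkg"
  utils::write.csv(en, file.path(dir, "energy.csv"), row.names = FALSE)
  gt <- lapply(dataset$ground_truth, function(p) as.list(as_param_vector(p)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- dataset$config
  cfg$scripted_games <- if (is.null(cfg$scripted_games)) NULL else "scripted"
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
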