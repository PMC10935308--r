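# Fixture builders shared across tests.  Everything is generated in code
# from the package's own forward model, so "measured" energies are exact
# model outputs unless noise is requested.

# One game whose interval energies come from the forward model.
make_model_game <- function(params, goals = NULL, duration = 90,
                            t_s = 0, t_e = duration, expectation = "f",
                            noise_sd = 0, drop_windows = list(),
                            game_id = "g1") {
  tl <- build_gd_timeline(goals, duration)
  stint <- list(player_id = "p1", game_id = game_id, t_s = t_s, t_e = t_e)
  tr <- simulate_energy(params, tl, stint, expectation)
  bounds <- seq(t_s, t_e, by = 5)
  iv <- data.frame(start_min = bounds[-length(bounds)], end_min = bounds[-1])
  iv$energy <- interval_energies(tr, iv, stint)
  if (noise_sd > 0) {
    iv$energy <- pmax(0, iv$energy + stats::rnorm(nrow(iv), 0, noise_sd))
  }
  iv$playing_flag <- TRUE
  for (w in drop_windows) {
    iv$playing_flag[iv$start_min < w[2] & iv$end_min > w[1]] <- FALSE
  }
  list(intervals = label_intervals(iv, tl, stint, expectation),
       timeline = tl, stint = stint, expectation = expectation)
}

# Generator config with scripted schedules guaranteeing coverage of all
# ten (GD, expectation) cells; n_cycles = 2 gives >= 30 min per cell.
recovery_config <- function(n_players, noise_sd, seed, n_cycles = 2, ...) {
  synthetic_config(n_players = n_players, n_games = 4 * n_cycles,
                   games_per_player = 4 * n_cycles, p_sub = 0,
                   noise_sd = noise_sd, scripted_games = coverage_schedule(),
                   seed = seed, ...)
}

# Example parameter set with distinct powers per state.
example_params <- function(eta90 = 0.8) {
  P <- cbind(f = c(700, 650, 500, 420, 380),
             nf = c(620, 560, 540, 500, 460))
  player_parameters(P, eta90 = eta90)
}
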