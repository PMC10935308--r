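test_that("outcome probabilities are a proper Skellam-type split", {
  p <- match_outcome_probs(2, 2)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(unname(p["p_win"]), unname(p["p_lose"]), tolerance = 1e-12)
  strong <- match_outcome_probs(3, 0.5)
  expect_gt(strong[["p_win"]] / strong[["p_lose"]], 2)  # clear favorite
  none <- match_outcome_probs(0, 0)
  expect_equal(none[["p_draw"]], 1)
})

test_that("config validation rejects infeasible settings", {
  expect_error(synthetic_config(duration = 92), "multiple of 5")
  expect_error(synthetic_config(noise_sd = -1), "non-negative")
  expect_error(synthetic_config(sub_on_window = c(80, 95)), "window")
  expect_error(synthetic_config(power_range = c(100, 700)), "\\[200, 800\\]")
  expect_error(synthetic_config(eta90_range = c(0.3, 0.9)), "\\[0.5, 1\\]")
})

test_that("zero goal rates yield an all-GD0 season", {
  cfg <- synthetic_config(n_players = 2, n_games = 4, games_per_player = 4,
                          team_rate = c(0, 0), opp_rate = c(0, 0),
                          noise_sd = 50, seed = 5)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$goals), 0L)
  mins <- summarize_gd_minutes(ds)
  expect_true(all(mins[c("-2", "-1", "1", "2")] == 0))
  expect_gt(mins[["0"]], 0)
})

test_that("generation is deterministic and CSV output byte-identical", {
  cfg <- synthetic_config(n_players = 2, n_games = 5, games_per_player = 4,
                          seed = 12)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$energy, d2$energy)
  expect_identical(d1$goals, d2$goals)
  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
})

test_that("noiseless energies are exact model output (cost 0 at truth)", {
  cfg <- synthetic_config(n_players = 3, n_games = 6, games_per_player = 5,
                          noise_sd = 0, seed = 23)
  ds <- generate_dataset(cfg)
  for (p in names(ds$ground_truth)) {
    games <- dataset_player_games(ds, p)
    expect_lt(cost_function(ds$ground_truth[[p]], games), 1e-16)
  }
})

test_that("GD values stay clipped while raw margins are preserved", {
  cfg <- synthetic_config(n_players = 1, n_games = 20, games_per_player = 20,
                          team_rate = c(3.5, 4), opp_rate = c(0.2, 0.5),
                          seed = 29)
  ds <- generate_dataset(cfg)
  for (gid in ds$fixtures$game_id) {
    tl <- build_gd_timeline(ds$goals[ds$goals$game_id == gid, ], 90)
    expect_true(all(tl$values %in% -2:2))
    fx <- ds$fixtures[ds$fixtures$game_id == gid, ]
    expect_equal(tail(tl$raw_values, 1), fx$score_for - fx$score_against)
  }
  # at least one game ran up a margin beyond the clip in this config
  expect_gt(max(ds$fixtures$score_for - ds$fixtures$score_against), 2)
})

test_that("a favorite-heavy schedule skews GD minutes positive", {
  cfg <- synthetic_config(n_players = 2, n_games = 30, games_per_player = 30,
                          team_rate = c(2, 2), opp_rate = c(1, 1),
                          noise_sd = 0, seed = 61)
  ds <- generate_dataset(cfg)
  mins <- summarize_gd_minutes(ds)
  expect_gt(mins[["1"]] + mins[["2"]], mins[["-1"]] + mins[["-2"]])
  # conservation: histogram totals equal total labeled minutes
  total <- 0
  for (p in unique(ds$stints$player_id)) {
    for (g in dataset_player_games(ds, p)) {
      total <- total + sum(g$intervals$end_min - g$intervals$start_min)
    }
  }
  expect_equal(sum(mins), total)
})

test_that("flagged warm-up and halftime records are emitted and excluded", {
  cfg <- synthetic_config(n_players = 1, n_games = 2, games_per_player = 2,
                          p_sub = 0, seed = 71)
  ds <- generate_dataset(cfg)
  en <- ds$energy
  expect_true(all(!en$playing_flag[en$start_min %in% c(0, 45)]))
  expect_true(all(en$playing_flag[en$start_min %in% c(10, 60)]))
  games <- dataset_player_games(ds, "athlete01")
  lab <- do.call(rbind, lapply(games, `[[`, "intervals"))
  expect_false(any(lab$start_min %in% c(0, 45)))
})
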