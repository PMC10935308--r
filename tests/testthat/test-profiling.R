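test_that("minutes ledger sums labeled interval lengths per state", {
  expect_true(all(minutes_ledger(NULL) == 0))

  lab <- data.frame(start_min = seq(0, 85, 5), end_min = seq(5, 90, 5),
                    energy = 2500, playing_flag = TRUE, gd = 0L,
                    expectation = "f", tau_start = seq(0, 85, 5))
  led <- minutes_ledger(lab)
  expect_equal(led["0", "f"], 90)   # 18 x 5 min
  expect_equal(sum(led), 90)

  set.seed(13)
  mix <- data.frame(start_min = 0, end_min = 5, energy = 2500,
                    playing_flag = TRUE,
                    gd = sample(-2:2, 40, replace = TRUE),
                    expectation = sample(c("f", "nf"), 40, replace = TRUE),
                    tau_start = 0)
  led <- minutes_ledger(mix)
  for (d in -2:2) for (e in c("f", "nf")) {
    expect_equal(led[as.character(d), e],
                 5 * sum(mix$gd == d & mix$expectation == e))
  }
  expect_equal(rowSums(led), led[, "f"] + led[, "nf"], ignore_attr = TRUE)
})

test_that("influence matrix normalizes powers by the GD reference", {
  led <- minutes_ledger(data.frame(start_min = rep(seq(0, 95, 5), 2)[1:40],
                                   end_min = rep(seq(5, 100, 5), 2)[1:40],
                                   energy = 2500, playing_flag = TRUE,
                                   gd = rep(-2:2, each = 8),
                                   expectation = rep(c("f", "nf"), 20),
                                   tau_start = 0))
  # equal minutes (20/20) in every cell
  p_eq <- player_parameters(500, eta90 = 0.8)
  im <- influence_matrix(p_eq, led)
  expect_true(all(im$g == 1))
  expect_true(all(im$r == 500))

  P <- cbind(f = rep(600, 5), nf = rep(400, 5))
  im <- influence_matrix(player_parameters(P, 0.8), led)
  expect_equal(unname(im$r["0"]), 500)
  expect_equal(unname(im$g["0", "f"]), 1.2)
  expect_equal(unname(im$g["0", "nf"]), 0.8)
})

test_that("single-class GDs and empty ledgers are handled", {
  lab <- data.frame(start_min = c(0, 5), end_min = c(5, 10), energy = 2500,
                    playing_flag = TRUE, gd = 2L, expectation = "f",
                    tau_start = c(0, 5))
  led <- minutes_ledger(lab)
  p <- example_params()
  im <- influence_matrix(p, led)
  expect_equal(unname(im$r["2"]), unname(p$P["2", "f"]))
  expect_equal(unname(im$g["2", "f"]), 1)
  expect_true(is.na(im$g["2", "nf"]))
  expect_true(all(is.na(im$g[c("-2", "-1", "0", "1"), ])))

  empty_led <- minutes_ledger(NULL)
  expect_error(influence_matrix(p, empty_led), "zero minutes")
})

test_that("minutes-weighted influence averages to one and is scale-free", {
  set.seed(17)
  for (rep in 1:60) {
    P <- matrix(runif(10, 200, 800), 5, 2)
    led <- minutes_ledger(NULL)
    m <- matrix(round(runif(10, 0, 40)) * 5, 5, 2)
    led[, ] <- m
    if (all(rowSums(m) == 0)) next
    pars <- player_parameters(P, eta90 = runif(1, 0.5, 1))
    im <- influence_matrix(pars, led)
    for (d in which(rowSums(m) > 0)) {
      gs <- im$g[d, ]
      w <- m[d, ]
      expect_lt(abs(sum(w * gs, na.rm = TRUE) / sum(w) - 1), 1e-9)
    }
    # scaling all powers leaves g untouched
    pars2 <- pars
    pars2$P <- pars$P * 0.5
    im2 <- influence_matrix(pars2, led)
    expect_equal(im2$g, im$g)
  }
})

test_that("profile reports round-trip through JSON", {
  ds <- generate_dataset(recovery_config(1, noise_sd = 100, seed = 51,
                                         n_cycles = 1))
  games <- dataset_player_games(ds, "athlete01")
  pair <- run_player_fit(games, fit_config(seed = 3, n_restarts = 2,
                                           pso = list(max_iter = 120,
                                                      stagnation = 30)))
  labeled <- do.call(rbind, lapply(games, `[[`, "intervals"))
  ledger <- minutes_ledger(labeled)
  infl <- influence_matrix(pair$NM$parameters, ledger)
  rep <- profile_report("athlete01", pair, infl, ledger)

  # fully observed player: no masked influence cells
  expect_true(all(infl$defined))

  # report echoes its inputs
  expect_equal(unlist(rep$influence$g$f), infl$g[, "f"], ignore_attr = TRUE)
  expect_equal(rep$methods$NM$cost, pair$NM$cost)

  path <- tempfile(fileext = ".json")
  write_profile(rep, path)
  back <- read_profile(path)
  expect_equal(back$player_id, "athlete01")
  expect_equal(unlist(back$methods$NM$x_hat), pair$NM$x_hat,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$eta90, rep$eta90, tolerance = 1e-12)
  expect_equal(unlist(back$minutes$nf), unclass(ledger)[, "nf"],
               ignore_attr = TRUE)
})
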