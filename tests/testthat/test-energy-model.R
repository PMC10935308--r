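test_that("decay rate and efficiency follow the 90-minute definition", {
  expect_identical(alpha_from_eta90(1), 0)
  expect_equal(alpha_from_eta90(0.5), log(2) / 90)
  expect_equal(alpha_from_eta90(0.5), 0.0077016, tolerance = 1e-5)
  expect_equal(alpha_from_eta90(0.7), 0.0039631, tolerance = 1e-4)
  expect_error(alpha_from_eta90(0), "\\(0, 1\\]")
  expect_error(alpha_from_eta90(-0.2), "\\(0, 1\\]")
  expect_error(alpha_from_eta90(1.1), "\\(0, 1\\]")

  expect_equal(eta_decay(0, 0.5), 1)
  a <- alpha_from_eta90(0.7)
  expect_equal(eta_decay(90, a), 0.7, tolerance = 1e-12)
  expect_equal(eta_decay(45, a), sqrt(0.7), tolerance = 1e-12)
  expect_error(eta_decay(-1, a), "non-negative")
})

test_that("eta(90) returns eta90 for random coefficients", {
  set.seed(3)
  eta90 <- runif(100, 0.5, 1)
  back <- eta_decay(90, alpha_from_eta90(eta90))
  expect_true(all(abs(back - eta90) < 1e-12))
})

test_that("constant power without decay integrates exactly", {
  p <- player_parameters(600, eta90 = 1)
  tr <- simulate_energy(p, build_gd_timeline(NULL, 90),
                        list(t_s = 0, t_e = 90), "f")
  expect_equal(tail(tr$cumulative, 1), 600 * 90)
  # piecewise linear with slope P everywhere
  expect_equal(diff(tr$cumulative), rep(600, 90))
})

test_that("Euler trace matches the closed-form integral within 0.5%", {
  for (eta90 in c(0.5, 0.7, 0.9)) {
    a <- alpha_from_eta90(eta90)
    p <- player_parameters(600, eta90 = eta90)
    tr <- simulate_energy(p, build_gd_timeline(NULL, 90),
                          list(t_s = 0, t_e = 90), "f")
    analytic <- 600 * (1 - exp(-a * 90)) / a
    rel <- abs(tail(tr$cumulative, 1) - analytic) / analytic
    expect_lt(rel, 0.005)
    # halving the step shrinks the error
    tr2 <- simulate_energy(p, build_gd_timeline(NULL, 90),
                           list(t_s = 0, t_e = 90), "f", dt = 0.5)
    expect_lt(abs(tail(tr2$cumulative, 1) - analytic) / analytic, rel)
  }
})

test_that("GD switches change the accumulation slope at the goal minute", {
  P <- cbind(f = c(200, 200, 400, 700, 200), nf = rep(200, 5))
  p <- player_parameters(P, eta90 = 1)
  tl <- build_gd_timeline(data.frame(minute = 30, side = "for"), 90)
  tr <- simulate_energy(p, tl, list(t_s = 0, t_e = 90), "f")
  expect_equal(tail(tr$cumulative, 1), 400 * 30 + 700 * 60)   # 54000

  # brute-force minute-by-minute oracle over the whole trace
  brute <- cumsum(vapply(0:89, function(k) {
    d <- if (k >= 30) 1 else 0
    P[d + 3, "f"]
  }, 0))
  expect_equal(tr$cumulative[-1], brute)
})

test_that("trace is homogeneous in power and consistent across stints", {
  tl <- build_gd_timeline(data.frame(minute = c(25, 60), side = c("for", "against")), 90)
  p1 <- example_params(0.75)
  p2 <- player_parameters(p1$P, eta90 = 0.75, validate = FALSE)
  p2$P <- p1$P * 1.3
  tr1 <- simulate_energy(p1, tl, list(t_s = 0, t_e = 90), "nf")
  tr2 <- simulate_energy(p2, tl, list(t_s = 0, t_e = 90), "nf")
  expect_equal(tr2$cumulative, 1.3 * tr1$cumulative)

  # prefix property: a shorter stint from the same entry is a prefix
  tr_s <- simulate_energy(p1, tl, list(t_s = 0, t_e = 40), "nf")
  expect_equal(tr_s$cumulative, tr1$cumulative[1:41])

  # the decay clock starts at entry, not kickoff
  tr_sub <- simulate_energy(p1, tl, list(t_s = 45, t_e = 90), "nf")
  expect_equal(tr_sub$eta[1], 1)
})

test_that("a partial final Euler step covers fractional stints", {
  p <- player_parameters(600, eta90 = 1)
  tr <- simulate_energy(p, build_gd_timeline(NULL, 90),
                        list(t_s = 0, t_e = 7.5), "f")
  expect_equal(tail(tr$tau, 1), 7.5)
  expect_equal(tail(tr$cumulative, 1), 600 * 7.5)
})

test_that("interval energies difference the trace and telescope", {
  p <- player_parameters(600, eta90 = 1)
  tl <- build_gd_timeline(NULL, 90)
  stint <- list(t_s = 0, t_e = 90)
  tr <- simulate_energy(p, tl, stint, "f")
  iv <- data.frame(start_min = seq(0, 85, 5), end_min = seq(5, 90, 5))
  en <- interval_energies(tr, iv, stint)
  expect_equal(en[9], 3000)                       # [40,45) at 600/min
  expect_equal(sum(en), tail(tr$cumulative, 1))   # telescoping

  # with decay, successive equal-GD intervals strictly decrease
  pd <- player_parameters(600, eta90 = 0.7)
  trd <- simulate_energy(pd, tl, stint, "f")
  end <- interval_energies(trd, iv, stint)
  expect_true(all(diff(end) < 0))

  expect_error(interval_energies(tr, data.frame(start_min = 88, end_min = 93),
                                 stint), "stint")
})
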