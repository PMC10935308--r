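test_that("expectation ratio and categories follow the odds thresholds", {
  e <- compute_expectation(p_win = 0.5, p_lose = 0.25)
  expect_equal(e$ratio, 2)
  expect_identical(e$category, "favorite")   # boundary inclusive at 2
  expect_identical(e$model_class, "f")

  e <- compute_expectation(p_win = 0.3, p_lose = 0.3)
  expect_equal(e$ratio, 1)
  expect_identical(e$category, "close")
  expect_identical(e$model_class, "nf")

  e <- compute_expectation(p_win = 0.1, p_lose = 0.6)
  expect_equal(e$ratio, 1 / 6, tolerance = 1e-12)
  expect_identical(e$category, "underdog")
  expect_identical(e$model_class, "nf")

  # ratio exactly 0.5 is a close game (underdog boundary is exclusive)
  expect_identical(compute_expectation(0.2, 0.4)$category, "close")
})

test_that("degenerate odds are warned about or rejected", {
  expect_warning(e <- compute_expectation(p_win = 0.4, p_lose = 0),
                 "p_lose")
  expect_identical(e$category, "favorite")
  expect_true(is.infinite(e$ratio))
  expect_error(compute_expectation(0, 0), "both")
  expect_error(compute_expectation(1.2, 0.3), "\\[0, 1\\]")
})

test_that("GD timeline is a clipped right-open running sum of goals", {
  tl <- build_gd_timeline(NULL, 90)
  expect_equal(tl$breakpoints, 0)
  expect_equal(tl$values, 0L)
  expect_equal(gd_at(tl, c(0, 45, 89.9)), c(0L, 0L, 0L))

  ev <- data.frame(minute = c(10, 25, 70), side = c("for", "for", "against"))
  tl <- build_gd_timeline(ev, 90)
  expect_equal(tl$breakpoints, c(0, 10, 25, 70))
  expect_equal(tl$values, c(0L, 1L, 2L, 1L))
  # right-open: the new GD applies at the goal minute itself
  expect_equal(gd_at(tl, c(9.99, 10, 24.99, 25, 70)), c(0L, 1L, 1L, 2L, 1L))

  ev <- data.frame(minute = c(5, 15, 30), side = "for")
  tl <- build_gd_timeline(ev, 90)
  expect_equal(tl$values, c(0L, 1L, 2L, 2L))   # raw 3 clipped to 2
  expect_equal(tl$raw_values, c(0L, 1L, 2L, 3L))

  expect_error(build_gd_timeline(data.frame(minute = 95, side = "for"), 90),
               "duration")
})

test_that("timeline matches a brute-force running sum on random schedules", {
  set.seed(11)
  for (rep in 1:25) {
    n <- rpois(1, 4)
    ev <- data.frame(minute = runif(n, 0, 90),
                     side = sample(c("for", "against"), n, replace = TRUE))
    tl <- build_gd_timeline(ev, 90)
    ts <- runif(20, 0, 90)
    brute <- vapply(ts, function(t) {
      raw <- sum(ev$minute <= t & ev$side == "for") -
        sum(ev$minute <= t & ev$side == "against")
      max(min(raw, 2L), -2L)
    }, 0)
    expect_equal(as.numeric(gd_at(tl, ts)), brute)
  }
})

test_that("labeling keeps contained playing intervals and attaches GD", {
  tl <- build_gd_timeline(data.frame(minute = 42, side = "for"), 90)
  stint <- list(t_s = 0, t_e = 90)
  iv <- data.frame(start_min = c(0, 40, 55), end_min = c(5, 45, 60),
                   energy = c(100, 2500, 2600),
                   playing_flag = c(FALSE, TRUE, TRUE))
  lab <- label_intervals(iv, tl, stint, "f")
  expect_equal(nrow(lab), 2L)                 # flagged-off record dropped
  expect_equal(lab$gd, c(0L, 1L))             # GD at each record's start
  expect_equal(lab$gd[1], gd_at(tl, 40))      # goal at 42 is mid-record
  expect_equal(lab$tau_start, c(40, 55))
  expect_identical(unique(lab$expectation), "f")
})

test_that("labeling respects the half-open stint and overlap threshold", {
  tl <- build_gd_timeline(NULL, 90)
  iv <- data.frame(start_min = 55, end_min = 60, energy = 2000,
                   playing_flag = TRUE)
  # zero overlap with [60, 90) -> dropped
  expect_equal(nrow(label_intervals(iv, tl, list(t_s = 60, t_e = 90), "nf")), 0L)
  # full containment default drops partial overlap
  expect_equal(nrow(label_intervals(iv, tl, list(t_s = 58, t_e = 90), "nf")), 0L)
  # configurable minimum overlap keeps it
  expect_equal(nrow(label_intervals(iv, tl, list(t_s = 58, t_e = 90), "nf",
                                    min_overlap = 2)), 1L)
})

test_that("labeling invariants: minutes bound, later goals, idempotence", {
  set.seed(21)
  tl <- build_gd_timeline(data.frame(minute = c(20, 60), side = c("for", "against")), 90)
  stint <- list(t_s = 10, t_e = 75)
  iv <- data.frame(start_min = seq(0, 85, 5), end_min = seq(5, 90, 5),
                   energy = runif(18, 1500, 3500), playing_flag = TRUE)
  lab <- label_intervals(iv, tl, stint, "f")
  expect_true(all(lab$start_min >= stint$t_s & lab$end_min <= stint$t_e))
  expect_lte(sum(lab$end_min - lab$start_min), stint$t_e - stint$t_s)

  # adding a goal after an interval's end does not change its label
  tl2 <- build_gd_timeline(data.frame(minute = c(20, 60, 80),
                                      side = c("for", "against", "for")), 90)
  lab2 <- label_intervals(iv[iv$end_min <= 80, ], tl2, stint, "f")
  common <- lab$end_min <= 80
  expect_equal(lab$gd[common], lab2$gd)

  # relabeling the labeled output is a no-op
  again <- label_intervals(lab, tl, stint, "f")
  expect_equal(again$gd, lab$gd)
  expect_equal(again$energy, lab$energy)
  expect_equal(nrow(again), nrow(lab))
})
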