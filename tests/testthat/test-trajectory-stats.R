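test_that("percent GFP-positive groups OFF and DIM as negative", {
  expect_equal(pct_gfp_positive(0, 0, 100), 100)
  expect_equal(pct_gfp_positive(100, 0, 0), 0)
  expect_equal(pct_gfp_positive(50, 25, 25), 25)
  expect_error(pct_gfp_positive(0, 0, 0), "no scored individuals")
})

test_that("generation-to-day arithmetic handles arrests exactly", {
  plain <- generation_schedule()
  expect_equal(day_of_generation(plain, 4, "20C"), 14)
  expect_equal(day_of_generation(plain, 0, "20C"), 0)
  arrest <- generation_schedule(
    arrests = data.frame(generation = 1, extra_days = 6))
  expect_equal(day_of_generation(arrest, 2, "20C"), 13)
  expect_error(day_of_generation(plain, 1, "37C"), "unknown temperature.*37C")
  expect_error(day_of_generation(plain, -1, "20C"), ">= 0")

  # an arrest adds exactly its extra days to every generation at or after
  # its index and nothing before
  g <- 0:8
  diff_days <- day_of_generation(arrest, g, "20C") -
    day_of_generation(plain, g, "20C")
  expect_equal(diff_days, ifelse(g >= 1, 6, 0))
})

test_that("trajectories are built with G0 and increasing days", {
  tbl <- tiny_scoring_table(n_rep = 1, generations = 1:8)
  grp <- group_replicates(tbl)[["C/A/20C_OP50/1"]]
  traj <- build_trajectory(grp)
  expect_equal(nrow(traj), 9L)
  expect_equal(traj$pct_on,
               pct_gfp_positive(grp$n_off, grp$n_dim, grp$n_on))
  expect_true(all(diff(traj$day) > 0))
  expect_error(build_trajectory(tibble::as_tibble(tbl)),
               "more than one")
})

test_that("bracket selection follows the closest-pair and smoothing rules", {
  b <- select_bracket(c(10, 40, 80, 100))
  expect_equal(b[c("below", "above")], list(below = 2L, above = 3L))
  expect_false(b$smoothing_applied)

  osc <- select_bracket(c(10, 60, 40, 80, 95))
  expect_equal(osc[c("below", "above")], list(below = 3L, above = 4L))
  expect_true(osc$smoothing_applied)

  expect_equal(select_bracket(c(60, 80, 90))$signal, "left_anchored")
  expect_equal(select_bracket(c(10, 20, 30))$signal, "censored")
  expect_error(select_bracket(numeric(0)), "at least one point")
})

test_that("half-life interpolation matches hand calculations", {
  tr <- function(g, pct) tibble::tibble(generation = g, day = g * 3.5,
                                        pct_on = pct)
  est <- half_life(tr(1:2, c(20, 80)))
  expect_equal(est$value, 1.5)
  expect_equal(est$status, "interpolated")

  # a point exactly at the threshold is the above point
  expect_equal(half_life(tr(1:3, c(20, 50, 90)))$value, 2)

  # left anchoring against full silencing at G0
  left <- half_life(tr(1:3, c(80, 90, 100)))
  expect_equal(left$value, 0.625)
  expect_equal(left$status, "left_anchored")

  cens <- half_life(tr(1:3, c(10, 20, 40)))
  expect_equal(cens$status, "censored")
  expect_true(is.na(cens$value))

  expect_error(half_life(tr(integer(0), numeric(0))), "empty")
})

test_that("half-life is contained in, shifted with, and scaled by its axis", {
  set.seed(101)
  for (i in 1:200) {
    traj <- random_logistic_trajectory()
    est <- half_life(traj)
    if (est$status == "censored") next
    # containment
    expect_lt(est$bracket$coordinate[1], est$value)
    expect_lte(est$value, est$bracket$coordinate[2])
    # axis consistency: constant 3.5 d per generation, no arrests
    est_d <- half_life(traj, axis = "days")
    expect_equal(est_d$value, 3.5 * est$value)
    # shift equivariance on the generation axis (monotone case only:
    # shifting cannot change the bracket when the series is monotone)
    if (!is.unsorted(traj$pct_on) && est$status == "interpolated") {
      shifted <- traj
      shifted$generation <- shifted$generation + 3L
      expect_equal(half_life(shifted)$value, est$value + 3)
    }
  }
})

test_that("pointwise-larger monotone trajectories never lengthen the half-life", {
  set.seed(202)
  for (i in 1:200) {
    traj <- random_logistic_trajectory()
    traj$pct_on <- cummax(traj$pct_on)  # monotone desilencing series
    bumped <- traj
    # non-decreasing bump keeps the series monotone and pointwise larger
    bump <- cumsum(100 * rbinom(nrow(traj), 5, 0.3) / 100)
    bumped$pct_on <- pmin(traj$pct_on + bump, 100)
    v1 <- half_life(traj)$value
    v2 <- half_life(bumped)$value
    if (is.na(v2)) expect_true(is.na(v1))
    if (!is.na(v1) && !is.na(v2)) expect_lte(v2, v1 + 1e-12)
  }
})

test_that("trajectory summaries average replicates pointwise", {
  trajs <- lapply(c(20, 30, 40), function(v) {
    tibble::tibble(generation = 1, day = 3.5, pct_on = v)
  })
  s <- summarize_trajectories(trajs)
  expect_equal(s$mean_pct, 30)
  expect_equal(s$sd_pct, 10)
  expect_equal(summarize_trajectories(trajs[1])$sd_pct, 0)
  misaligned <- list(
    tibble::tibble(generation = 1:2, day = c(3.5, 7), pct_on = c(1, 2)),
    tibble::tibble(generation = 1:3, day = c(3.5, 7, 10.5),
                   pct_on = c(1, 2, 3)))
  expect_error(summarize_trajectories(misaligned), "different generation")

  # replicate means track the generating curve
  design <- simulation_design(strain_halflives = c(N2 = 3),
                              sd_block = 0, sd_replicate = 0,
                              n_blocks = 1, n_replicates = 3,
                              n_scored = 400L, seed = 31)
  tbl <- simulate_experiment(design)
  s2 <- trajectory_summary(tbl)
  p <- c(0, expected_on_probability(1:8, 3, 1.5))
  se <- 100 * sqrt(p * (1 - p) / (3 * 400))
  expect_true(all(abs(s2$mean_pct - 100 * p) <= pmax(3 * se, 1e-9)))
})

test_that("half-life tables carry provenance for every series", {
  tbl <- tiny_scoring_table()
  hl <- half_life_table(tbl)
  expect_equal(nrow(hl), 4L)
  expect_named(hl, c("block", "strain", "environment", "replicate", "axis",
                     "value", "status", "g_below", "g_above", "smoothing"))
  expect_true(all(hl$status != "censored"))
  expect_true(all(hl$value > hl$g_below | hl$status == "left_anchored"))
  expect_error(
    half_life_table(tbl, environments = list(environment_scenario("25C"))),
    "no environment scenario.*20C_OP50")

  # day-axis values scale with the base generation time
  hl_d <- half_life_table(tbl, axis = "days")
  expect_equal(hl_d$value, 3.5 * hl$value)
})
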