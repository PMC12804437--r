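test_that("collection schedule bins steps into days or hours", {
  expect_equal(collection_schedule(3), 1:3)
  # daily, S = 12: step 12 ends day 1, step 13 opens day 2
  expect_equal(ceiling(12 / 12), 1)
  expect_equal(ceiling(13 / 12), 2)
  # hourly: step 6 is half a day; S * n_days bins in total
  h <- collection_schedule(2, "hourly", S = 12)
  expect_length(h, 24)
  expect_equal(h[6], 0.5)
  expect_error(collection_schedule(0), "at least 1")
})

test_that("free walkers obey the uncorrelated-walk mean square displacement", {
  w <- walk_config(k = 35, n_days = 6, N = 10000, reps = 1, seed = 42)
  sim <- simulate_recapture(free_layout(), w, track_msd = TRUE,
                            return_positions = TRUE)
  expect_equal(sum(sim$counts), 0)

  # after m steps, MSD = m (k h)^2; compare at the final step using the
  # empirical standard error of r^2
  m <- w$S * w$n_days
  r2 <- sim$positions[, "x"]^2 + sim$positions[, "y"]^2
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - m * (35 * 0.1)^2), 3 * se)

  # MSD grows linearly: slope of msd against step count is (k h)^2
  steps <- seq_len(m)
  slope <- coef(lm(sim$msd[, 1] ~ 0 + steps))[[1]]
  expect_equal(slope, (35 * 0.1)^2, tolerance = 0.05)
})

test_that("free-walker zone occupancy matches the diffusion annulus law", {
  w <- walk_config(k = 35, n_days = 6, N = 10000, reps = 1, seed = 9)
  sim <- simulate_recapture(free_layout(), w, return_positions = TRUE)
  D <- k_to_D(35)
  r <- sqrt(sim$positions[, "x"]^2 + sim$positions[, "y"]^2)
  zb <- seq(0, 90, by = 15)
  for (j in 1:6) {
    p_th <- annulus_prob(zb[j], zb[j + 1], D, 6)
    p_emp <- mean(r > zb[j] & r <= zb[j + 1])
    se <- sqrt(p_th * (1 - p_th) / length(r))
    expect_lt(abs(p_emp - p_th), 3 * se + 1e-12)
  }
})

test_that("capture accounting is conserved and seeded runs are identical", {
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 2,
                                                     s_e = 0.05), seed = 3)
  w <- walk_config(k = 35, n_days = 4, N = 3000, reps = 3, seed = 11)
  sim <- simulate_recapture(ml$layout, w)
  expect_true(all(sim$captured + sim$exited + sim$free == w$N))
  expect_equal(sum(sim$counts), sum(sim$captured))
  expect_gt(sum(sim$captured), 0)

  sim2 <- simulate_recapture(ml$layout, w)
  expect_identical(sim$captures, sim2$captures)
  expect_identical(sim$tau, sim2$tau)

  w3 <- walk_config(k = 35, n_days = 4, N = 3000, reps = 3, seed = 12)
  sim3 <- simulate_recapture(ml$layout, w3)
  expect_false(identical(sim$captures, sim3$captures))

  # averaged ratios are normalized over captured walkers only
  expect_equal(sum(sim$tau), 1, tolerance = 1e-12)
  expect_equal(sum(sim$sigma), 1, tolerance = 1e-12)
})

test_that("a perfectly efficient collection disk absorbs walkers on contact", {
  # one big site covering the neighbourhood of the release point, s_e = 1,
  # p = 0: every walker is captured as soon as it steps within q h
  zb <- seq(0, 90, by = 15)
  sites <- data.frame(x = 10, y = 0, q = 60, p = 0, s_e = 1)
  lay <- study_layout(c(0, 0), zb, sites)
  w <- walk_config(k = 35, n_days = 4, N = 2000, reps = 1, seed = 5)
  sim <- simulate_recapture(lay, w, return_positions = TRUE)
  expect_gt(sum(sim$counts) / w$N, 0.4)
  # all captures credited to the site's zone (zone 1: center at 10 m)
  expect_equal(sum(sim$counts[, 1]), sum(sim$counts))
  # absorption is checked at every step start, so a surviving walker can
  # be inside the disk only by having entered on the very last step: its
  # distance to the center is at least q h - k h
  d <- sqrt((sim$positions[, "x"] - 10)^2 + sim$positions[, "y"]^2)
  expect_gte(min(d), (60 - 35) * 0.1)
})

test_that("simulated ratios are stable in the number of walkers released", {
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 0,
                                                     s_e = 0.03), seed = 21)
  sims <- lapply(c(1000, 100000), function(N) {
    w <- walk_config(k = 35, n_days = 6, N = N, reps = 4, seed = 77)
    simulate_recapture(ml$layout, w)
  })
  # multinomial pooled standard error from the captured totals
  c1 <- sum(sims[[1]]$captured)
  c2 <- sum(sims[[2]]$captured)
  for (ratio in c("tau", "sigma")) {
    a <- sims[[1]][[ratio]]
    b <- sims[[2]][[ratio]]
    p <- (a + b) / 2
    se <- sqrt(p * (1 - p) * (1 / c1 + 1 / c2))
    expect_true(all(abs(a - b) <= 3 * se + 1e-9))
  }
})

test_that("non-consecutive collection days accumulate the intervening bins", {
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 0,
                                                     s_e = 0.1), seed = 8)
  w <- walk_config(k = 35, n_days = 6, N = 2000, reps = 2, seed = 13)
  daily <- simulate_recapture(ml$layout, w)
  coll <- simulate_recapture(ml$layout, w, collect_days = c(2, 5, 6))
  expect_equal(dim(coll$counts), c(3, 6))
  expect_equal(coll$counts[1, ], daily$counts[1, ] + daily$counts[2, ])
  expect_equal(coll$counts[2, ],
               daily$counts[3, ] + daily$counts[4, ] + daily$counts[5, ])
  expect_equal(coll$counts[3, ], daily$counts[6, ])
  expect_error(simulate_recapture(ml$layout, w, collect_days = c(2, 9)),
               "horizon")
})

test_that("hourly granularity yields one bin per step", {
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 0,
                                                     s_e = 0.1), seed = 8)
  w <- walk_config(k = 35, n_days = 2, N = 1000, reps = 1, seed = 3)
  sim <- simulate_recapture(ml$layout, w, granularity = "hourly")
  expect_equal(nrow(sim$counts), 24)
  expect_equal(sim$times, (1:24) / 12)
  # aggregating hourly bins by day reproduces the daily run
  simd <- simulate_recapture(ml$layout, w)
  agg <- rowsum(sim$counts, rep(1:2, each = 12))
  dimnames(agg) <- NULL
  expect_equal(agg, simd$counts)
})
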