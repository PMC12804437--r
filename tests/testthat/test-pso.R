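test_that("the ratio discrepancy E behaves like half a sum of Euclidean norms", {
  obs <- ratio_set(c(0.5, 0.5), c(0.2, 0.3, 0.5))
  expect_equal(error_E(obs, obs), 0)

  # sigma off by (0.3, -0.4, 0), tau identical: E = 0.5 * 0.5
  sim <- list(tau = c(0.5, 0.5), sigma = c(0.5, -0.1, 0.5) + c(0, 0.0, 0))
  sim$sigma <- obs$spatial + c(0.3, -0.4, 0)
  expect_equal(error_E(sim, obs), 0.25)

  # symmetry
  sim2 <- ratio_set(c(0.6, 0.4), c(0.3, 0.3, 0.4))
  expect_equal(error_E(sim2, obs), error_E(obs, sim2))

  expect_error(error_E(list(tau = c(1), sigma = c(1, 0, 0)), obs),
               "share day and zone grids")
})

test_that("k and D convert through the fixed-step walk relation", {
  expect_equal(k_to_D(35), 36.75)
  expect_equal(round(k_to_D(36.87), 2), 40.78)
  expect_equal(round(k_to_D(71.99), 2), 155.48)
  expect_equal(round(k_to_D(120.67), 2), 436.84)
  expect_equal(k_to_D(0), 0)
  # exact inverse pair
  for (k in c(0.3, 12, 35, 120.67))
    expect_equal(D_to_k(k_to_D(k)), k, tolerance = 1e-12)
  # other step counts and mesh sizes
  expect_equal(k_to_D(10, h = 0.5, S = 24), 24 / 4 * 25)
  expect_error(k_to_D(-1), "non-negative")
})

test_that("pso configuration validates bounds", {
  expect_s3_class(pso_config(), "pso_config")
  expect_error(pso_config(n_particles = 1), "at least 2")
  expect_error(pso_config(bounds = list(k = c(5, 1), q = c(1, 2),
                                        p = c(0, 1), s_e = c(0.1, 1))),
               "non-degenerate")
  expect_error(pso_config(bounds = list(k = c(1, 5), q = c(1, 2),
                                        p = c(0, 1), s_e = c(0, 1))),
               "s_e")
})

test_that("grid search maps the error surface and brackets the minimum", {
  set.seed(1)
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 0,
                                                     s_e = 0.05), seed = 31)
  w <- walk_config(k = 30, n_days = 3, N = 2000, reps = 2, seed = 55)
  obs <- sim_ratios(simulate_recapture(ml$layout, w))
  cfg <- pso_config(sim_N = 800, sim_reps = 1)
  g <- grid_search(obs, ml$layout, walk_config(k = 1, n_days = 3),
                   k_range = c(10, 50), q_range = c(5, 20),
                   resolution = 5, config = cfg, seed = 2)
  expect_equal(dim(g$E), c(5, 5))
  expect_true(all(is.finite(g$E) | is.nan(g$E)))
  expect_equal(g$min_E, min(g$E, na.rm = TRUE))
  # init box is the argmin cell +/- one cell, clipped to the range
  expect_true(g$init_box$k[1] <= g$argmin["k"] &&
                g$argmin["k"] <= g$init_box$k[2])
  expect_gte(g$init_box$q[1], 5)
  expect_lte(g$init_box$q[2], 20)

  # single-cell grid returns that cell
  g1 <- grid_search(obs, ml$layout, walk_config(k = 1, n_days = 3),
                    k_range = c(30, 30), q_range = c(10, 10),
                    resolution = 1, config = cfg, seed = 3)
  expect_equal(unname(g1$argmin), c(30, 10))

  # deterministic under a fixed seed
  g2 <- grid_search(obs, ml$layout, walk_config(k = 1, n_days = 3),
                    k_range = c(10, 50), q_range = c(5, 20),
                    resolution = 5, config = cfg, seed = 2)
  expect_identical(g$E, g2$E)
})

test_that("a degenerate swarm at the optimum does not move", {
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 0,
                                                     s_e = 0.05), seed = 31)
  w <- walk_config(k = 30, n_days = 2, N = 1500, reps = 2, seed = 55)
  obs <- sim_ratios(simulate_recapture(ml$layout, w))
  cfg <- pso_config(n_particles = 4, n_generations = 3,
                    sim_N = 500, sim_reps = 1,
                    fixed = list(p = 0, s_e = 0.05))
  box <- list(k = c(30, 30), q = c(10, 10), p = c(0, 0),
              s_e = c(0.05, 0.05))
  res <- pso_optimize(obs, ml$layout, walk_config(k = 1, n_days = 2),
                      cfg, init_box = box, seed = 4)
  expect_equal(unname(res$par[c("k", "q")]), c(30, 10))
  # gbest error is a running minimum: never increases over generations
  expect_true(all(diff(res$history) <= 0))
})

test_that("PSO refines the grid-search minimum on synthetic data", {
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 0,
                                                     s_e = 0.05), seed = 31)
  w <- walk_config(k = 30, n_days = 3, N = 3000, reps = 2, seed = 56)
  obs <- sim_ratios(simulate_recapture(ml$layout, w))
  walk <- walk_config(k = 1, n_days = 3)
  cfg <- pso_config(n_particles = 10, n_generations = 4,
                    bounds = list(k = c(10, 50), q = c(5, 20), p = c(0, 10),
                                  s_e = c(0.001, 1)),
                    sim_N = 800, sim_reps = 1)
  g <- grid_search(obs, ml$layout, walk, c(10, 50), c(5, 20),
                   resolution = 4, config = cfg, seed = 6)
  res <- pso_optimize(obs, ml$layout, walk, cfg, grid = g, seed = 7)
  expect_lte(res$E, g$min_E)
  expect_true(all(diff(res$history) <= 0))
  # returned parameters respect the bounds
  expect_true(res$par[["k"]] >= 10 && res$par[["k"]] <= 50)
  expect_true(res$par[["s_e"]] >= 0.001 && res$par[["s_e"]] <= 1)
})

test_that("replicated runs filter outliers and summarize k as a normal sample", {
  ml <- make_layout(seq(0, 90, by = 15), trap = list(q = 10, p = 0,
                                                     s_e = 0.05), seed = 31)
  w <- walk_config(k = 30, n_days = 3, N = 3000, reps = 2, seed = 57)
  obs <- sim_ratios(simulate_recapture(ml$layout, w))
  walk <- walk_config(k = 1, n_days = 3)
  cfg <- pso_config(n_particles = 6, n_generations = 2,
                    bounds = list(k = c(10, 50), q = c(5, 20), p = c(0, 10),
                                  s_e = c(0.001, 1)),
                    sim_N = 500, sim_reps = 1)
  res <- run_replicates(obs, ml$layout, walk, c(10, 50), c(5, 20),
                        config = cfg, resolution = 3, n_runs = 4,
                        outlier_rule = "mean+0.5sd", seed = 12)
  expect_equal(nrow(res$runs), 4)
  expect_true(all(res$runs$E >= 0))
  # the filter keeps exactly the runs at or below the threshold
  expect_equal(res$kept, res$runs$E <= res$threshold)
  expect_true(any(res$kept))
  expect_equal(res$D, k_to_D(res$k_mean))
  expect_true(res$D_ci[1] <= res$D && res$D <= res$D_ci[2])
  expect_error(run_replicates(obs, ml$layout, walk, c(10, 50), c(5, 20),
                              config = cfg, n_runs = 1), "at least 2")
})
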