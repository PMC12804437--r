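#' Discrepancy between simulated and observed recapture ratios
#'
#' `E = (||sigma - sigma_obs||_2 + ||tau - tau_obs||_2) / 2`: the average
#' of the Euclidean distances between the spatial and the temporal ratio
#' vectors.  Zero exactly when both ratio sets coincide; symmetric in its
#' arguments.
#'
#' @param sim a `ratio_set` or `sim_output` with the simulated ratios.
#' @param obs a `ratio_set` with the observed ratios.
#' @return non-negative scalar (`NaN` when the simulation captured
#'   nothing).
#' @export
error_E <- function(sim, obs) {
  st <- sim$tau %||% sim$temporal
  ss <- sim$sigma %||% sim$spatial
  ot <- obs$temporal %||% obs$tau
  os <- obs$spatial %||% obs$sigma
  if (length(st) != length(ot) || length(ss) != length(os))
    stop("simulated and observed ratios must share day and zone grids")
  (sqrt(sum((ss - os)^2)) + sqrt(sum((st - ot)^2))) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert between the walk step multiplier k and the diffusion coefficient
#'
#' For an uncorrelated fixed-step walk with `S` steps per day of length
#' `k * h`, the mean square displacement after one day is `S * (k h)^2`,
#' so `D = (S / 4) * (k * h)^2`.  `D_to_k()` is the exact inverse.
#'
#' @param k step-length multiplier (non-negative).
#' @param D diffusion coefficient, m^2/day (non-negative).
#' @param h reference mesh length, meters (default 0.1).
#' @param S steps per day (default 12).
#' @return `k_to_D()` returns m^2/day; `D_to_k()` returns the multiplier.
#' @examples
#' k_to_D(35)           # 36.75
#' D_to_k(k_to_D(35))   # 35
#' @export
k_to_D <- function(k, h = 0.1, S = 12) {
  if (any(k < 0)) stop("`k` must be non-negative")
  (S / 4) * (k * h)^2
}

#' @rdname k_to_D
#' @export
D_to_k <- function(D, h = 0.1, S = 12) {
  if (any(D < 0)) stop("`D` must be non-negative")
  sqrt(4 * D / S) / h
}

#' Configuration of the particle swarm optimizer
#'
#' Defaults follow the constriction coefficient set (`w = 0.729`,
#' `c1 = c2 = 1.49445`); velocities are clamped to `v_clamp` times each
#' bound range, and out-of-bound positions are clipped with the offending
#' velocity component zeroed.
#'
#' @param n_particles swarm size (default 36).
#' @param n_generations number of position updates of the whole swarm
#'   (default 12).
#' @param bounds named list of length-2 ranges for `k`, `q`, `p`
#'   (units of `h`) and `s_e` (within `[0.001, 1]`).
#' @param w,c1,c2 inertia, cognitive and social coefficients.
#' @param v_clamp velocity clamp as a fraction of each bound range.
#' @param fixed named list of parameters held constant (e.g.
#'   `list(p = 0, s_e = 1)`).
#' @param sim_N,sim_reps walker count and replicate count used for forward
#'   simulations inside the optimization; smaller values trade sampling
#'   noise for speed.
#' @return an object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 36, n_generations = 12,
                       bounds = list(k = c(5, 150), q = c(1, 40),
                                     p = c(0, 15), s_e = c(0.001, 1)),
                       w = 0.729, c1 = 1.49445, c2 = 1.49445,
                       v_clamp = 0.2, fixed = list(),
                       sim_N = 10000, sim_reps = 5) {
  if (n_particles < 2 || n_generations < 1)
    stop("need at least 2 particles and 1 generation")
  for (nm in c("k", "q", "p", "s_e"))
    if (is.null(bounds[[nm]]) || diff(bounds[[nm]]) < 0)
      stop("`bounds` must contain a non-degenerate range for ", nm)
  if (bounds$s_e[1] <= 0 || bounds$s_e[2] > 1)
    stop("`s_e` bounds must lie in (0, 1]")
  structure(list(n_particles = n_particles, n_generations = n_generations,
                 bounds = bounds, w = w, c1 = c1, c2 = c2,
                 v_clamp = v_clamp, fixed = fixed,
                 sim_N = sim_N, sim_reps = sim_reps),
            class = "pso_config")
}

# largest feasible trap radii for a layout: interaction disks must stay
# pairwise disjoint and collection disks must not swallow the release point
layout_feasibility <- function(layout) {
  s <- layout$sites
  if (nrow(s) == 0) return(list(qp_max = Inf, q_max = Inf))
  dr <- sqrt((s$x - layout$release[1])^2 + (s$y - layout$release[2])^2)
  qp_max <- if (nrow(s) > 1) min(stats::dist(cbind(s$x, s$y))) / (2 * layout$h)
            else Inf
  list(qp_max = qp_max,
       q_max = min(qp_max, min(dr) / layout$h * (1 - 1e-9)))
}

# project (q, p) onto the feasible set, following the convention that the
# attraction width ranges up to the maximum size at which traps do not
# overlap
project_feasible <- function(par, feas) {
  par[["q"]] <- min(par[["q"]], feas$q_max)
  par[["p"]] <- min(par[["p"]], max(0, feas$qp_max - par[["q"]]))
  par
}

# forward-model objective on the observed day grid
make_objective <- function(obs, layout, walk, config, next_seed) {
  feas <- layout_feasibility(layout)
  obs_days <- obs$days %||% seq_along(obs$temporal)
  n_days <- as.integer(ceiling(max(obs_days)))
  daily <- isTRUE(all.equal(obs_days, seq_len(n_days)))
  function(par) {
    par <- project_feasible(par, feas)
    w <- walk_config(k = par[["k"]], n_days = n_days, S = walk$S,
                     N = config$sim_N, reps = config$sim_reps,
                     seed = next_seed())
    sim <- simulate_recapture(layout, w,
                              site_params = list(q = par[["q"]],
                                                 p = par[["p"]],
                                                 s_e = par[["s_e"]]),
                              collect_days = if (daily) NULL else obs_days)
    error_E(sim, obs)
  }
}

#' Grid search over the (k, q) error landscape
#'
#' Maps the error `E` on a uniform grid over step multiplier `k` and
#' collection radius `q`, with the attraction width fixed at `p = 0` and
#' efficiency at `s_e = 1`, to obtain an overall description of the error
#' landscape and a refined initialization box (the argmin cell plus one
#' cell in each direction, clipped to the ranges) for the swarm.
#'
#' @param obs observed `ratio_set`.
#' @param layout a [study_layout()].
#' @param walk a [walk_config()] supplying `S` (its `k` is ignored).
#' @param k_range,q_range numeric length-2 search ranges (`q` in units of
#'   `h`).
#' @param resolution grid points per axis (default 8), scalar or length 2.
#' @param config a [pso_config()] (for `sim_N`, `sim_reps`).
#' @param seed integer seed for the forward-simulation streams.
#' @return an object of class `rda_grid`: `k_values`, `q_values`, `E`
#'   (matrix `k` x `q`), `argmin` (named vector), `min_E`, `init_box`.
#' @export
grid_search <- function(obs, layout, walk, k_range, q_range,
                        resolution = 8, config = pso_config(), seed = 1) {
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  if (diff(k_range) < 0 || diff(q_range) < 0) stop("empty search range")
  kv <- if (resolution[1] == 1) mean(k_range)
        else seq(k_range[1], k_range[2], length.out = resolution[1])
  qv <- if (resolution[2] == 1) mean(q_range)
        else seq(q_range[1], q_range[2], length.out = resolution[2])
  seeds <- derive_seeds(seed, length(kv) * length(qv))
  i <- 0
  nxt <- function() { i <<- i + 1; seeds[i] }
  obj <- make_objective(obs, layout, walk, config, nxt)
  E <- matrix(NA_real_, length(kv), length(qv),
              dimnames = list(k = signif(kv, 6), q = signif(qv, 6)))
  for (a in seq_along(kv)) for (b in seq_along(qv))
    E[a, b] <- obj(c(k = kv[a], q = qv[b], p = 0, s_e = 1))
  wmin <- which(E == min(E, na.rm = TRUE), arr.ind = TRUE)[1, ]
  box <- list(
    k = c(kv[max(1, wmin[1] - 1)], kv[min(length(kv), wmin[1] + 1)]),
    q = c(qv[max(1, wmin[2] - 1)], qv[min(length(qv), wmin[2] + 1)]))
  structure(list(k_values = kv, q_values = qv, E = E,
                 argmin = c(k = kv[wmin[1]], q = qv[wmin[2]]),
                 min_E = min(E, na.rm = TRUE), init_box = box, seed = seed),
            class = "rda_grid")
}

#' @export
print.rda_grid <- function(x, ...) {
  cat(sprintf("RDA grid search %dx%d: min E = %.4g at k = %.4g, q = %.4g\n",
              length(x$k_values), length(x$q_values), x$min_E,
              x$argmin["k"], x$argmin["q"]))
  invisible(x)
}

#' Particle swarm optimization of the forward model
#'
#' Standard global-best PSO over the `(k, q, p, s_e)` parameter space.
#' Velocities update as `v <- w v + c1 U1 (pbest - x) + c2 U2 (gbest - x)`
#' with per-dimension uniform draws; positions are clipped to the bounds
#' (zeroing the clipped velocity component) and velocities clamped.  The
#' objective is the discrepancy [error_E()] of the replicate-averaged
#' forward simulation; `NaN` objectives (no captures) cause the particle
#' to be re-sampled uniformly inside the bounds.  The swarm is initialized
#' uniformly in `init_box` (falling back to the bounds for parameters the
#' box omits); when a grid search is supplied, its box is used and one
#' particle is seeded at the grid argmin with `p = 0`, `s_e = 1`, so the
#' swarm refines the grid minimum.  The global best error is a running
#' minimum and never increases across generations.
#'
#' @inheritParams grid_search
#' @param config a [pso_config()].
#' @param init_box named list of length-2 ranges to initialize particles
#'   in; ignored when `grid` is given.
#' @param grid an `rda_grid` from [grid_search()].
#' @param seed integer master seed (swarm randomness and simulation
#'   streams).
#' @return an object of class `rda_pso`: `par` (named vector `k, q, p,
#'   s_e`), `E`, `D` (from [k_to_D()]), `history` (gbest error per
#'   generation, starting at initialization), `n_evals`.
#' @export
pso_optimize <- function(obs, layout, walk, config = pso_config(),
                         init_box = NULL, grid = NULL, seed = 1) {
  par_names <- c("k", "q", "p", "s_e")
  bounds <- config$bounds
  if (!is.null(grid)) init_box <- grid$init_box
  init_box <- modifyList(bounds, init_box %||% list())
  for (nm in par_names) {
    init_box[[nm]][1] <- max(init_box[[nm]][1], bounds[[nm]][1])
    init_box[[nm]][2] <- min(init_box[[nm]][2], bounds[[nm]][2])
  }
  np <- config$n_particles
  seeds <- derive_seeds(seed, 2)
  sim_seeds_needed <- np * (config$n_generations + 2L) * 2L
  sim_seeds <- derive_seeds(seeds[1], sim_seeds_needed)
  si <- 0
  nxt <- function() { si <<- si + 1; sim_seeds[si] }
  obj <- make_objective(obs, layout, walk, config, nxt)
  lb <- vapply(bounds, `[`, numeric(1), 1)[par_names]
  ub <- vapply(bounds, `[`, numeric(1), 2)[par_names]
  fixed <- config$fixed
  feas <- layout_feasibility(layout)
  apply_fixed <- function(x) {
    for (nm in names(fixed)) x[nm] <- fixed[[nm]]
    project_feasible(x, feas)
  }
  vmax <- config$v_clamp * (ub - lb)

  set.seed(seeds[2])
  X <- t(vapply(seq_len(np), function(i)
    vapply(par_names, function(nm) runif(1, init_box[[nm]][1],
                                         init_box[[nm]][2]), numeric(1)),
    numeric(4)))
  colnames(X) <- par_names
  if (!is.null(grid))
    X[1, ] <- c(grid$argmin["k"], grid$argmin["q"], 0, 1)
  X <- t(apply(X, 1, apply_fixed))
  V <- matrix(0, np, 4, dimnames = list(NULL, par_names))
  n_evals <- 0L
  evaluate <- function(x) {
    n_evals <<- n_evals + 1L
    e <- obj(x)
    if (is.nan(e)) {          # no captures: re-sample inside the bounds
      x <- runif(4, lb, ub)
      names(x) <- par_names
      x <- apply_fixed(x)
      n_evals <<- n_evals + 1L
      e <- obj(x)
      if (is.nan(e)) e <- Inf
    }
    list(x = x, e = e)
  }

  Ep <- numeric(np)
  for (i in seq_len(np)) {
    r <- evaluate(X[i, ])
    X[i, ] <- r$x
    Ep[i] <- r$e
  }
  P <- X
  g <- which.min(Ep)
  gbest <- X[g, ]
  gbest_E <- Ep[g]
  history <- gbest_E

  for (gen in seq_len(config$n_generations)) {
    for (i in seq_len(np)) {
      U1 <- runif(4); U2 <- runif(4)
      V[i, ] <- config$w * V[i, ] + config$c1 * U1 * (P[i, ] - X[i, ]) +
        config$c2 * U2 * (gbest - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
      x <- X[i, ] + V[i, ]
      low <- x < lb; high <- x > ub
      x[low] <- lb[low]; x[high] <- ub[high]
      V[i, low | high] <- 0
      x <- apply_fixed(x)
      r <- evaluate(x)
      X[i, ] <- r$x
      if (r$e < Ep[i]) { Ep[i] <- r$e; P[i, ] <- r$x }
      if (r$e < gbest_E) { gbest_E <- r$e; gbest <- r$x }
    }
    history <- c(history, gbest_E)
  }
  structure(list(par = gbest, E = gbest_E,
                 D = k_to_D(gbest[["k"]], layout$h, walk$S),
                 history = history, n_evals = n_evals, seed = seed),
            class = "rda_pso")
}

#' @export
print.rda_pso <- function(x, ...) {
  cat(sprintf(paste0("RDA-PSO optimum: k = %.4g, q = %.4g, p = %.4g, ",
                     "s_e = %.4g  (E = %.4g)\n"),
              x$par[["k"]], x$par[["q"]], x$par[["p"]], x$par[["s_e"]], x$E))
  cat(sprintf("Implied D = %.4g m^2/day\n", x$D))
  invisible(x)
}

#' Replicated RDA-PSO estimation with outlier filtering
#'
#' Repeats the full inverse pipeline (grid search then PSO) `n_runs` times
#' with distinct seeds, removes runs whose error exceeds the outlier
#' threshold (mean plus one, or one half, standard deviation of the run
#' errors), and summarizes the surviving step multipliers: their mean and
#' standard deviation, a Shapiro-Wilk normality p-value, the implied
#' diffusion coefficient `D = (S/4) (k_mean h)^2`, and a confidence
#' interval for `D` obtained by transforming the normal-theory interval
#' for the mean of `k` through the (monotone) conversion.
#'
#' @inheritParams grid_search
#' @param n_runs number of independent runs (at least 2).
#' @param outlier_rule `"mean+1.0sd"` or `"mean+0.5sd"`.
#' @param conf confidence level for the interval on `D`.
#' @param seed integer master seed; split deterministically across runs.
#' @return an object of class `rda_result`: `runs` (data frame of
#'   per-run `k, q, p, s_e, E`), `kept` (logical filter), `k_mean`,
#'   `k_sd`, `shapiro_p`, `D`, `D_ci`, `outlier_rule`, `threshold`.
#' @export
run_replicates <- function(obs, layout, walk, k_range, q_range,
                           config = pso_config(), resolution = 8,
                           n_runs = 10,
                           outlier_rule = c("mean+1.0sd", "mean+0.5sd"),
                           conf = 0.95, seed = 1) {
  outlier_rule <- match.arg(outlier_rule)
  if (n_runs < 2) stop("`n_runs` must be at least 2")
  run_seeds <- derive_seeds(seed, 2 * n_runs)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    g <- grid_search(obs, layout, walk, k_range, q_range, resolution,
                     config, seed = run_seeds[2 * r - 1])
    p <- pso_optimize(obs, layout, walk, config, grid = g,
                      seed = run_seeds[2 * r])
    runs[[r]] <- c(p$par, E = p$E)
  }
  runs <- as.data.frame(do.call(rbind, runs))
  mult <- if (outlier_rule == "mean+1.0sd") 1 else 0.5
  thr <- mean(runs$E) + mult * sd(runs$E)
  kept <- runs$E <= thr | !is.finite(thr)
  if (!any(kept)) stop("all runs flagged as outliers")
  k <- runs$k[kept]
  k_mean <- mean(k)
  k_sd <- sd(k)
  shapiro_p <- if (length(unique(k)) >= 3) shapiro.test(k)$p.value else NA_real_
  z <- qnorm(1 - (1 - conf) / 2)
  k_ci <- k_mean + c(-1, 1) * z * k_sd / sqrt(length(k))
  structure(list(runs = runs, kept = kept, k_mean = k_mean, k_sd = k_sd,
                 shapiro_p = shapiro_p,
                 D = k_to_D(k_mean, layout$h, walk$S),
                 D_ci = k_to_D(pmax(k_ci, 0), layout$h, walk$S),
                 outlier_rule = outlier_rule, threshold = thr,
                 conf = conf, seed = seed),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA-PSO estimate from %d runs (%d kept, rule %s):\n",
              nrow(x$runs), sum(x$kept), x$outlier_rule))
  cat(sprintf("  k = %.4g +/- %.4g (Shapiro-Wilk p = %.3g)\n",
              x$k_mean, x$k_sd, x$shapiro_p))
  cat(sprintf("  D = %.4g m^2/day, %g%% CI [%.4g, %.4g]\n",
              x$D, 100 * x$conf, x$D_ci[1], x$D_ci[2]))
  invisible(x)
}
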