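#' Collection schedule of the forward model
#'
#' Times (in days) at which simulated captures are binned.  With daily
#' granularity a capture at step `m` is credited to day `ceiling(m / S)`;
#' with hourly granularity (one bin per walk step) to time `m / S` in
#' fractional days.
#'
#' @param n_days horizon in days.
#' @param granularity `"daily"` or `"hourly"`.
#' @param S steps per day.
#' @return numeric vector of collection times in days.
#' @export
collection_schedule <- function(n_days, granularity = c("daily", "hourly"),
                                S = 12) {
  granularity <- match.arg(granularity)
  if (n_days < 1) stop("`n_days` must be at least 1")
  if (granularity == "daily") seq_len(n_days)
  else seq_len(S * n_days) / S
}

#' Simulate an MRR experiment with diffusing walkers
#'
#' Releases `N` independent walkers at the release point; each takes `S`
#' isotropic steps of fixed length `k * h` per day.  Before every step, a
#' walker within the interaction disk (radius `(q + p) * h`) of its nearest
#' in-range capture site draws a Bernoulli trial with success probability
#' `s_e`: on success inside the collection disk (radius `q * h`) it is
#' captured and recorded under the site's zone and the current collection
#' bin; on success inside the attracting annulus its next displacement
#' (still of length `k * h`, clipped to land at the center when closer than
#' one step) is directed at the site center; on failure it steps
#' isotropically.  Walkers crossing the region boundary are removed
#' permanently and never counted.  The recapture ratios are averaged over
#' `reps` independent replicates, each with its own RNG stream derived
#' from the master seed.
#'
#' @param layout a [study_layout()].
#' @param walk a [walk_config()].
#' @param site_params optional named list overriding `q`, `p` and/or `s_e`
#'   for every site (used by the inverse solver).
#' @param granularity `"daily"` or `"hourly"` capture binning.
#' @param collect_days optional vector of observed collection days (daily
#'   granularity only); simulated daily bins are accumulated into the
#'   half-open intervals ending at each collection day, matching
#'   experiments that collect on non-consecutive days.
#' @param return_positions record the final positions of free walkers.
#' @param track_msd record the mean square displacement of free walkers
#'   after every step.
#' @return an object of class `sim_output`: `counts` (collection bins x
#'   zones, summed over replicates), `captures` (bins x zones x reps
#'   array), `times`, `tau` and `sigma` (replicate-averaged ratios; `NaN`
#'   when no replicate captured anything), `captured`/`exited`/`free`
#'   per-replicate bookkeeping, `msd`, `positions`, `seed`.
#' @export
simulate_recapture <- function(layout, walk, site_params = NULL,
                               granularity = c("daily", "hourly"),
                               collect_days = NULL,
                               return_positions = FALSE, track_msd = FALSE) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(layout, "study_layout"), inherits(walk, "walk_config"))
  s <- layout$sites
  if (!is.null(site_params)) {
    for (col in c("q", "p", "s_e"))
      if (!is.null(site_params[[col]])) s[[col]] <- site_params[[col]]
    layout$sites <- s
  }
  check_site_overlap(layout)
  seed <- walk$seed
  if (is.null(seed)) seed <- sample.int(.seed_cap, 1)
  nz <- length(layout$zone_bounds) - 1
  res <- cpp_simulate(layout$release[1], layout$release[2], layout$region,
                      s$x, s$y, as.integer(s$zone),
                      s$q * layout$h, s$p * layout$h, s$s_e,
                      as.integer(nz), walk$k * layout$h,
                      walk$S, walk$n_days, walk$N, walk$reps,
                      as.double(seed),
                      granularity == "hourly", return_positions, track_msd)
  captures <- res$captures
  times <- collection_schedule(walk$n_days, granularity, walk$S)
  if (!is.null(collect_days)) {
    if (granularity != "daily")
      stop("`collect_days` applies to daily granularity only")
    if (max(collect_days) > walk$n_days)
      stop("`collect_days` extend beyond the simulation horizon")
    grp <- findInterval(times, c(0, collect_days), left.open = TRUE)
    keep <- grp >= 1 & grp <= length(collect_days)
    agg <- array(0L, c(length(collect_days), nz, walk$reps))
    for (b in which(keep))
      agg[grp[b], , ] <- agg[grp[b], , , drop = FALSE] + captures[b, , , drop = FALSE]
    captures <- agg
    times <- collect_days
  }
  rep_tot <- apply(captures, 3, sum)
  avg_ratio <- function(margin) {
    per_rep <- apply(captures, c(margin, 3), sum)
    ok <- rep_tot > 0
    if (!any(ok)) return(rep(NaN, nrow(per_rep)))
    rowMeans(sweep(per_rep[, ok, drop = FALSE], 2, rep_tot[ok], `/`))
  }
  structure(list(counts = apply(captures, c(1, 2), sum),
                 captures = captures, times = times,
                 zone_bounds = layout$zone_bounds,
                 tau = avg_ratio(1), sigma = avg_ratio(2),
                 captured = res$captured, exited = res$exited,
                 free = res$free, msd = res$msd,
                 positions = res$positions,
                 granularity = granularity, seed = seed, walk = walk),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(paste0("Forward simulation: %d reps x %d walkers, %d bins x ",
                     "%d zones\n"),
              length(x$captured), x$walk$N, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("Captured %s, exited %s, free %s (per-rep means); seed %s\n",
              format(mean(x$captured)), format(mean(x$exited)),
              format(mean(x$free)), format(x$seed)))
  invisible(x)
}

#' Recapture ratios of a simulation
#'
#' @param sim a `sim_output`.
#' @return a `ratio_set` with the replicate-averaged simulated ratios.
#' @export
sim_ratios <- function(sim) {
  ratio_set(sim$tau, sim$sigma, days = sim$times,
            zone_bounds = sim$zone_bounds)
}
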