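#' Study layout for the agent-based forward model
#'
#' Geometry of a (real or virtual) MRR experiment: the release point, the
#' rectangular computational region (walkers crossing its boundary are
#' removed and never return), the annular zone radii, and the capture
#' sites.  Each site has a collection disk of radius `q * h` (walkers
#' inside may be captured), an attracting annulus of width `p * h` (walkers
#' inside are pulled toward the site center), and a Bernoulli efficiency
#' `s_e`.
#'
#' Site interaction disks of radius `(q + p) * h` must be pairwise
#' non-overlapping and the release point must not sit inside a collection
#' disk.
#'
#' @param release numeric length-2, release point `(x, y)` in meters.
#' @param zone_bounds zone radii in meters.
#' @param sites data frame with columns `x`, `y` (meters) and optionally
#'   `q`, `p`, `s_e` per site; missing trap columns are filled from `trap`.
#' @param trap default trap parameters, a list with `q`, `p` (units of
#'   `h`) and `s_e` in `(0, 1]`.
#' @param region numeric length-4 `(xmin, ymin, xmax, ymax)`; default is
#'   the square circumscribing the outermost zone, centered on the release
#'   point.
#' @param h reference mesh length in meters (default 0.1); `q` and `p` are
#'   expressed in units of `h`.
#' @return an object of class `study_layout`; sites gain a `zone` column
#'   (zone index of the site center).
#' @export
study_layout <- function(release, zone_bounds, sites,
                         trap = list(q = 10, p = 0, s_e = 1),
                         region = NULL, h = 0.1) {
  release <- as.numeric(release)
  if (length(release) != 2) stop("`release` must be (x, y)")
  zone_bounds <- as.numeric(zone_bounds)
  if (zone_bounds[1] < 0 || any(diff(zone_bounds) <= 0))
    stop("`zone_bounds` must be non-negative and strictly increasing")
  if (is.null(region)) {
    r <- max(zone_bounds)
    region <- c(release[1] - r, release[2] - r, release[1] + r, release[2] + r)
  }
  region <- as.numeric(region)
  if (release[1] < region[1] || release[1] > region[3] ||
      release[2] < region[2] || release[2] > region[4])
    stop("release point must lie inside the region")
  sites <- as.data.frame(sites)
  if (nrow(sites) > 0) {
    if (!all(c("x", "y") %in% names(sites)))
      stop("`sites` must have columns x and y")
    for (col in c("q", "p", "s_e"))
      if (is.null(sites[[col]])) sites[[col]] <- trap[[col]]
    if (any(sites$q <= 0) || any(sites$p < 0))
      stop("site `q` must be positive and `p` non-negative")
    if (any(sites$s_e <= 0 | sites$s_e > 1))
      stop("site `s_e` must be in (0, 1]")
    if (any(sites$x < region[1] | sites$x > region[3] |
            sites$y < region[2] | sites$y > region[4]))
      stop("all sites must lie inside the region")
    sites$zone <- vapply(seq_len(nrow(sites)), function(i)
      zone_of_point(sites$x[i], sites$y[i], release, zone_bounds), integer(1))
  } else {
    sites <- data.frame(x = numeric(0), y = numeric(0), q = numeric(0),
                        p = numeric(0), s_e = numeric(0), zone = integer(0))
  }
  out <- structure(list(release = release, region = region,
                        zone_bounds = zone_bounds, sites = sites, h = h),
                   class = "study_layout")
  check_site_overlap(out)
  out
}

#' @export
print.study_layout <- function(x, ...) {
  cat(sprintf(paste0("Study layout: %d capture sites, %d zones ",
                     "(outer radius %g m), h = %g m\n"),
              nrow(x$sites), length(x$zone_bounds) - 1,
              max(x$zone_bounds), x$h))
  cat(sprintf("Release (%g, %g); region [%g, %g] x [%g, %g]\n",
              x$release[1], x$release[2], x$region[1], x$region[3],
              x$region[2], x$region[4]))
  invisible(x)
}

check_site_overlap <- function(layout, q = NULL, p = NULL) {
  s <- layout$sites
  if (nrow(s) < 1) return(invisible(TRUE))
  qv <- if (is.null(q)) s$q else rep(q, nrow(s))
  pv <- if (is.null(p)) s$p else rep(p, nrow(s))
  rad <- (qv + pv) * layout$h
  if (nrow(s) > 1) {
    d <- as.matrix(stats::dist(cbind(s$x, s$y)))
    lim <- outer(rad, rad, `+`)
    diag(d) <- Inf
    if (any(d < lim - 1e-9))
      stop("capture-site interaction disks overlap")
  }
  dr <- sqrt((s$x - layout$release[1])^2 + (s$y - layout$release[2])^2)
  if (any(dr <= qv * layout$h))
    stop("release point lies inside a collection disk")
  invisible(TRUE)
}

zone_of_point <- function(x, y, release, zone_bounds) {
  d <- sqrt((x - release[1])^2 + (y - release[2])^2)
  if (d > max(zone_bounds) + 1e-9)
    stop("site beyond the outermost zone radius")
  if (d < zone_bounds[1] - 1e-9)
    stop("site inside the innermost zone bound")
  # half-open annuli (r_{j-1}, r_j]; the inner edge of zone 1 is included
  j <- findInterval(d, zone_bounds, left.open = TRUE)
  as.integer(max(j, 1L))
}

#' Zone index of a capture site
#'
#' Zone `j` such that the site's distance to the release point lies in
#' `(r_{j-1}, r_j]`; a site at the release point (or on the innermost
#' bound) belongs to zone 1.
#'
#' @param site list or one-row data frame with `x`, `y` in meters.
#' @param layout a [study_layout()].
#' @return integer zone index.
#' @export
zone_of_site <- function(site, layout) {
  zone_of_point(site$x, site$y, layout$release, layout$zone_bounds)
}

#' Walker configuration for the forward model
#'
#' @param k step-length multiplier; each step has length `k * h` meters.
#' @param n_days simulation horizon in days.
#' @param S steps per day (default 12: one step per active hour).
#' @param N number of walkers released (default 10000).
#' @param reps independent replicate simulations to average (default 5).
#' @param seed integer RNG seed; drawn (and recorded) at simulation time
#'   when `NULL`.
#' @return an object of class `walk_config`.
#' @export
walk_config <- function(k, n_days, S = 12, N = 10000, reps = 5, seed = NULL) {
  if (k <= 0) stop("`k` must be positive")
  if (S < 1 || N < 1 || reps < 1 || n_days < 1)
    stop("`S`, `N`, `reps` and `n_days` must be at least 1")
  structure(list(k = k, S = as.integer(S), N = as.integer(N),
                 n_days = as.integer(n_days), reps = as.integer(reps),
                 seed = seed),
            class = "walk_config")
}

#' Read and write study layouts as JSON
#'
#' Schema: `{"release": [x, y], "region": [xmin, ymin, xmax, ymax],
#' "zone_bounds": [...], "h": 0.1, "sites": [{"x":, "y":, "q":, "p":,
#' "s_e":}, ...]}`.  Distances are meters; `q` and `p` are in units of
#' `h`.
#'
#' @param path file path.
#' @return [read_layout_json()] returns a [study_layout()].
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  sites <- if (is.null(x$sites) || length(x$sites) == 0)
    data.frame(x = numeric(0), y = numeric(0)) else as.data.frame(x$sites)
  study_layout(x$release, x$zone_bounds, sites,
               region = x$region, h = if (is.null(x$h)) 0.1 else x$h)
}

#' @rdname read_layout_json
#' @param layout a [study_layout()].
#' @export
write_layout_json <- function(layout, path) {
  x <- list(release = layout$release, region = layout$region,
            zone_bounds = layout$zone_bounds, h = layout$h,
            sites = layout$sites[, c("x", "y", "q", "p", "s_e")])
  writeLines(jsonlite::toJSON(x, auto_unbox = FALSE, digits = NA,
                              dataframe = "rows"), path)
  invisible(path)
}
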