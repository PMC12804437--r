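#' Recapture table for a mark-release-recapture experiment
#'
#' Bundles the per-day, per-zone recapture counts of an MRR experiment with
#' the elapsed collection days and the radii bounding the concentric annular
#' recapture zones.  Zone `j` is the half-open annulus
#' `(r[j-1], r[j]]` around the release point (the innermost zone also
#' includes its inner boundary, so a capture at distance `r0` belongs to
#' zone 1).
#'
#' @param counts numeric matrix of non-negative recapture counts, one row
#'   per collection day and one column per zone.  Counts are usually
#'   integers; real values arise after applying [lillie_correction()].
#' @param days numeric vector of elapsed days since release, positive and
#'   strictly increasing; need not be consecutive integers.
#' @param zone_bounds numeric vector of zone radii in meters,
#'   `r0 < r1 < ... < r_nz` with `r0 >= 0`; length `ncol(counts) + 1`.
#'   Zone widths may be unequal.
#' @param released optional total number of insects released.
#' @return an object of class `recapture_table`.
#' @examples
#' tab <- recapture_table(matrix(c(5, 3, 2, 0), 2, 2), days = 1:2,
#'                        zone_bounds = c(0, 15, 30))
#' temporal_ratios(tab)
#' @export
recapture_table <- function(counts, days, zone_bounds, released = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be a numeric matrix of non-negative finite values")
  days <- as.numeric(days)
  if (length(days) != nrow(counts))
    stop("`days` must have one entry per row of `counts`")
  if (any(days <= 0) || any(diff(days) <= 0))
    stop("`days` must be positive and strictly increasing")
  zone_bounds <- as.numeric(zone_bounds)
  if (length(zone_bounds) != ncol(counts) + 1)
    stop("`zone_bounds` must have length ncol(counts) + 1")
  if (zone_bounds[1] < 0 || any(diff(zone_bounds) <= 0))
    stop("`zone_bounds` must be non-negative and strictly increasing")
  if (!is.null(released) && (length(released) != 1 || released <= 0))
    stop("`released` must be a single positive number")
  dimnames(counts) <- list(day = days, zone = seq_len(ncol(counts)))
  structure(list(counts = counts, days = days, zone_bounds = zone_bounds,
                 released = released),
            class = "recapture_table")
}

#' @export
print.recapture_table <- function(x, ...) {
  cat(sprintf("Recapture table: %d collection days x %d zones, %s recaptured\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts))))
  cat("Zone bounds (m):", paste(x$zone_bounds, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

total_recaptured <- function(table) sum(table$counts)

#' Temporal recapture ratios
#'
#' Fraction of all recaptured insects caught on each collection day,
#' `tau_i = N_i / N_tot`.  Ratios are invariant under uniform scaling of
#' the counts (a constant recapture fraction cancels).
#'
#' @param table a [recapture_table()].
#' @return numeric vector summing to 1, named by elapsed day.
#' @export
temporal_ratios <- function(table) {
  tot <- total_recaptured(table)
  if (tot <= 0) stop("cannot compute ratios: total recaptures is zero")
  tau <- rowSums(table$counts) / tot
  names(tau) <- table$days
  tau
}

#' Spatial recapture ratios
#'
#' Fraction of all recaptured insects caught in each annular zone,
#' `sigma_j = N_j / N_tot`.
#'
#' @inheritParams temporal_ratios
#' @return numeric vector summing to 1, one entry per zone.
#' @export
spatial_ratios <- function(table) {
  tot <- total_recaptured(table)
  if (tot <= 0) stop("cannot compute ratios: total recaptures is zero")
  unname(colSums(table$counts)) / tot
}

#' Bundle temporal and spatial ratios
#'
#' @inheritParams temporal_ratios
#' @param corrected logical, whether the ratios come from area-corrected
#'   counts.
#' @param correction_scope one of `"none"`, `"spatial_only"`,
#'   `"spatial_and_temporal"`.
#' @return an object of class `ratio_set` with elements `temporal`,
#'   `spatial`, `days`, `zone_bounds`, `corrected`, `correction_scope`.
#' @export
recapture_ratios <- function(table, corrected = FALSE,
                             correction_scope = "none") {
  ratio_set(temporal_ratios(table), spatial_ratios(table),
            days = table$days, zone_bounds = table$zone_bounds,
            corrected = corrected, correction_scope = correction_scope)
}

ratio_set <- function(temporal, spatial, days = NULL, zone_bounds = NULL,
                      corrected = FALSE, correction_scope = "none") {
  for (v in list(temporal, spatial)) {
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
      stop("ratios must lie in [0, 1]")
    if (abs(sum(v) - 1) > 1e-9)
      stop("ratios must sum to 1")
  }
  structure(list(temporal = temporal, spatial = spatial, days = days,
                 zone_bounds = zone_bounds, corrected = corrected,
                 correction_scope = match.arg(correction_scope,
                   c("none", "spatial_only", "spatial_and_temporal"))),
            class = "ratio_set")
}

#' Trap census over recapture zones
#'
#' Records how many capture sites (traps or collection houses) sit in each
#' annular zone, together with the zone areas, for use in the Lillie
#' area correction.
#'
#' @param sites_per_zone non-negative integer vector, number of capture
#'   sites per zone.
#' @param zone_bounds zone radii in meters (length one more than
#'   `sites_per_zone`).
#' @return an object of class `trap_census` with `sites_per_zone`,
#'   `zone_areas` (m^2), `total_area`, `total_sites`, `zone_bounds`.
#' @export
trap_census <- function(sites_per_zone, zone_bounds) {
  sites_per_zone <- as.numeric(sites_per_zone)
  if (any(sites_per_zone < 0)) stop("`sites_per_zone` must be non-negative")
  zone_bounds <- as.numeric(zone_bounds)
  if (length(zone_bounds) != length(sites_per_zone) + 1)
    stop("`zone_bounds` must have length(sites_per_zone) + 1")
  areas <- pi * diff(zone_bounds^2)
  structure(list(sites_per_zone = sites_per_zone, zone_areas = areas,
                 total_area = sum(areas), total_sites = sum(sites_per_zone),
                 zone_bounds = zone_bounds),
            class = "trap_census")
}

#' Lillie area correction for uneven trap density
#'
#' Rescales the recapture counts of each zone to compensate for trap
#' density varying between zones.  The corrected count for zone `j` is
#' `N_j^c = N_j * (nT_tot / nT_j) * (A_j / A_tot)`, i.e. each count is
#' divided by the number of traps in its zone and multiplied by the
#' zone-area-weighted total trap count.  When trap density is uniform
#' (`nT_j` proportional to `A_j`) the correction is the identity.
#'
#' @param table a [recapture_table()].
#' @param census a [trap_census()] consistent with the table's zones.
#' @param scope `"spatial_and_temporal"` corrects every (day, zone) cell so
#'   that both ratio types are recomputed from corrected counts;
#'   `"spatial_only"` marks the table so that downstream fits correct only
#'   the spatial ratios, keeping the raw temporal ratios (the situation
#'   where per-day-per-zone counts are not reported).  The cell counts
#'   returned are the same in both cases; the scope is carried as an
#'   attribute and honoured by [fit_atc()].
#' @param rounding `"none"` (default) keeps real-valued corrected counts;
#'   `"nearest"` rounds each corrected cell to the nearest integer,
#'   reproducing the round-off sensitivity of corrected field tables.
#' @return a [recapture_table()] of corrected (possibly real-valued)
#'   counts, with attributes `correction_scope` and `rounding`.
#' @export
lillie_correction <- function(table, census,
                              scope = c("spatial_and_temporal", "spatial_only"),
                              rounding = c("none", "nearest")) {
  scope <- match.arg(scope)
  rounding <- match.arg(rounding)
  if (length(census$sites_per_zone) != ncol(table$counts))
    stop("census and table disagree on the number of zones")
  nT <- census$sites_per_zone
  zone_tot <- colSums(table$counts)
  if (any(zone_tot > 0 & nT == 0))
    stop("captures recorded in a zone with no registered capture sites")
  factor <- ifelse(nT > 0,
                   (census$total_sites / nT) *
                     (census$zone_areas / census$total_area),
                   1)
  corrected <- sweep(table$counts, 2, factor, `*`)
  if (rounding == "nearest") corrected <- round(corrected)
  out <- recapture_table(corrected, table$days, table$zone_bounds,
                         table$released)
  attr(out, "correction_scope") <- scope
  attr(out, "rounding") <- rounding
  out
}

#' Read and write recapture tables as CSV
#'
#' The on-disk format is long: columns `day`, `zone` (1-based index),
#' `count`, with a header row.  Zone bounds are stored separately (see
#' [read_zone_bounds()]).  Writing then reading reproduces the table
#' exactly.
#'
#' @param path file path.
#' @param zone_bounds zone radii in meters.
#' @param released optional number released.
#' @return [read_recapture_csv()] returns a [recapture_table()];
#'   [write_recapture_csv()] returns `path` invisibly.
#' @export
read_recapture_csv <- function(path, zone_bounds, released = NULL) {
  df <- read.csv(path)
  need <- c("day", "zone", "count")
  if (!all(need %in% names(df)))
    stop("recapture CSV must have columns day, zone, count")
  days <- sort(unique(df$day))
  nz <- length(zone_bounds) - 1
  if (any(df$zone < 1 | df$zone > nz))
    stop("zone index outside 1..", nz)
  counts <- matrix(0, length(days), nz)
  counts[cbind(match(df$day, days), df$zone)] <- df$count
  recapture_table(counts, days, zone_bounds, released)
}

#' @rdname read_recapture_csv
#' @param table a [recapture_table()].
#' @export
write_recapture_csv <- function(table, path) {
  df <- data.frame(day = rep(table$days, ncol(table$counts)),
                   zone = rep(seq_len(ncol(table$counts)),
                              each = nrow(table$counts)),
                   count = as.vector(table$counts))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read zone bounds from a one-column CSV or a JSON array
#'
#' @param path file path; `.json` files are parsed as a JSON array of
#'   radii, anything else as a headered single-column CSV.
#' @return numeric vector of radii in meters.
#' @export
read_zone_bounds <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    as.numeric(jsonlite::fromJSON(path))
  else
    as.numeric(read.csv(path)[[1]])
}

#' Read a trap census from JSON
#'
#' Expects `{"sites_per_zone": [...], "zone_bounds": [...]}`.
#'
#' @param path file path.
#' @return a [trap_census()].
#' @export
read_trap_census <- function(path) {
  x <- jsonlite::fromJSON(path)
  trap_census(x$sites_per_zone, x$zone_bounds)
}
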