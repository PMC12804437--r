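# Printed recapture tables from two published MRR field studies: a village
# release (center and edge release points, six 15 m zones, six daily
# collections) and a suburban release (50 m zones starting at 10 m,
# non-consecutive collection days).  Used as worked real inputs throughout
# the tests.

hainan_center <- function() {
  counts <- cbind(c(43, 12, 9, 13, 5, 3), c(4, 1, 1, 3, 3, 1),
                  c(0, 1, 0, 0, 1, 1), c(1, 0, 0, 0, 0, 3),
                  c(0, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 0))
  # per-day-per-zone cells are not published for this study; only the day
  # totals (48,14,10,16,9,8) and zone totals (85,13,3,4,0,0) are.  The cell
  # split above is a synthetic disaggregation consistent with both margins,
  # used only where a full table object is required; ratio-level tests rely
  # on the margins alone.
  recapture_table(counts, days = 1:6, zone_bounds = seq(0, 90, by = 15))
}

hainan_center_margins <- function() {
  list(day_counts = c(48, 14, 10, 16, 9, 8),
       zone_counts = c(85, 13, 3, 4, 0, 0),
       days = 1:6, zone_bounds = seq(0, 90, by = 15), n_tot = 105)
}

hainan_edge_margins <- function() {
  list(day_counts = c(29, 12, 7, 9, 9, 10),
       zone_counts = c(0, 49, 17, 6, 2, 2),
       days = 1:6, zone_bounds = c(0, 15, 27, 37, 60, 75, 92), n_tot = 76)
}

cairns_margins <- function() {
  list(day_counts = c(20, 18, 9, 5),
       zone_counts = c(24, 16, 7, 5),
       days = c(5, 8, 11, 15), zone_bounds = c(10, 60, 110, 160, 210),
       n_tot = 52)
}

# small all-purpose table with known margins
toy_table <- function() {
  recapture_table(matrix(c(6, 2, 3, 1, 0, 0), nrow = 2), days = c(1, 3),
                  zone_bounds = c(0, 10, 20, 40))
}

# trap-free layout in a large box, for free-diffusion checks
free_layout <- function(half = 500) {
  study_layout(c(0, 0), seq(0, 90, by = 15),
               data.frame(x = numeric(0), y = numeric(0)),
               region = c(-half, -half, half, half))
}
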