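#' Radial presence density under two-dimensional diffusion
#'
#' Probability density for the distance `r` from the release point of an
#' insect diffusing in the plane with diffusion coefficient `D` after time
#' `t`: `P_t(r) = r/(2 D t) * exp(-r^2 / (4 D t))`.  Integrates to 1 over
#' `r` in `[0, Inf)`, with mode at `sqrt(2 D t)`.
#'
#' @param r distance from the release point, meters (non-negative;
#'   vectorized).
#' @param D diffusion coefficient, m^2/day (positive).
#' @param t elapsed time, days (positive).
#' @return density per meter.
#' @export
presence_pdf <- function(r, D, t) {
  check_Dt(D, t)
  if (any(r < 0)) stop("`r` must be non-negative")
  r / (2 * D * t) * exp(-r^2 / (4 * D * t))
}

#' Probability of presence in an annulus
#'
#' Integral of [presence_pdf()] between radii `r_a` and `r_b`:
#' `exp(-r_a^2 / (4 D t)) - exp(-r_b^2 / (4 D t))`.  `r_b = Inf` is
#' evaluated in closed form.  Probabilities over contiguous annuli
#' telescope.
#'
#' @param r_a inner radius, meters (non-negative; vectorized).
#' @param r_b outer radius, meters, strictly greater than `r_a`; may be
#'   `Inf`.
#' @inheritParams presence_pdf
#' @return probability in `[0, 1]`.
#' @export
annulus_prob <- function(r_a, r_b, D, t) {
  check_Dt(D, t)
  if (any(r_a < 0)) stop("`r_a` must be non-negative")
  if (any(r_a >= r_b)) stop("`r_b` must exceed `r_a`")
  # r_b = Inf gives exp(-Inf) = 0: the closed form covers the open annulus
  exp(-r_a^2 / (4 * D * t)) - exp(-r_b^2 / (4 * D * t))
}

#' Mean and mean-square distance traveled under diffusion
#'
#' `mean_distance()` is the expected distance from the release point,
#' `sqrt(pi * D * t)` -- the theoretical mean distance traveled (MDT) after
#' `t` days.  `mean_square_distance()` is `4 * D * t`.
#'
#' @param D diffusion coefficient, m^2/day (non-negative).
#' @param t elapsed time, days (non-negative).
#' @return meters, or m^2 for the mean square.
#' @export
mean_distance <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stop("`D` and `t` must be non-negative")
  sqrt(pi * D * t)
}

#' @rdname mean_distance
#' @export
mean_square_distance <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stop("`D` and `t` must be non-negative")
  4 * D * t
}

check_Dt <- function(D, t) {
  if (any(D <= 0)) stop("`D` must be positive")
  if (any(t <= 0)) stop("`t` must be positive")
  invisible(TRUE)
}
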