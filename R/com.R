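#' Estimate the body centre of mass from the pelvic markers
#'
#' The CoM is approximated by the midpoint between the midpoint of the left
#' and right anterior-superior iliac spine markers and the midpoint of the
#' two posterior-superior iliac spine markers -- i.e. the centroid of the
#' four pelvic markers. The trajectory is expressed in the walking frame
#' (anterior-posterior, medio-lateral, vertical), with the vertical
#' coordinate measured from the floor datum (the lowest heel-marker sample
#' of the trial).
#'
#' @param recording A [gait_recording()] with the four pelvic markers.
#' @return Tibble with columns `time`, `ap`, `ml`, `v` (metres), carrying
#'   attribute `sample_rate`.
#' @export
estimate_com <- function(recording) {
  require_markers(recording, PELVIC_MARKERS)
  mid <- pelvic_midpoint(recording)
  frame <- walking_frame(recording)
  floor_v <- floor_height(recording)
  vax_i <- match(recording$vertical_axis, c("x", "y", "z"))
  out <- tibble::tibble(
    time = recording$data$time,
    ap = drop(mid %*% frame$ap),
    ml = drop(mid %*% frame$ml),
    v = mid[, vax_i] - floor_v
  )
  attr(out, "sample_rate") <- recording$sample_rate
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass design forward and backward
#' (zero net phase, DC gain 1). With the default configuration the design
#' itself is 4th order, so the combined magnitude response is 8th order;
#' `filter_halved = TRUE` in [gait_config()] instead runs a 2nd-order design
#' both ways for a combined 4th-order magnitude response.
#'
#' @param x Numeric vector to filter.
#' @param sample_rate Sampling rate (Hz).
#' @param config A [gait_config()] providing `filter_cutoff` and
#'   `filter_order`.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, sample_rate, config = gait_config()) {
  ord <- config$filter_order
  if (config$filter_halved) ord <- max(1L, ord %/% 2L)
  if (length(x) <= 3 * ord) {
    abort(sprintf("Series too short to filter: %d samples with order %d.",
                  length(x), ord))
  }
  if (config$filter_cutoff >= sample_rate / 2) {
    abort("Filter cut-off must be below the Nyquist frequency.")
  }
  bw <- signal::butter(ord, config$filter_cutoff / (sample_rate / 2),
                       type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (zero-initial-condition filtering otherwise rings
  # at the edges)
  n <- length(x)
  k <- min(n - 2L, 6L * (2L * ord + 1L))
  x_pad <- c(2 * x[1] - x[(k + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - k)])
  y <- as.numeric(signal::filtfilt(bw, x_pad))
  y[(k + 1L):(k + n)]
}

#' First-order finite-difference velocity
#'
#' Forward first differences divided by the sampling interval, aligned to the
#' earlier sample, with the final value replicated to preserve length.
#' A central-difference scheme is available through `scheme`.
#'
#' @param x Numeric vector of positions (m).
#' @param sample_rate Sampling rate (Hz).
#' @param scheme `"forward"` or `"central"`.
#' @return Velocity series (m/s), same length as `x`.
#' @export
finite_velocity <- function(x, sample_rate, scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  n <- length(x)
  if (n < 2) abort("Need at least two samples to differentiate.")
  dt <- 1 / sample_rate
  if (scheme == "forward") {
    v <- diff(x) / dt
    c(v, v[n - 1L])
  } else {
    v <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1L]) / dt
    v
  }
}

#' Centre-of-mass trajectory with velocities
#'
#' Runs the standard processing chain: pelvic-marker CoM estimate, zero-phase
#' low-pass filtering of the position, finite-difference velocities, and
#' (optionally) the same filter on the velocities.
#'
#' @param recording A [gait_recording()].
#' @param config A [gait_config()].
#' @return Tibble with `time`, `ap`, `ml`, `v`, `v_ap`, `v_ml`, `v_v`,
#'   carrying attribute `sample_rate`.
#' @export
com_trajectory <- function(recording, config = gait_config()) {
  com <- estimate_com(recording)
  sr <- attr(com, "sample_rate")
  for (cc in c("ap", "ml", "v")) {
    com[[cc]] <- lowpass_filter(com[[cc]], sr, config)
    vel <- finite_velocity(com[[cc]], sr, config$velocity_scheme)
    if (config$filter_velocity) vel <- lowpass_filter(vel, sr, config)
    com[[paste0("v_", cc)]] <- vel
  }
  attr(com, "sample_rate") <- sr
  com
}

#' Mechanical energies of the centre of mass
#'
#' Potential energy `e_p = m g h` with `h` the floor-referenced vertical CoM
#' position; kinetic energy `e_k = m/2 (v_ap^2 + v_ml^2 + v_v^2)` from the
#' full 3D velocity magnitude; total energy their pointwise sum.
#'
#' @param com A CoM trajectory from [com_trajectory()] (needs `v`, `v_ap`,
#'   `v_ml`, `v_v`).
#' @param mass Body mass (kg), positive.
#' @param config A [gait_config()] providing `gravity`.
#' @return Tibble `time`, `e_p`, `e_k`, `e_tot` (joules), with attribute
#'   `sample_rate`.
#' @export
com_energies <- function(com, mass, config = gait_config()) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0) {
    abort("`mass` must be a single positive number (kg).")
  }
  needed <- c("time", "v", "v_ap", "v_ml", "v_v")
  if (!all(needed %in% names(com))) {
    abort("`com` must contain columns time, v, v_ap, v_ml, v_v (see com_trajectory()).")
  }
  e_p <- mass * config$gravity * com$v
  e_k <- 0.5 * mass * (com$v_ap^2 + com$v_ml^2 + com$v_v^2)
  out <- tibble::tibble(time = com$time, e_p = e_p, e_k = e_k,
                        e_tot = e_p + e_k)
  attr(out, "sample_rate") <- attr(com, "sample_rate")
  out
}

#' Time-normalize a step curve to a 0--100% grid
#'
#' Linear interpolation of a series onto `config$normalized_samples_per_step`
#' points spanning the step interval, used for ensemble averaging and
#' plotting of per-step curves.
#'
#' @param time Sample times (s).
#' @param x Series values at `time`.
#' @param t_start,t_end Step interval (must lie inside the series support and
#'   contain at least 3 samples).
#' @param config A [gait_config()].
#' @return Tibble with `pct` (0--100) and `value`.
#' @export
time_normalize <- function(time, x, t_start, t_end, config = gait_config()) {
  if (t_start < min(time) - 1e-9 || t_end > max(time) + 1e-9 || t_end <= t_start) {
    abort("Step interval must lie inside the series support.")
  }
  if (sum(time >= t_start & time <= t_end) < 3) {
    abort("Step interval spans fewer than 3 samples.")
  }
  grid <- seq(t_start, t_end, length.out = config$normalized_samples_per_step)
  tibble::tibble(pct = seq(0, 100, length.out = config$normalized_samples_per_step),
                 value = approx(time, x, xout = grid)$y)
}
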