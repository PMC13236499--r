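#' Pipeline configuration
#'
#' Bundles the numerical constants and processing switches used throughout the
#' pipeline, so that every derived quantity is auditable from a single object.
#'
#' @param gravity Gravitational acceleration in m/s^2.
#' @param filter_cutoff Low-pass cut-off frequency for the centre-of-mass
#'   trajectory and velocity, in Hz.
#' @param filter_order Order of the Butterworth design that is applied
#'   forward and backward (zero phase). The default, 4, means a 4th-order
#'   design run in both directions; set `filter_halved = TRUE` to instead run
#'   a 2nd-order design twice so the combined magnitude response is 4th order.
#' @param filter_halved Logical; see `filter_order`.
#' @param normalized_samples_per_step Number of points of the 0--100% grid
#'   used when step-level curves are time-normalized.
#' @param froude_number Dimensionless Froude number used for the optimal
#'   walking speed. 0.25 is the classical energetically optimal value for
#'   bipedal walking.
#' @param event_algorithm Gait-event detection algorithm. Currently only
#'   `"coordinate"`: heel strikes at local maxima of the heel marker's
#'   anterior position relative to the pelvic midpoint, toe offs at local
#'   minima of the toe marker's relative anterior position.
#' @param min_steps_per_trial Minimum number of steps a trial must contain to
#'   be analysed.
#' @param velocity_scheme `"forward"` (first-order forward difference, last
#'   sample replicated) or `"central"`.
#' @param filter_velocity Logical; also low-pass filter the velocity series
#'   with the same filter after differentiation.
#' @param max_gap_frames Marker gaps up to this many frames are filled by
#'   cubic interpolation; longer gaps invalidate the overlapping steps.
#' @param step_duration_range Two-element numeric vector (s); steps with
#'   durations outside this range are rejected before averaging.
#' @param pool_alpha Significance level of the paired side-to-side test above
#'   which bilateral parameters are pooled across limbs.
#'
#' @return An object of class `gait_config` (a named list).
#' @export
#' @examples
#' cfg <- gait_config()
#' cfg$froude_number
gait_config <- function(gravity = 9.81,
                        filter_cutoff = 10,
                        filter_order = 4L,
                        filter_halved = FALSE,
                        normalized_samples_per_step = 101L,
                        froude_number = 0.25,
                        event_algorithm = c("coordinate"),
                        min_steps_per_trial = 4L,
                        velocity_scheme = c("forward", "central"),
                        filter_velocity = TRUE,
                        max_gap_frames = 10L,
                        step_duration_range = c(0.2, 2.5),
                        pool_alpha = 0.05) {
  stopifnot(gravity > 0, filter_cutoff > 0, filter_order >= 1,
            normalized_samples_per_step >= 3, froude_number > 0,
            min_steps_per_trial >= 1, max_gap_frames >= 0,
            length(step_duration_range) == 2,
            step_duration_range[1] < step_duration_range[2])
  structure(list(
    gravity = gravity,
    filter_cutoff = filter_cutoff,
    filter_order = as.integer(filter_order),
    filter_halved = isTRUE(filter_halved),
    normalized_samples_per_step = as.integer(normalized_samples_per_step),
    froude_number = froude_number,
    event_algorithm = match.arg(event_algorithm),
    min_steps_per_trial = as.integer(min_steps_per_trial),
    velocity_scheme = match.arg(velocity_scheme),
    filter_velocity = isTRUE(filter_velocity),
    max_gap_frames = as.integer(max_gap_frames),
    step_duration_range = step_duration_range,
    pool_alpha = pool_alpha
  ), class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
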