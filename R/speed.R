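#' Optimal walking speed from inverted-pendulum scaling
#'
#' `OWS = sqrt(Fr g L)`: the walking speed at which a subject of leg length
#' `L` walks at the Froude number `Fr`. With the classical energetically
#' optimal value `Fr = 0.25`, this is the dynamically similar speed at which
#' pendulum-like energy exchange is most effective.
#'
#' @param leg_length Leg length (m), positive.
#' @param config A [gait_config()] providing `froude_number` and `gravity`.
#' @return Optimal walking speed (m/s).
#' @export
#' @examples
#' optimal_walking_speed(1)  # sqrt(0.25 * 9.81) = 1.566
optimal_walking_speed <- function(leg_length, config = gait_config()) {
  if (any(!is.finite(leg_length) | leg_length <= 0)) {
    abort("`leg_length` must be positive and finite.")
  }
  sqrt(config$froude_number * config$gravity * leg_length)
}

#' Locomotor Rehabilitation Index
#'
#' `LRI = 100 SSWS / OWS`: the self-selected walking speed as a percentage
#' of the subject's predicted optimal walking speed. 100% means the subject
#' walks at the energetically optimal speed for their leg length; values far
#' below 100% indicate walking well below the dynamically similar optimum.
#' LRI is scale-free: rescaling both speeds by a common factor leaves it
#' unchanged.
#'
#' @param ssws Self-selected walking speed (m/s), non-negative.
#' @param ows Optimal walking speed (m/s), positive.
#' @return LRI in percent.
#' @export
locomotor_rehab_index <- function(ssws, ows) {
  if (any(!is.finite(ows) | ows <= 0)) abort("`ows` must be positive.")
  if (any(ssws < 0)) abort("`ssws` must be non-negative.")
  100 * ssws / ows
}
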