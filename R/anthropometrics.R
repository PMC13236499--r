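#' Subject anthropometrics
#'
#' Body measurements used by the mechanical model: mass enters the energy
#' computations, leg length enters the Froude-based optimal walking speed.
#' All lengths in metres, mass in kilograms.
#'
#' @param mass Body mass (kg), must be positive.
#' @param height Stature (m), optional.
#' @param leg_length Leg length (m), measured ASIS to medial malleolus;
#'   must lie in (0.3, 1.5) when given.
#' @param asis_distance Inter-ASIS distance (m), optional.
#' @param knee_width,ankle_width Joint widths (m), optional, positive.
#'
#' @return An `anthropometrics` object (named list).
#' @export
#' @examples
#' anthropometrics(mass = 70, leg_length = 0.85)
anthropometrics <- function(mass,
                            height = NA_real_,
                            leg_length = NA_real_,
                            asis_distance = NA_real_,
                            knee_width = NA_real_,
                            ankle_width = NA_real_) {
  if (!is.numeric(mass) || length(mass) != 1 || !is.finite(mass) || mass <= 0) {
    abort("`mass` must be a single positive number (kg).")
  }
  if (is.finite(leg_length) && (leg_length <= 0.3 || leg_length >= 1.5)) {
    abort("`leg_length` must lie in (0.3, 1.5) m.")
  }
  for (w in c(asis_distance = asis_distance, knee_width = knee_width,
              ankle_width = ankle_width)) {
    if (is.finite(w) && w <= 0) abort("widths must be positive when present.")
  }
  structure(list(mass = mass, height = height, leg_length = leg_length,
                 asis_distance = asis_distance, knee_width = knee_width,
                 ankle_width = ankle_width),
            class = "anthropometrics")
}

#' @export
print.anthropometrics <- function(x, ...) {
  cat("<anthropometrics>",
      sprintf("mass %.1f kg", x$mass),
      if (is.finite(x$leg_length)) sprintf("leg length %.3f m", x$leg_length),
      if (is.finite(x$height)) sprintf("height %.2f m", x$height), "\n")
  invisible(x)
}
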