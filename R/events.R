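#' Gait events of a trial
#'
#' Ordered heel-strike and toe-off times per side, in seconds from trial
#' start. Constructed by [detect_gait_events()] or directly from known times
#' (e.g. synthetic ground truth).
#'
#' @param heel_strikes Named list with numeric vectors `left` and `right`.
#' @param toe_offs Named list with numeric vectors `left` and `right`.
#' @param validate Check ordering/alternation invariants (default `TRUE`).
#' @return A `gait_events` object.
#' @export
gait_events <- function(heel_strikes, toe_offs = list(left = numeric(0), right = numeric(0)),
                        validate = TRUE) {
  ev <- structure(list(heel_strikes = lapply(heel_strikes[c("left", "right")], sort),
                       toe_offs = lapply(toe_offs[c("left", "right")], sort)),
                  class = "gait_events")
  if (validate) validate_gait_events(ev)
  ev
}

validate_gait_events <- function(ev) {
  for (side in c("left", "right")) {
    hs <- ev$heel_strikes[[side]]
    if (is.unsorted(hs, strictly = TRUE)) {
      abort(paste0("Heel strikes on the ", side, " side are not strictly increasing."))
    }
  }
  merged <- merged_strikes(ev)
  if (nrow(merged) >= 2 && any(merged$side[-1] == merged$side[-nrow(merged)])) {
    abort("Heel strikes do not alternate sides; inconsistent events.")
  }
  invisible(ev)
}

merged_strikes <- function(ev) {
  tb <- tibble::tibble(
    time = c(ev$heel_strikes$left, ev$heel_strikes$right),
    side = c(rep("left", length(ev$heel_strikes$left)),
             rep("right", length(ev$heel_strikes$right)))
  )
  dplyr::arrange(tb, .data$time)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d L / %d R heel strikes, %d L / %d R toe offs\n",
              length(x$heel_strikes$left), length(x$heel_strikes$right),
              length(x$toe_offs$left), length(x$toe_offs$right)))
  invisible(x)
}

#' @export
as_tibble.gait_events <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(event = "heel_strike", side = "left", time = x$heel_strikes$left),
    tibble::tibble(event = "heel_strike", side = "right", time = x$heel_strikes$right),
    tibble::tibble(event = "toe_off", side = "left", time = x$toe_offs$left),
    tibble::tibble(event = "toe_off", side = "right", time = x$toe_offs$right)
  ) %>% dplyr::arrange(.data$time)
}

#' Detect heel-strike and toe-off events from foot markers
#'
#' Coordinate-based detection: walking direction is auto-detected from the
#' pelvic midpoint's displacement, then heel strikes are taken at local
#' maxima of the heel marker's anterior position relative to the pelvic
#' midpoint and toe offs at local minima of the toe marker's relative
#' anterior position. This uses markers only (no force plates) and is
#' insensitive to walkway orientation and walking direction.
#'
#' @param recording A [gait_recording()] with pelvic and foot markers.
#' @param config A [gait_config()].
#' @return A [gait_events()] object (times in seconds from trial start).
#' @export
detect_gait_events <- function(recording, config = gait_config()) {
  require_markers(recording)
  frame <- walking_frame(recording)
  mid <- pelvic_midpoint(recording)
  mid_ap <- drop(mid %*% frame$ap)
  span <- diff(range(mid_ap, na.rm = TRUE))
  if (!is.finite(span) || span < 0.5) {
    abort("No anterior progression detected (pelvis displacement < 0.5 m); cannot identify gait events.")
  }
  t <- recording$data$time
  hs <- list(); to <- list()
  # spurious extrema are excluded by a prominence floor and a refractory
  # distance of 0.35 s (shorter than any plausible stride)
  min_dist <- max(3L, round(0.35 * recording$sample_rate))
  for (side in c("left", "right")) {
    pre <- if (side == "left") "L" else "R"
    heel_rel <- drop(marker_xyz(recording, paste0(pre, "HEE")) %*% frame$ap) - mid_ap
    toe_rel <- drop(marker_xyz(recording, paste0(pre, "TOE")) %*% frame$ap) - mid_ap
    prom <- 0.25 * diff(range(heel_rel, na.rm = TRUE))
    hs[[side]] <- t[find_extrema(heel_rel, min_dist, prom)]
    to[[side]] <- t[find_extrema(-toe_rel, min_dist,
                                 0.25 * diff(range(toe_rel, na.rm = TRUE)))]
  }
  n_steps <- length(hs$left) + length(hs$right) - 1L
  if (n_steps < config$min_steps_per_trial) {
    abort(sprintf("Only %d steps detected; trial rejected (min_steps_per_trial = %d).",
                  max(n_steps, 0L), config$min_steps_per_trial))
  }
  gait_events(heel_strikes = hs, toe_offs = to)
}

# Local maxima with a minimum separation (samples) and minimum topographic
# prominence: the drop to the lowest point between the peak and the nearest
# higher sample on each side (the full signal range if no higher sample
# exists). NA samples never qualify.
find_extrema <- function(x, min_dist, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  xi <- x
  xi[is.na(xi)] <- -Inf
  cand <- which(diff(sign(diff(xi))) < 0) + 1L
  cand <- cand[is.finite(x[cand])]
  if (length(cand) == 0) return(integer(0))
  prominence <- vapply(cand, function(i) {
    base <- -Inf
    for (dir in c(-1L, 1L)) {
      j <- i + dir
      run_min <- Inf
      while (j >= 1L && j <= n && xi[j] <= x[i]) {
        run_min <- min(run_min, xi[j])
        j <- j + dir
      }
      if (is.infinite(run_min)) run_min <- x[i]
      base <- max(base, run_min)
    }
    x[i] - base
  }, numeric(1))
  cand <- cand[prominence >= min_prom]
  if (length(cand) == 0) return(integer(0))
  # enforce separation, keeping the higher peak
  ord <- cand[order(x[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Segment a trial into steps
#'
#' A step runs from one heel strike to the next contralateral heel strike.
#' Intervals are ordered, contiguous and non-overlapping, each tagged with
#' the leading (landing-first) side.
#'
#' @param events A [gait_events()].
#' @return Tibble with columns `step_index`, `side` (the side striking at
#'   the start of the step), `t_start`, `t_end`, `duration`.
#' @export
segment_steps <- function(events) {
  merged <- merged_strikes(events)
  if (nrow(merged) >= 2 &&
      any(merged$side[-1] == merged$side[-nrow(merged)])) {
    abort("Heel strikes do not alternate sides; cannot segment steps.")
  }
  if (nrow(merged) < 2) {
    return(tibble::tibble(step_index = integer(0), side = character(0),
                          t_start = numeric(0), t_end = numeric(0),
                          duration = numeric(0)))
  }
  tibble::tibble(
    step_index = seq_len(nrow(merged) - 1L),
    side = merged$side[-nrow(merged)],
    t_start = merged$time[-nrow(merged)],
    t_end = merged$time[-1],
    duration = diff(merged$time)
  )
}
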