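#' Spatio-temporal gait parameters of one trial
#'
#' Computes the eight standard spatio-temporal parameters from detected gait
#' events and the heel-marker trajectories:
#'
#' * step time (s): interval between consecutive contralateral and
#'   ipsilateral heel strikes;
#' * stride time (s): interval between consecutive same-side heel strikes;
#' * step length (m): antero-posterior heel-to-heel distance between
#'   consecutive opposite-side strikes;
#' * stride length (m): antero-posterior distance covered between
#'   consecutive same-side strikes;
#' * double support (s): total time per gait cycle with both feet on the
#'   ground (sum of the two double-contact intervals);
#' * foot off (%): toe-off time as a percentage of the same-side gait cycle;
#' * cadence (steps/min);
#' * walking speed SSWS (m/s): stride length divided by stride time.
#'
#' Values are averaged across all valid cycles of the trial; bilateral
#' parameters are reported per side.
#'
#' @param events A [gait_events()].
#' @param recording The [gait_recording()] the events came from.
#' @return Tibble with columns `parameter`, `side` (`"left"`, `"right"` or
#'   `"both"`), `value`, `n_cycles`.
#' @export
compute_spatiotemporal <- function(events, recording) {
  validate_gait_events(events)
  frame <- walking_frame(recording)
  t <- recording$data$time
  heel_ap <- list(
    left = drop(marker_xyz(recording, "LHEE") %*% frame$ap),
    right = drop(marker_xyz(recording, "RHEE") %*% frame$ap)
  )
  ap_at <- function(side, times) {
    approx(t, heel_ap[[side]], xout = times, rule = 2)$y
  }
  other <- c(left = "right", right = "left")
  rows <- list()
  add <- function(parameter, side, values, n = NULL) {
    values <- values[is.finite(values)]
    if (length(values) == 0) return()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      parameter = parameter, side = side,
      value = mean(values), n_cycles = as.integer(n %||% length(values)))
  }

  steps <- segment_steps(events)
  stride_time <- list(); stride_len <- list()
  for (side in c("left", "right")) {
    hs <- events$heel_strikes[[side]]
    hs_c <- events$heel_strikes[[other[[side]]]]
    to <- events$toe_offs[[side]]
    # stride time / stride length: same-side strike to strike
    if (length(hs) >= 2) {
      st <- diff(hs)
      sl <- abs(diff(ap_at(side, hs)))
      stride_time[[side]] <- st; stride_len[[side]] <- sl
      add("stride_time", side, st)
      add("stride_length", side, sl)
      # foot off: first same-side toe off inside each cycle, % of that cycle
      fo <- vapply(seq_len(length(hs) - 1L), function(k) {
        cand <- to[to > hs[k] & to < hs[k + 1L]]
        if (length(cand) == 0) return(NA_real_)
        100 * (cand[1] - hs[k]) / (hs[k + 1L] - hs[k])
      }, numeric(1))
      add("foot_off", side, fo)
    }
    # step time / step length: contralateral strike -> this side's strike
    if (length(hs) >= 1 && length(hs_c) >= 1) {
      prev_c <- vapply(hs, function(h) {
        p <- hs_c[hs_c < h]
        if (length(p)) max(p) else NA_real_
      }, numeric(1))
      ok <- is.finite(prev_c)
      add("step_time", side, hs[ok] - prev_c[ok])
      add("step_length", side,
          abs(ap_at(side, hs[ok]) - ap_at(other[[side]], prev_c[ok])))
    }
  }

  # double support: per step, time from the new strike until the previous
  # stance foot's toe off; one gait cycle contains two such intervals
  if (nrow(steps) > 0) {
    ds_step <- vapply(seq_len(nrow(steps)), function(i) {
      lifting <- other[[steps$side[i]]]
      to <- events$toe_offs[[lifting]]
      cand <- to[to >= steps$t_start[i] & to <= steps$t_end[i]]
      if (length(cand) == 0) return(NA_real_)
      cand[1] - steps$t_start[i]
    }, numeric(1))
    add("double_support", "both", 2 * ds_step)
  }

  all_step_times <- steps$duration
  if (length(all_step_times)) {
    add("cadence", "both", 60 / mean(all_step_times), n = length(all_step_times))
  }

  st_all <- unlist(stride_time); sl_all <- unlist(stride_len)
  if (length(st_all) && length(sl_all)) {
    add("ssws", "both", mean(sl_all) / mean(st_all), n = length(st_all))
  }
  dplyr::bind_rows(rows)
}

#' Pool bilateral parameters across limbs
#'
#' Bilateral spatio-temporal parameters are averaged across sides only when
#' a preliminary paired side-to-side comparison found no significant
#' difference; parameters with a significant side difference are kept per
#' side. A parameter is pooled only if its paired p-value is strictly
#' greater than `alpha` (a p-value exactly at the threshold keeps the sides
#' separate).
#'
#' @param params Tidy parameter table with columns `parameter`, `side`,
#'   `value` (and optionally `subject_id`, `n_cycles`), as produced by
#'   [compute_spatiotemporal()].
#' @param side_tests Data frame with columns `parameter` and `p_value` from
#'   the paired side comparison (see [paired_limb_test()]). Parameters not
#'   listed are pooled.
#' @param alpha Pooling threshold, default 0.05.
#' @return The table with pooled parameters collapsed to `side = "pooled"`.
#' @export
pool_limbs <- function(params, side_tests = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(params))
  sig <- character(0)
  if (!is.null(side_tests) && nrow(side_tests)) {
    sig <- side_tests$parameter[side_tests$p_value <= alpha]
  }
  bilateral <- params$side %in% c("left", "right")
  poolable <- bilateral & !(params$parameter %in% sig)
  keys <- intersect(c("subject_id", "group", "parameter"), names(params))
  pooled <- params[poolable, ] %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(side = "pooled", value = mean(.data$value),
                     n_cycles = if ("n_cycles" %in% names(params))
                       sum(.data$n_cycles) else NA_integer_,
                     .groups = "drop")
  dplyr::bind_rows(params[!poolable, ], pooled) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "side"))))
}
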