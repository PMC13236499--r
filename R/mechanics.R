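#' Positive work of an energy curve
#'
#' Sum of the positive increments of an energy time series over consecutive
#' samples -- the standard measure of the positive "work" performed on the
#' centre of mass within a step.
#'
#' @param e Energy series (J), at least 2 samples.
#' @return Positive-increment sum (J), non-negative.
#' @export
#' @examples
#' positive_work(c(0, 1, 0, 1))  # 2
positive_work <- function(e) {
  if (length(e) < 2) abort("Need at least 2 samples to compute positive work.")
  sum(pmax(diff(e), 0))
}

#' Energy Recovery Index
#'
#' `ERI = 100 (W_P + W_K - W_TOT) / (W_P + W_K)`: the percentage of the
#' combined potential and kinetic energy fluctuations recovered through
#' their out-of-phase exchange. 100% corresponds to a perfect inverted
#' pendulum (exactly anti-phase, equal-amplitude curves), 0% to fully
#' in-phase curves with no exchange.
#'
#' @param w_p,w_k,w_tot Positive works of the potential, kinetic and total
#'   energy curves (same units; all non-negative).
#' @return ERI in percent.
#' @export
energy_recovery <- function(w_p, w_k, w_tot) {
  if (any(w_p < 0 | w_k < 0 | w_tot < 0)) {
    abort("Positive works must be non-negative.")
  }
  denom <- w_p + w_k
  if (any(denom <= 0)) {
    abort("Undefined ERI: w_p + w_k must be positive (step rejected).")
  }
  100 * (w_p + w_k - w_tot) / denom
}

#' Congruity of potential and kinetic energy
#'
#' Percentage of the step during which potential and kinetic energy change
#' in the same direction, i.e. the fraction of sample intervals with a
#' positive product of the two rates of change (computed with the same
#' first-order difference scheme as the CoM velocities). High congruity
#' means in-phase energy curves and poor pendulum-like exchange; the raw
#' integrated derivative product is attached as attribute `"raw_product"`
#' for diagnostics.
#'
#' @param e_p,e_k Equal-length potential and kinetic energy series (J),
#'   at least 3 samples, not constant.
#' @param sample_rate Sampling rate (Hz).
#' @return Congruity in percent.
#' @export
congruity <- function(e_p, e_k, sample_rate) {
  if (length(e_p) != length(e_k)) abort("`e_p` and `e_k` must have equal length.")
  if (length(e_p) < 3) abort("Need at least 3 samples for congruity.")
  if (max(e_p) - min(e_p) < .Machine$double.eps * 100 ||
      max(e_k) - min(e_k) < .Machine$double.eps * 100) {
    abort("Undefined congruity: constant energy series.")
  }
  dp <- diff(e_p) * sample_rate
  dk <- diff(e_k) * sample_rate
  out <- 100 * mean(dp * dk > 0)
  attr(out, "raw_product") <- sum(dp * dk) / sample_rate
  out
}

#' Per-step mechanical work, recovery and congruity
#'
#' Segments the trial into steps (heel strike to contralateral heel strike),
#' and for each step computes the positive works of the potential, kinetic
#' and total CoM energy on the raw-time curves, mass-normalized to J/kg,
#' together with the Energy Recovery Index and congruity. Steps with
#' implausible durations (outside `config$step_duration_range`), steps
#' overlapping unfilled marker gaps, and steps on which ERI is undefined are
#' rejected.
#'
#' @param recording A [gait_recording()] with anthropometrics (mass).
#' @param events A [gait_events()] for the trial.
#' @param config A [gait_config()].
#' @return Tibble with one row per retained step: `step_index`, `side`,
#'   `t_start`, `duration`, `w_p`, `w_k`, `w_tot` (J/kg), `eri_pct`,
#'   `congruity_pct`. Rejected steps are counted in attribute
#'   `"n_rejected"`; the energy series is attached as attribute `"energies"`.
#' @export
step_mechanics <- function(recording, events, config = gait_config()) {
  if (is.null(recording$anthropometrics)) {
    abort("Recording has no anthropometrics; body mass is required.")
  }
  mass <- recording$anthropometrics$mass
  com <- com_trajectory(recording, config)
  en <- com_energies(com, mass, config)
  steps <- segment_steps(events)
  t <- en$time
  invalid <- attr(recording, "invalid_frames") %||% integer(0)
  rows <- list()
  n_rejected <- 0L
  for (i in seq_len(nrow(steps))) {
    idx <- which(t >= steps$t_start[i] - 1e-9 & t <= steps$t_end[i] + 1e-9)
    dur <- steps$duration[i]
    if (length(idx) < 3 ||
        dur < config$step_duration_range[1] ||
        dur > config$step_duration_range[2] ||
        any(idx %in% invalid)) {
      n_rejected <- n_rejected + 1L
      next
    }
    w_p <- positive_work(en$e_p[idx])
    w_k <- positive_work(en$e_k[idx])
    w_tot <- positive_work(en$e_tot[idx])
    if (w_p + w_k <= 0) { n_rejected <- n_rejected + 1L; next }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      step_index = steps$step_index[i],
      side = steps$side[i],
      t_start = steps$t_start[i],
      duration = dur,
      w_p = w_p / mass, w_k = w_k / mass, w_tot = w_tot / mass,
      eri_pct = energy_recovery(w_p, w_k, w_tot),
      congruity_pct = as.numeric(congruity(en$e_p[idx], en$e_k[idx],
                                           recording$sample_rate))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_rejected") <- n_rejected
  attr(out, "energies") <- en
  out
}

#' Subject-level summary of step mechanics
#'
#' Averages per-step mechanics across all valid steps (of one or more
#' trials) to a representative value per subject.
#'
#' @param steps Per-step table from [step_mechanics()] (rows from several
#'   trials may be bound together).
#' @return One-row tibble: mean `w_p`, `w_k`, `w_tot` (J/kg), `eri_pct`,
#'   `congruity_pct`, and `n_steps`.
#' @export
summarize_mechanics <- function(steps) {
  if (!is.data.frame(steps) || nrow(steps) == 0) {
    abort("No valid steps to summarize.")
  }
  tibble::tibble(
    w_p = mean(steps$w_p), w_k = mean(steps$w_k), w_tot = mean(steps$w_tot),
    eri_pct = mean(steps$eri_pct), congruity_pct = mean(steps$congruity_pct),
    n_steps = nrow(steps)
  )
}

#' Ensemble of time-normalized per-step energy curves
#'
#' Interpolates the potential, kinetic and total energy of each step onto
#' the 0--100% step grid, for ensemble averaging and plotting.
#'
#' @param energies Energy table from [com_energies()] (or the `"energies"`
#'   attribute of [step_mechanics()]).
#' @param steps Step intervals from [segment_steps()].
#' @param config A [gait_config()].
#' @return Long tibble: `step_index`, `pct`, `e_p`, `e_k`, `e_tot`.
#' @export
normalized_energy_curves <- function(energies, steps, config = gait_config()) {
  purrr::map_dfr(seq_len(nrow(steps)), function(i) {
    grids <- lapply(c("e_p", "e_k", "e_tot"), function(cc) {
      time_normalize(energies$time, energies[[cc]],
                     steps$t_start[i], steps$t_end[i], config)$value
    })
    tibble::tibble(
      step_index = steps$step_index[i],
      pct = seq(0, 100, length.out = config$normalized_samples_per_step),
      e_p = grids[[1]], e_k = grids[[2]], e_tot = grids[[3]]
    )
  })
}
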