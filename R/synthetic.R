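#' Closed-form phase and recovery for two-sinusoid energy curves
#'
#' For potential and kinetic energy curves that are single sinusoids of
#' amplitudes `amp_p`, `amp_k` and relative phase `phase` over an integer
#' number of cycles, the positive works are `2 amp_p` and `2 amp_k` per
#' cycle and the total-energy work is `2 R` with
#' `R = sqrt(amp_p^2 + amp_k^2 + 2 amp_p amp_k cos(phase))`, so
#' `ERI = 100 (1 - R / (amp_p + amp_k))` and, for equal-frequency
#' sinusoids, congruity is `100 (1 - phase/pi)`. These closed forms serve
#' as independent oracles for the discrete positive-increment pipeline.
#'
#' @param amp_p,amp_k Sinusoid amplitudes (>= 0, same units).
#' @param phase Relative phase in radians, in `[0, pi]`.
#' @return List with `eri` and `congruity` (percent; congruity is `NA` when
#'   either amplitude is zero).
#' @export
#' @examples
#' sinusoid_exchange(1, 1, pi)$eri       # 100
#' sinusoid_exchange(1, 1, pi / 2)$eri   # 100 * (1 - cos(pi/4))
sinusoid_exchange <- function(amp_p, amp_k, phase) {
  stopifnot(amp_p >= 0, amp_k >= 0, phase >= 0, phase <= pi)
  if (amp_p + amp_k == 0) abort("At least one amplitude must be positive.")
  r <- sqrt(amp_p^2 + amp_k^2 + 2 * amp_p * amp_k * cos(phase))
  list(eri = 100 * (1 - r / (amp_p + amp_k)),
       congruity = if (amp_p > 0 && amp_k > 0) 100 * (1 - phase / pi) else NA_real_)
}

# Phase that yields a target ERI for given per-step positive works (J/kg).
# Sinusoid amplitudes are half the per-cycle positive works. The achievable
# maximum is 100 (1 - |amp_p - amp_k| / (amp_p + amp_k)); targets beyond it
# clip to anti-phase.
phase_for_eri <- function(w_p, w_k, eri_pct) {
  amp_p <- w_p / 2; amp_k <- w_k / 2
  r <- (1 - eri_pct / 100) * (amp_p + amp_k)
  cphi <- (r^2 - amp_p^2 - amp_k^2) / (2 * amp_p * amp_k)
  acos(pmin(1, pmax(-1, cphi)))
}

#' Synthetic analytic energy curves
#'
#' Generates idealized potential and kinetic energy sinusoids with a
#' controlled phase offset, offset so the kinetic energy stays non-negative,
#' with closed-form ground-truth recovery and congruity attached. Used as
#' an oracle for the positive-increment work pipeline: exactly anti-phase
#' equal-amplitude curves give 100% recovery (the perfect inverted
#' pendulum), exactly in-phase curves give 0%.
#'
#' @param phase Phase offset between the two curves, radians in `[0, pi]`.
#' @param amp_p,amp_k Amplitudes (J), non-negative.
#' @param n_cycles Number of full cycles (>= 1).
#' @param samples_per_cycle Samples per cycle (default 1000).
#' @param period Cycle period in seconds (default 1).
#' @return Tibble `time`, `e_p`, `e_k`, `e_tot` with attributes
#'   `eri_true`, `congruity_true`, `sample_rate`.
#' @export
make_energy_curves <- function(phase, amp_p = 1, amp_k = 1, n_cycles = 1,
                               samples_per_cycle = 1000, period = 1) {
  stopifnot(n_cycles >= 1, samples_per_cycle >= 8, period > 0)
  n <- n_cycles * samples_per_cycle
  t <- seq(0, n_cycles * period, length.out = n + 1)
  w <- 2 * pi / period
  e_p <- amp_p * sin(w * t) + amp_p
  e_k <- amp_k * sin(w * t + phase) + amp_k
  out <- tibble::tibble(time = t, e_p = e_p, e_k = e_k, e_tot = e_p + e_k)
  gt <- sinusoid_exchange(amp_p, amp_k, phase)
  attr(out, "eri_true") <- gt$eri
  attr(out, "congruity_true") <- gt$congruity
  attr(out, "sample_rate") <- samples_per_cycle / period
  out
}

#' Cohort specification for the synthetic gait generator
#'
#' Describes the distribution a synthetic cohort is drawn from. Defaults are
#' provided by [healthy_cohort_spec()] and [stroke_cohort_spec()], anchored
#' to published group means and standard deviations for self-selected
#' walking in healthy adults and chronic hemiparetic (stroke) gait. The
#' `severity_loading` parameter makes subject-level draws share a latent
#' severity factor, which induces the clinically observed covariation of
#' speed, step length, double support, foot-off timing and energy recovery.
#'
#' @param n_subjects Number of subjects.
#' @param label Group label (`"healthy"` or `"stroke"`).
#' @param speed_mean,speed_sd Walking speed (m/s).
#' @param stride_length_mean,stride_length_sd Stride length (m).
#' @param w_p_mean,w_p_sd,w_k_mean,w_k_sd Per-step positive works (J/kg);
#'   these set the vertical CoM excursion (`a = w_p / g`) and the forward
#'   velocity fluctuation (`dv = w_k / (2 speed)`).
#' @param eri_mean,eri_sd Target Energy Recovery Index (%); the phase offset
#'   between potential and kinetic energy is solved per subject from the
#'   target and the drawn works.
#' @param foot_off_first_mean,foot_off_first_sd Stance fraction of the
#'   (plegic) first side, as a fraction of the gait cycle.
#' @param foot_off_second_mean,foot_off_second_sd Stance fraction of the
#'   (non-plegic) second side.
#' @param asymmetry_ratio Plegic / non-plegic step-time ratio (1 = symmetric).
#' @param mass_mean,mass_sd Body mass (kg).
#' @param leg_length_mean,leg_length_sd Leg length (m).
#' @param ml_sway_amplitude Medio-lateral CoM sway amplitude (m), at stride
#'   frequency.
#' @param marker_noise_sd Additive Gaussian marker noise (m).
#' @param severity_loading Loading in `[0, 1)` of the shared severity factor.
#' @param n_steps Steps generated per trial.
#' @param sample_rate Sampling rate (Hz).
#' @return A `cohort_spec` object (named list).
#' @export
cohort_spec <- function(n_subjects = 30,
                        label = "healthy",
                        speed_mean = 1.42, speed_sd = 0.23,
                        stride_length_mean = 1.43, stride_length_sd = 0.16,
                        w_p_mean = 0.43, w_p_sd = 0.12,
                        w_k_mean = 0.51, w_k_sd = 0.14,
                        eri_mean = 68.08, eri_sd = 4.61,
                        foot_off_first_mean = 0.598, foot_off_first_sd = 0.014,
                        foot_off_second_mean = 0.598, foot_off_second_sd = 0.014,
                        asymmetry_ratio = 1,
                        mass_mean = 65.67, mass_sd = 9.59,
                        leg_length_mean = 0.846, leg_length_sd = 0.035,
                        ml_sway_amplitude = 0.02,
                        marker_noise_sd = 0.001,
                        severity_loading = 0,
                        n_steps = 12,
                        sample_rate = 100) {
  spec <- as.list(environment())
  stopifnot(n_subjects >= 1, speed_sd >= 0, stride_length_sd >= 0,
            asymmetry_ratio > 0, marker_noise_sd >= 0,
            severity_loading >= 0, severity_loading < 1,
            n_steps >= 2, sample_rate > 0)
  ratio <- stride_length_mean / speed_mean
  if (ratio < 0.5 || ratio > 3) {
    abort("Inconsistent spec: implied stride time outside [0.5, 3] s.")
  }
  structure(spec, class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
healthy_cohort_spec <- function(n_subjects = 30, ...) {
  cohort_spec(n_subjects = n_subjects, label = "healthy", ...)
}

#' Stroke-like cohort: slower, shorter steps, prolonged double support,
#' asymmetric step timing and more in-phase energy curves.
#' @rdname cohort_spec
#' @export
stroke_cohort_spec <- function(n_subjects = 30, ...) {
  defaults <- list(
    n_subjects = n_subjects, label = "stroke",
    speed_mean = 0.56, speed_sd = 0.23,
    stride_length_mean = 0.78, stride_length_sd = 0.21,
    w_p_mean = 0.21, w_p_sd = 0.09,
    w_k_mean = 0.14, w_k_sd = 0.09,
    eri_mean = 54.44, eri_sd = 12.66,
    foot_off_first_mean = 0.613, foot_off_first_sd = 0.034,
    foot_off_second_mean = 0.7105, foot_off_second_sd = 0.0666,
    asymmetry_ratio = 0.85 / 0.68,
    mass_mean = 84.37, mass_sd = 12.01,
    leg_length_mean = 0.811, leg_length_sd = 0.069,
    ml_sway_amplitude = 0.03,
    severity_loading = 0.8)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Noiseless per-step mechanics of the generator's CoM model, evaluated the
# way the measurement chain defines the quantities: positions sampled at the
# recording rate, velocities by first-order forward differences, works as
# sums of positive increments. (Kinetic energy is *defined* through finite
# differences of the sampled displacements, so the discrete scheme belongs
# to the ground truth, not to the implementation.) Vertical position is one
# cosine arch per step with minima at heel strikes; forward velocity
# fluctuates at step frequency, offset by `phase` against the vertical
# oscillation; lateral sway is a sinusoid at stride frequency. Works are
# per unit mass (J/kg), averaged across the steps of `n_strides` strides.
stride_model_mechanics <- function(p, phase, g = 9.81, sr = 100,
                                   n_strides = 4L) {
  a_v <- p$w_p / g
  dv <- min(p$w_k / (2 * p$ssws), 0.6 * p$ssws)
  phi0 <- -pi / 2 + phase
  durs <- rep(c(p$step_time_first, p$step_time_second), n_strides + 1L)
  grid <- c(0, cumsum(durs))
  t <- seq(0, grid[length(grid)], by = 1 / sr)
  seg <- pmin(findInterval(t, grid, rightmost.closed = TRUE), length(durs))
  u <- (t - grid[seg]) / durs[seg]
  h <- a_v * (1 - cos(2 * pi * u)) / 2
  x_strike <- c(0, cumsum(p$ssws * durs))
  x <- x_strike[seg] + p$ssws * (t - grid[seg]) -
    dv * durs[seg] / (2 * pi) * (cos(2 * pi * u + phi0) - cos(phi0))
  ml <- p$ml_sway * sin(pi * (seg + u))
  fd <- function(z) { v <- diff(z) * sr; c(v, v[length(v)]) }
  e_p <- g * h
  e_k <- 0.5 * (fd(x)^2 + fd(h)^2 + fd(ml)^2)
  pw <- function(z) sum(pmax(diff(z), 0))
  # analyse the interior steps only (skip first and last)
  steps <- 2:(length(grid) - 2L)
  per_step <- t(vapply(steps, function(k) {
    idx <- which(t >= grid[k] - 1e-12 & t <= grid[k + 1L] + 1e-12)
    w_p <- pw(e_p[idx]); w_k <- pw(e_k[idx]); w_tot <- pw(e_p[idx] + e_k[idx])
    dpk <- diff(e_p[idx]) * diff(e_k[idx])
    c(w_p = w_p, w_k = w_k, w_tot = w_tot,
      eri = 100 * (w_p + w_k - w_tot) / (w_p + w_k),
      congruity = 100 * mean(dpk > 0))
  }, numeric(5)))
  as.list(colMeans(per_step))
}

# Energy phase that makes the full kinematic model reach a target recovery.
# ERI increases monotonically with the phase offset; targets beyond the
# model's achievable range clip to the nearest endpoint.
solve_phase <- function(p, eri_target) {
  f <- function(phi) stride_model_mechanics(p, phi)$eri - eri_target
  lo <- f(0); hi <- f(pi)
  if (hi <= 0) return(pi)
  if (lo >= 0) return(0)
  stats::uniroot(f, c(0, pi), tol = 1e-4)$root
}

# Draw one subject's parameters. `z` is the shared severity factor;
# variables marked sign = -1 decrease with severity (speed, stride, works,
# recovery), sign = +1 increase (stance fractions).
draw_subject_params <- function(spec, z) {
  lam <- spec$severity_loading
  mix <- function(mean, sd, sign) {
    mean + sign * sd * (lam * z + sqrt(1 - lam^2) * rnorm(1))
  }
  ssws <- clip(mix(spec$speed_mean, spec$speed_sd, -1), 0.2, 2.2)
  stride <- clip(mix(spec$stride_length_mean, spec$stride_length_sd, -1), 0.35, 2.2)
  stride_time <- clip(stride / ssws, 0.7, 2.6)
  stride <- ssws * stride_time
  w_p <- clip(mix(spec$w_p_mean, spec$w_p_sd, -1), 0.05, 1.2)
  w_k <- clip(mix(spec$w_k_mean, spec$w_k_sd, -1), 0.04, 1.2)
  eri_target <- clip(mix(spec$eri_mean, spec$eri_sd, -1), 8, 92)
  r <- spec$asymmetry_ratio
  step_first <- stride_time * r / (1 + r)    # plegic (or left) step time
  step_second <- stride_time / (1 + r)
  f1 <- clip(mix(spec$foot_off_first_mean, spec$foot_off_first_sd, +1), 0.52, 0.88)
  f2 <- clip(mix(spec$foot_off_second_mean, spec$foot_off_second_sd, +1), 0.52, 0.90)
  # each stance must outlast the contralateral strike within the cycle
  f1 <- max(f1, step_second / stride_time + 0.04)
  f2 <- max(f2, step_first / stride_time + 0.04)
  mass <- clip(rnorm(1, spec$mass_mean, spec$mass_sd), 40, 140)
  leg <- clip(rnorm(1, spec$leg_length_mean, spec$leg_length_sd), 0.6, 1.1)
  p <- list(ssws = ssws, stride_length = stride, stride_time = stride_time,
            w_p = w_p, w_k = w_k,
            step_time_first = step_first, step_time_second = step_second,
            foot_off_first = f1, foot_off_second = f2,
            mass = mass, leg_length = leg,
            ml_sway = spec$ml_sway_amplitude)
  # solve the energy phase against the full CoM kinematic model (including
  # the vertical and lateral kinetic-energy components) so the drawn target
  # is the subject's true recovery, not a two-sinusoid approximation
  p$phase <- solve_phase(p, eri_target)
  gt <- stride_model_mechanics(p, p$phase)
  p$eri <- gt$eri
  p$congruity <- gt$congruity
  p$w_p_true <- gt$w_p
  p$w_k_true <- gt$w_k
  p
}

#' Generate one synthetic walking trial
#'
#' Builds Plug-In-Gait-style pelvic and foot marker trajectories whose
#' downstream analysis has known ground truth. The pelvic markers ride a
#' centre-of-mass path with constant mean forward speed, a vertical
#' sinusoid per step (minima at heel strikes) and lateral sway at stride
#' frequency; the forward-velocity fluctuation is phase-shifted against the
#' vertical oscillation by the subject's solved energy phase, so the
#' kinetic-energy timing is imposed through the marker kinematics rather
#' than written into energies directly. Feet are stationary during stance
#' and advance linearly during swing, producing heel-strike and toe-off
#' events at prescribed times. Gaussian noise is added to every marker
#' coordinate.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Index within the cohort (used for the subject id).
#' @param severity Optional severity factor `z`; drawn `N(0,1)` if `NULL`.
#' @return List with `recording` (a [gait_recording()]) and `truth` (a
#'   one-row tibble of ground-truth parameters).
#' @export
make_walking_trial <- function(spec, subject_index = 1, severity = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  z <- severity %||% rnorm(1)
  p <- draw_subject_params(spec, z)
  stroke <- identical(spec$label, "stroke")
  plegic <- if (stroke) sample(c("left", "right"), 1) else "none"
  # "first" side carries the plegic timing; map it onto left/right
  first_side <- if (stroke) plegic else "left"
  second_side <- if (first_side == "left") "right" else "left"

  sr <- spec$sample_rate
  pad <- 0.9
  T_str <- p$stride_time
  n_strikes <- spec$n_steps + 1L
  # strike sequence: first_side strikes first at t = pad; the interval
  # preceding a side's strike is that side's step time
  sides <- rep(c(first_side, second_side), length.out = n_strikes + 1L)
  step_of <- function(s) if (s == first_side) p$step_time_first else p$step_time_second
  strikes <- pad + c(0, cumsum(vapply(sides[2:n_strikes], step_of, numeric(1))))
  dur <- strikes[n_strikes] + pad
  nfr <- floor(dur * sr) + 1L
  t <- (seq_len(nfr) - 1L) / sr

  # merged strike grid with one phantom strike on each side of the trial so
  # the per-step CoM formulas are defined over the whole padded record
  grid <- c(strikes[1] - step_of(sides[1]), strikes,
            strikes[n_strikes] + step_of(sides[n_strikes + 1L]))
  grid_sides <- c(second_side, sides)
  seg <- findInterval(t, grid, rightmost.closed = TRUE)
  seg <- clip(seg, 1L, length(grid) - 1L)
  d_i <- diff(grid)
  u <- (t - grid[seg]) / d_i[seg]

  a_v <- p$w_p / 9.81                       # vertical excursion per step
  dv <- min(p$w_k / (2 * p$ssws), 0.6 * p$ssws)
  h0 <- p$leg_length + 0.08
  h <- h0 + a_v * (1 - cos(2 * pi * u)) / 2
  phi0 <- -pi / 2 + p$phase
  # forward position: closed-form integral of v = ssws + dv sin(2 pi u + phi0)
  x_at_strike <- c(0, cumsum(p$ssws * d_i))
  x_ap <- x_at_strike[seg] + p$ssws * (t - grid[seg]) -
    dv * d_i[seg] / (2 * pi) * (cos(2 * pi * u + phi0) - cos(phi0))
  ml <- spec$ml_sway_amplitude * sin(pi * (seg + u))

  # feet: per-side strike times and landing positions on the pelvis mean line
  all_strike_t <- grid
  all_strike_side <- grid_sides
  foot <- list()
  for (s in c("left", "right")) {
    st <- all_strike_t[all_strike_side == s]
    st <- c(st[1] - T_str, st, st[length(st)] + T_str)
    land <- p$ssws * st + 0.12
    f_s <- if (s == first_side) p$foot_off_first else p$foot_off_second
    xs <- numeric(nfr); zs <- numeric(nfr)
    k <- findInterval(t, st, rightmost.closed = TRUE)
    k <- clip(k, 1L, length(st) - 1L)
    cyc <- st[k + 1L] - st[k]
    uc <- (t - st[k]) / cyc
    stance <- uc <= f_s
    xs[stance] <- land[k[stance]]
    usw <- (uc - f_s) / (1 - f_s)
    xs[!stance] <- land[k[!stance]] +
      (land[k[!stance] + 1L] - land[k[!stance]]) * usw[!stance]
    zs <- ifelse(stance, 0.02, 0.02 + 0.06 * sin(pi * clip(usw, 0, 1)))
    foot[[s]] <- list(x = xs, z = zs)
  }

  asis <- 0.24
  noise <- function() rnorm(nfr, 0, spec$marker_noise_sd)
  col3 <- function(x, y, z) list(x = x + noise(), y = y + noise(), z = z + noise())
  mk <- list(
    LASI = col3(x_ap + 0.11, ml + asis / 2, h - 0.02),
    RASI = col3(x_ap + 0.11, ml - asis / 2, h - 0.02),
    LPSI = col3(x_ap - 0.12, ml + 0.05, h + 0.03),
    RPSI = col3(x_ap - 0.12, ml - 0.05, h + 0.03),
    LHEE = col3(foot$left$x, ml * 0 + 0.10, foot$left$z),
    RHEE = col3(foot$right$x, ml * 0 - 0.10, foot$right$z),
    LTOE = col3(foot$left$x + 0.16, ml * 0 + 0.10, foot$left$z),
    RTOE = col3(foot$right$x + 0.16, ml * 0 - 0.10, foot$right$z)
  )
  dat <- tibble::as_tibble(
    setNames(unlist(lapply(names(mk), function(nmk) {
      setNames(mk[[nmk]], paste0(nmk, "_", c("x", "y", "z")))
    }), recursive = FALSE),
    unlist(lapply(names(mk), function(nmk) paste0(nmk, "_", c("x", "y", "z"))))))

  sid <- sprintf("%s%02d", if (stroke) "S" else "H", subject_index)
  rec <- gait_recording(dat, sample_rate = sr, subject_id = sid,
                        anthropometrics = anthropometrics(
                          mass = p$mass, leg_length = p$leg_length),
                        group = spec$label, plegic_side = plegic)

  # ground truth lists the nominal strikes only; the padded edges contain one
  # further (detectable but truncated) contact on each side of the trial
  nominal_t <- strikes
  nominal_side <- sides[seq_len(n_strikes)]
  hs_true <- list(left = nominal_t[nominal_side == "left"],
                  right = nominal_t[nominal_side == "right"])
  to_true <- list()
  for (s in c("left", "right")) {
    st <- nominal_t[nominal_side == s]
    f_s <- if (s == first_side) p$foot_off_first else p$foot_off_second
    to <- st + f_s * T_str
    to_true[[s]] <- to[to < dur - 0.3]
  }

  f_first <- p$foot_off_first; f_second <- p$foot_off_second
  truth <- tibble::tibble(
    subject_id = sid, group = spec$label, plegic_side = plegic,
    severity = z,
    ssws = p$ssws, stride_length = p$stride_length,
    stride_time = p$stride_time, cadence = 120 / p$stride_time,
    step_time_plegic = p$step_time_first,
    step_time_nonplegic = p$step_time_second,
    step_length_plegic = p$ssws * p$step_time_first,
    step_length_nonplegic = p$ssws * p$step_time_second,
    double_support = (f_first + f_second - 1) * p$stride_time,
    foot_off_plegic = 100 * f_first,
    foot_off_nonplegic = 100 * f_second,
    w_p = p$w_p_true, w_k = p$w_k_true, phase = p$phase,
    eri = p$eri, congruity = p$congruity,
    mass = p$mass, leg_length = p$leg_length,
    n_steps = spec$n_steps
  )
  list(recording = rec, truth = truth,
       events_true = gait_events(hs_true, to_true, validate = FALSE))
}

#' Generate a reproducible two-group synthetic cohort
#'
#' Draws `spec_healthy$n_subjects + spec_stroke$n_subjects` subjects, one
#' trial each, with a fixed per-subject seed derived from `seed`, and
#' returns the trials together with a manifest of every ground-truth
#' parameter.
#'
#' @param spec_healthy,spec_stroke [cohort_spec()] objects for the two
#'   groups (defaults: [healthy_cohort_spec()], [stroke_cohort_spec()]).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `trials` (named list of [gait_recording()]), `truth`
#'   (manifest tibble, one row per subject) and `events_true` (named list).
#' @export
make_cohort <- function(spec_healthy = healthy_cohort_spec(),
                        spec_stroke = stroke_cohort_spec(),
                        seed = 1L) {
  trials <- list(); truths <- list(); events <- list()
  specs <- list(spec_healthy, spec_stroke)
  offsets <- c(0L, 100000L)
  for (gi in 1:2) {
    spec <- specs[[gi]]
    for (i in seq_len(spec$n_subjects)) {
      set.seed(seed + offsets[gi] + i)
      tr <- make_walking_trial(spec, subject_index = i)
      sid <- tr$truth$subject_id
      trials[[sid]] <- tr$recording
      truths[[sid]] <- tr$truth
      events[[sid]] <- tr$events_true
    }
  }
  list(trials = trials, truth = dplyr::bind_rows(truths), events_true = events)
}
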