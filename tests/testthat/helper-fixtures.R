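# Minimal straight-line walk: every marker translates at constant speed
# along +x, so event times and distances are exact by construction.
straight_walk_recording <- function(speed = 1.4, duration = 2, sr = 100,
                                    mass = 70, leg_length = 0.85) {
  t <- seq(0, duration, by = 1 / sr)
  x <- speed * t
  mk <- function(dx, dy, dz) {
    list(x = x + dx, y = rep(dy, length(t)), z = rep(dz, length(t)))
  }
  specs <- list(
    LASI = mk(0.11, 0.12, 0.93), RASI = mk(0.11, -0.12, 0.93),
    LPSI = mk(-0.12, 0.05, 0.98), RPSI = mk(-0.12, -0.05, 0.98),
    LHEE = mk(0, 0.1, 0.02), RHEE = mk(0, -0.1, 0.02),
    LTOE = mk(0.16, 0.1, 0.02), RTOE = mk(0.16, -0.1, 0.02)
  )
  cols <- list()
  for (nm in names(specs)) {
    cols[[paste0(nm, "_x")]] <- specs[[nm]]$x
    cols[[paste0(nm, "_y")]] <- specs[[nm]]$y
    cols[[paste0(nm, "_z")]] <- specs[[nm]]$z
  }
  gait_recording(tibble::as_tibble(cols), sample_rate = sr,
                 subject_id = "fix01",
                 anthropometrics = anthropometrics(mass = mass,
                                                   leg_length = leg_length))
}

# Match each reference event to the nearest candidate; returns the absolute
# differences (NA where no candidate lies within `window`).
match_events <- function(reference, detected, window = 0.25) {
  vapply(reference, function(r) {
    d <- abs(detected - r)
    if (length(d) == 0 || min(d) > window) NA_real_ else min(d)
  }, numeric(1))
}

# Small noiseless-or-not single trial for event / mechanics tests.
quick_trial <- function(spec, seed = 42, ...) {
  set.seed(seed)
  make_walking_trial(spec, 1, ...)
}
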