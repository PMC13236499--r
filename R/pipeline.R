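#' Process all trials of one subject
#'
#' Runs the full per-subject chain: gap filling, event detection,
#' spatio-temporal parameters, CoM mechanics, and the speed indices, then
#' averages across all valid steps of all trials.
#'
#' @param trials A [gait_recording()] or a list of them (one per walking
#'   trial of the same subject).
#' @param config A [gait_config()].
#' @return List of class `subject_result` with elements `summary` (one-row
#'   tibble), `spatiotemporal` (tidy parameter table) and `steps` (per-step
#'   mechanics).
#' @export
run_subject <- function(trials, config = gait_config()) {
  if (inherits(trials, "gait_recording")) trials <- list(trials)
  if (length(trials) == 0) abort("No trials supplied.")
  rec1 <- trials[[1]]
  st_all <- list(); steps_all <- list()
  for (ti in seq_along(trials)) {
    rec <- fill_marker_gaps(trials[[ti]], config$max_gap_frames)
    ev <- detect_gait_events(rec, config)
    st <- compute_spatiotemporal(ev, rec)
    st$trial <- ti
    st_all[[ti]] <- st
    steps <- step_mechanics(rec, ev, config)
    if (nrow(steps)) { steps$trial <- ti; steps_all[[ti]] <- steps }
  }
  st <- dplyr::bind_rows(st_all) %>%
    dplyr::group_by(.data$parameter, .data$side) %>%
    dplyr::summarise(value = stats::weighted.mean(.data$value, .data$n_cycles),
                     n_cycles = sum(.data$n_cycles), .groups = "drop")
  steps <- dplyr::bind_rows(steps_all)
  if (nrow(steps) == 0) abort(paste0("Subject ", rec1$subject_id,
                                     ": no valid steps after rejection."))
  mech <- summarize_mechanics(steps)

  pick <- function(parameter, side = NULL) {
    sel <- st$parameter == parameter
    if (!is.null(side)) sel <- sel & st$side == side
    v <- st$value[sel]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  leg <- rec1$anthropometrics$leg_length %||% NA_real_
  ows <- if (is.finite(leg)) optimal_walking_speed(leg, config) else NA_real_
  ssws <- pick("ssws")
  summary <- tibble::tibble(
    subject_id = rec1$subject_id, group = rec1$group,
    plegic_side = rec1$plegic_side,
    mass = rec1$anthropometrics$mass, leg_length = leg,
    ssws = ssws, cadence = pick("cadence"),
    double_support = pick("double_support"),
    stride_time = pick("stride_time"), stride_length = pick("stride_length"),
    step_time_left = pick("step_time", "left"),
    step_time_right = pick("step_time", "right"),
    step_length_left = pick("step_length", "left"),
    step_length_right = pick("step_length", "right"),
    foot_off_left = pick("foot_off", "left"),
    foot_off_right = pick("foot_off", "right"),
    w_p = mech$w_p, w_k = mech$w_k, w_tot = mech$w_tot,
    eri_pct = mech$eri_pct, congruity_pct = mech$congruity_pct,
    ows = ows,
    lri = if (is.finite(ows)) locomotor_rehab_index(ssws, ows) else NA_real_,
    n_steps = mech$n_steps, n_trials = length(trials)
  )
  structure(list(summary = summary, spatiotemporal = st, steps = steps),
            class = "subject_result")
}

# Map left/right columns onto plegic/non-plegic roles. For subjects without
# an affected side the left limb is (arbitrarily) taken as "plegic" so that
# pooled statistics remain defined.
side_roles <- function(subjects) {
  pl <- ifelse(subjects$plegic_side == "right", "right", "left")
  npl <- ifelse(pl == "left", "right", "left")
  get2 <- function(base, side) {
    ifelse(side == "left", subjects[[paste0(base, "_left")]],
           subjects[[paste0(base, "_right")]])
  }
  subjects %>%
    dplyr::mutate(
      step_time_plegic = get2("step_time", pl),
      step_time_nonplegic = get2("step_time", npl),
      step_length_plegic = get2("step_length", pl),
      step_length_nonplegic = get2("step_length", npl),
      foot_off_plegic = get2("foot_off", pl),
      foot_off_nonplegic = get2("foot_off", npl)
    )
}

BILATERAL_PARAMS <- c("step_time", "step_length", "foot_off")

#' Run the full two-group study
#'
#' Processes every subject, performs the preliminary paired limb comparison
#' in the stroke group (bilateral parameters whose paired test is
#' non-significant are pooled across limbs), assembles the group-level
#' descriptive tables, the independent-group comparisons with Cohen's d,
#' the speed-adjusted ANCOVA for the Energy Recovery Index and congruity,
#' and the four ERI correlations within the stroke group (step length,
#' double support, non-plegic foot off, Locomotor Rehabilitation Index).
#'
#' @param trials Named list: one [gait_recording()] (or list of them) per
#'   subject.
#' @param config A [gait_config()].
#' @return A `gait_study` list: `subjects` (per-subject summary rows),
#'   `failed` (subject ids that could not be processed), `limb_tests`,
#'   `demographics`, `spatiotemporal`, `mechanics`, `speed_indices`
#'   (comparison tables), `ancova` (list per outcome), `correlations`, and
#'   `config`.
#' @export
run_study <- function(trials, config = gait_config()) {
  results <- list(); failed <- character(0)
  for (sid in names(trials)) {
    res <- tryCatch(run_subject(trials[[sid]], config), error = function(e) e)
    if (inherits(res, "error")) {
      warn(paste0("Subject ", sid, " excluded: ", conditionMessage(res)))
      failed <- c(failed, sid)
    } else {
      results[[sid]] <- res
    }
  }
  if (length(results) == 0) abort("No subject could be processed.")
  subjects <- side_roles(dplyr::bind_rows(lapply(results, `[[`, "summary")))

  sg <- subjects[subjects$group == "stroke", ]
  hg <- subjects[subjects$group == "healthy", ]
  two_groups <- nrow(sg) >= 2 && nrow(hg) >= 2
  if (!two_groups) {
    warn("Fewer than 2 subjects in a group: descriptives only.")
  }

  # preliminary paired limb tests in the stroke group
  limb_tests <- NULL
  pooled_for <- BILATERAL_PARAMS
  if (nrow(sg) >= 3) {
    limb_tests <- purrr::map_dfr(BILATERAL_PARAMS, function(pp) {
      ct <- paired_limb_test(sg[[paste0(pp, "_plegic")]],
                             sg[[paste0(pp, "_nonplegic")]])
      dplyr::mutate(ct, parameter = pp, .before = 1)
    })
    pooled_for <- limb_tests$parameter[limb_tests$p_value > config$pool_alpha]
  }
  pooled_col <- function(tb, base) {
    if (base %in% pooled_for) {
      (tb[[paste0(base, "_plegic")]] + tb[[paste0(base, "_nonplegic")]]) / 2
    } else NULL
  }

  compare_tbl <- function(vars) {
    purrr::map_dfr(names(vars), function(vn) {
      a <- sg[[vars[[vn]]]]; b <- hg[[vars[[vn]]]]
      if (two_groups && sd(c(a, b)) > 0) {
        ct <- independent_comparison(a, b)
        tibble::tibble(variable = vn,
                       stroke_mean = mean(a), stroke_sd = sd(a),
                       healthy_mean = mean(b), healthy_sd = sd(b),
                       t = ct$statistic, df = ct$df, p_value = ct$p_value,
                       d = ct$effect_size_d, d_band = ct$d_band)
      } else {
        all <- c(a, b)
        tibble::tibble(variable = vn, stroke_mean = mean(a), stroke_sd = sd(a),
                       healthy_mean = mean(b), healthy_sd = sd(b),
                       t = NA_real_, df = NA_real_, p_value = NA_real_,
                       d = NA_real_, d_band = NA_character_)
      }
    })
  }

  st_vars <- list(cadence = "cadence", double_support = "double_support",
                  stride_time = "stride_time", stride_length = "stride_length",
                  ssws = "ssws")
  for (bp in BILATERAL_PARAMS) {
    if (bp %in% pooled_for) {
      cn <- paste0(bp, "_pooled")
      sg[[cn]] <- pooled_col(sg, bp); hg[[cn]] <- pooled_col(hg, bp)
      st_vars[[bp]] <- cn
    } else {
      # healthy comparators are pooled across sides regardless (no affected
      # side); the stroke group keeps its sides separate
      cn <- paste0(bp, "_pooled")
      hg[[cn]] <- (hg[[paste0(bp, "_plegic")]] + hg[[paste0(bp, "_nonplegic")]]) / 2
      for (role in c("plegic", "nonplegic")) {
        sg[[paste0(bp, "_", role, "_cmp")]] <- sg[[paste0(bp, "_", role)]]
        hg[[paste0(bp, "_", role, "_cmp")]] <- hg[[cn]]
        st_vars[[paste0(bp, "_", role)]] <- paste0(bp, "_", role, "_cmp")
      }
    }
  }
  demographics <- compare_tbl(list(mass = "mass", leg_length = "leg_length"))
  spatiotemporal <- compare_tbl(st_vars)
  mechanics <- compare_tbl(list(w_p = "w_p", w_k = "w_k", w_tot = "w_tot",
                                eri = "eri_pct", congruity = "congruity_pct"))
  speed_indices <- compare_tbl(list(ows = "ows", lri = "lri"))

  ancova <- NULL
  if (two_groups && nrow(sg) >= 3 && nrow(hg) >= 3) {
    ancova <- list(
      eri = ancova_adjusted(subjects, "eri_pct", "group", "ssws"),
      congruity = ancova_adjusted(subjects, "congruity_pct", "group", "ssws"))
  }

  correlations <- NULL
  if (nrow(sg) >= 3) {
    sg_cor <- sg
    sg_cor$step_length_for_cor <- if ("step_length_pooled" %in% names(sg_cor) &&
                                      !is.null(sg_cor$step_length_pooled)) {
      sg_cor$step_length_pooled
    } else {
      (sg_cor$step_length_plegic + sg_cor$step_length_nonplegic) / 2
    }
    correlations <- dplyr::bind_rows(
      dplyr::mutate(correlate_pair(sg_cor, "eri_pct", "step_length_for_cor"),
                    pair = "eri vs step_length"),
      dplyr::mutate(correlate_pair(sg_cor, "eri_pct", "double_support"),
                    pair = "eri vs double_support"),
      dplyr::mutate(correlate_pair(sg_cor, "eri_pct", "foot_off_nonplegic"),
                    pair = "eri vs foot_off_nonplegic"),
      dplyr::mutate(correlate_pair(sg_cor, "eri_pct", "lri"),
                    pair = "eri vs lri"))
  }

  structure(list(
    subjects = subjects, failed = failed, limb_tests = limb_tests,
    pooled_parameters = pooled_for,
    demographics = demographics, spatiotemporal = spatiotemporal,
    mechanics = mechanics, speed_indices = speed_indices,
    ancova = ancova, correlations = correlations, config = config
  ), class = "gait_study")
}

#' @export
print.gait_study <- function(x, ...) {
  cat(sprintf("<gait_study> %d subjects (%d stroke, %d healthy), %d excluded\n",
              nrow(x$subjects), sum(x$subjects$group == "stroke"),
              sum(x$subjects$group == "healthy"), length(x$failed)))
  if (!is.null(x$mechanics)) {
    cat("Mechanics comparison:\n"); print(x$mechanics)
  }
  if (!is.null(x$correlations)) {
    cat("Stroke-group ERI correlations:\n"); print(x$correlations)
  }
  invisible(x)
}

#' Write a study report bundle as CSV tables
#'
#' Writes every table of a [run_study()] result plus the configuration used
#' to `dir`, with fixed float formatting and no timestamps, so re-running on
#' identical input yields byte-identical files.
#'
#' @param study A `gait_study` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df <- as.data.frame(df)
    for (cc in names(df)) {
      if (is.numeric(df[[cc]])) df[[cc]] <- formatC(df[[cc]], format = "g", digits = 10)
    }
    df
  }
  paths <- character(0)
  tables <- list(subjects = study$subjects, limb_tests = study$limb_tests,
                 demographics = study$demographics,
                 spatiotemporal = study$spatiotemporal,
                 mechanics = study$mechanics, speed_indices = study$speed_indices,
                 correlations = study$correlations)
  if (!is.null(study$ancova)) {
    tables$ancova <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(study$ancova$eri), outcome = "eri"),
      dplyr::mutate(tibble::as_tibble(study$ancova$congruity), outcome = "congruity"))
  }
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    pp <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(fmt(tables[[nm]]), pp, row.names = FALSE)
    paths <- c(paths, pp)
  }
  cfg <- study$config
  cfg_lines <- vapply(names(cfg), function(k) {
    sprintf("%s: %s", k, paste(format(cfg[[k]]), collapse = ","))
  }, character(1))
  cfg_path <- file.path(dir, "config.txt")
  writeLines(cfg_lines, cfg_path)
  invisible(c(paths, cfg_path))
}
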