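# Marker labels required by the downstream pipeline (Plug-In Gait names).
PELVIC_MARKERS <- c("LASI", "RASI", "LPSI", "RPSI")
FOOT_MARKERS <- c("LHEE", "RHEE", "LTOE", "RTOE")

# Common label dialects mapped to the canonical Plug-In Gait names.
DEFAULT_MARKER_ALIASES <- c(
  L_ASIS = "LASI", R_ASIS = "RASI", L_PSIS = "LPSI", R_PSIS = "RPSI",
  LASIS = "LASI", RASIS = "RASI", LPSIS = "LPSI", RPSIS = "RPSI",
  L_HEEL = "LHEE", R_HEEL = "RHEE", LHEEL = "LHEE", RHEEL = "RHEE",
  L_TOE = "LTOE", R_TOE = "RTOE"
)

#' Motion-capture walking trial
#'
#' Container for one walking trial: labelled 3D marker trajectories in metres
#' (laboratory frame, vertical axis explicit) sampled at a fixed rate, plus
#' subject metadata. Marker data live in a wide tibble with columns `frame`,
#' `time` and `<LABEL>_<axis>` for `axis` in `x`, `y`, `z`, so trajectories
#' can be manipulated with ordinary data-frame tools.
#'
#' @param data Data frame with one row per frame and columns
#'   `<LABEL>_<x|y|z>` (metres). `frame` and `time` columns are added when
#'   absent (frames are 0-based; time = frame / `sample_rate`).
#' @param sample_rate Sampling rate in Hz (positive).
#' @param subject_id Subject identifier.
#' @param anthropometrics An [anthropometrics()] object, or `NULL`.
#' @param group Group label: `"stroke"`, `"healthy"` or `"unknown"`.
#' @param plegic_side Affected side for stroke subjects: `"left"`, `"right"`
#'   or `"none"`.
#' @param vertical_axis Which coordinate axis is vertical (`"x"`, `"y"` or
#'   `"z"`; default `"z"`).
#' @param aliases Named character vector mapping non-canonical marker labels
#'   to canonical ones; applied to column prefixes on construction.
#'
#' @return A `gait_recording` object.
#' @export
#' @examples
#' dat <- tibble::tibble(LASI_x = 0.1, LASI_y = 0, LASI_z = 1)
#' rec <- gait_recording(dat, sample_rate = 100, subject_id = "demo")
#' marker_labels(rec)
gait_recording <- function(data,
                           sample_rate,
                           subject_id = "unknown",
                           anthropometrics = NULL,
                           group = c("unknown", "healthy", "stroke"),
                           plegic_side = c("none", "left", "right"),
                           vertical_axis = "z",
                           aliases = DEFAULT_MARKER_ALIASES) {
  if (!is.data.frame(data) || nrow(data) < 1) {
    abort("`data` must be a data frame with at least one row of frames.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).")
  }
  if (!vertical_axis %in% c("x", "y", "z")) abort("`vertical_axis` must be x, y or z.")
  group <- match.arg(group)
  plegic_side <- match.arg(plegic_side)

  data <- tibble::as_tibble(data)
  names(data) <- canonicalize_columns(names(data), aliases)
  labs <- marker_labels_from_cols(names(data))
  if (length(labs) == 0) abort("`data` contains no `<LABEL>_<x|y|z>` marker columns.")
  for (lab in labs) {
    miss <- setdiff(paste0(lab, "_", c("x", "y", "z")), names(data))
    if (length(miss)) {
      abort(paste0("Marker ", lab, " is missing axis column(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  if (!"frame" %in% names(data)) data$frame <- seq_len(nrow(data)) - 1L
  data$time <- data$frame / sample_rate
  axis_cols <- unlist(lapply(labs, function(l) paste0(l, "_", c("x", "y", "z"))))
  data <- data[, c("frame", "time", axis_cols)]

  structure(list(
    data = data,
    sample_rate = sample_rate,
    subject_id = subject_id,
    anthropometrics = anthropometrics,
    group = group,
    plegic_side = plegic_side,
    vertical_axis = vertical_axis
  ), class = "gait_recording")
}

canonicalize_columns <- function(cols, aliases) {
  if (length(aliases) == 0) return(cols)
  vapply(cols, function(cn) {
    m <- regmatches(cn, regexec("^(.*)_([xyz])$", cn))[[1]]
    if (length(m) == 3 && m[2] %in% names(aliases)) {
      paste0(aliases[[m[2]]], "_", m[3])
    } else cn
  }, character(1), USE.NAMES = FALSE)
}

marker_labels_from_cols <- function(cols) {
  hits <- grep("^.+_[xyz]$", cols, value = TRUE)
  unique(sub("_[xyz]$", "", hits))
}

#' Marker labels present in a recording
#' @param recording A [gait_recording()].
#' @return Character vector of canonical marker labels.
#' @export
marker_labels <- function(recording) {
  stopifnot(inherits(recording, "gait_recording"))
  marker_labels_from_cols(names(recording$data))
}

#' Extract one marker trajectory as an n-by-3 matrix
#'
#' @param recording A [gait_recording()].
#' @param label Canonical marker label, e.g. `"LASI"`.
#' @return Numeric matrix with columns `x`, `y`, `z` (metres).
#' @export
marker_xyz <- function(recording, label) {
  cols <- paste0(label, "_", c("x", "y", "z"))
  if (!all(cols %in% names(recording$data))) {
    abort(paste0("Marker ", label, " not present in recording."))
  }
  m <- as.matrix(recording$data[, cols])
  colnames(m) <- c("x", "y", "z")
  m
}

n_frames <- function(recording) nrow(recording$data)

#' Check that the markers needed downstream are present
#'
#' The pipeline needs the four pelvic markers (LASI, RASI, LPSI, RPSI) for
#' the centre-of-mass estimate and the heel/toe markers (LHEE, RHEE, LTOE,
#' RTOE) for event detection.
#'
#' @param recording A [gait_recording()].
#' @param markers Labels to require.
#' @return Invisibly `TRUE`; errors naming the absent labels otherwise.
#' @export
require_markers <- function(recording,
                            markers = c(PELVIC_MARKERS, FOOT_MARKERS)) {
  absent <- setdiff(markers, marker_labels(recording))
  if (length(absent)) {
    abort(paste0("Recording '", recording$subject_id,
                 "' is missing required marker(s): ",
                 paste(absent, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Fill short marker drop-outs by cubic interpolation
#'
#' Runs of missing samples no longer than `max_gap_frames` are filled with a
#' natural cubic spline through the surrounding samples; longer runs are left
#' missing so that the steps they overlap can be rejected rather than the
#' whole trial.
#'
#' @param recording A [gait_recording()].
#' @param max_gap_frames Longest gap (frames) that will be filled.
#' @return The recording with short gaps filled; the frames that remain
#'   invalid are recorded in attribute `"invalid_frames"` of the result.
#' @export
fill_marker_gaps <- function(recording, max_gap_frames = 10L) {
  dat <- recording$data
  invalid <- logical(nrow(dat))
  for (lab in marker_labels(recording)) {
    for (ax in c("x", "y", "z")) {
      col <- paste0(lab, "_", ax)
      v <- dat[[col]]
      if (!anyNA(v)) next
      runs <- rle(is.na(v))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      fillable <- rep(FALSE, length(v))
      for (k in which(runs$values)) {
        idx <- starts[k]:ends[k]
        if (runs$lengths[k] <= max_gap_frames &&
            starts[k] > 1L && ends[k] < length(v)) {
          fillable[idx] <- TRUE
        } else {
          invalid[idx] <- TRUE
        }
      }
      if (any(fillable)) {
        ok <- !is.na(v)
        v[fillable] <- stats::spline(x = which(ok), y = v[ok],
                                     xout = which(fillable),
                                     method = "natural")$y
        dat[[col]] <- v
      }
    }
  }
  recording$data <- dat
  attr(recording, "invalid_frames") <- which(invalid)
  recording
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> subject %s (%s), %d frames @ %g Hz, %d markers\n",
              x$subject_id, x$group, n_frames(x), x$sample_rate,
              length(marker_labels(x))))
  invisible(x)
}

#' @export
as_tibble.gait_recording <- function(x, ...) x$data

# Heights of heel markers define the floor datum: potential energy is measured
# from the lowest heel-marker sample of the trial.
floor_height <- function(recording) {
  vax <- recording$vertical_axis
  cols <- paste0(c("LHEE", "RHEE"), "_", vax)
  cols <- intersect(cols, names(recording$data))
  if (length(cols) == 0) {
    return(min(as.matrix(recording$data[, grep(paste0("_", vax, "$"),
                                               names(recording$data))]),
               na.rm = TRUE))
  }
  min(as.matrix(recording$data[, cols]), na.rm = TRUE)
}

#' Walking reference frame of a trial
#'
#' The anterior-posterior (AP) axis is the principal axis of the pelvic
#' midpoint's horizontal displacement, signed so that net progression is
#' positive; the vertical (V) axis is the configured laboratory vertical and
#' the medio-lateral (ML) axis completes the right-handed triad. This makes
#' all downstream quantities invariant to walkway orientation, including
#' walking the lane in the reverse direction.
#'
#' @param recording A [gait_recording()].
#' @return List with unit vectors `ap`, `ml`, `v` (length-3, lab frame).
#' @export
walking_frame <- function(recording) {
  require_markers(recording, PELVIC_MARKERS)
  mid <- pelvic_midpoint(recording)
  vax_i <- match(recording$vertical_axis, c("x", "y", "z"))
  v <- c(0, 0, 0); v[vax_i] <- 1
  horiz <- setdiff(1:3, vax_i)
  xy <- mid[, horiz, drop = FALSE]
  xy <- xy[complete.cases(xy), , drop = FALSE]
  disp <- sweep(xy, 2, colMeans(xy))
  net <- xy[nrow(xy), ] - xy[1, ]
  if (sqrt(sum(net^2)) < 1e-6) {
    # no progression: fall back to first horizontal axis
    dir2 <- c(1, 0)
  } else {
    pc <- eigen(crossprod(disp) / nrow(disp), symmetric = TRUE)$vectors[, 1]
    if (sum(pc * net) < 0) pc <- -pc
    dir2 <- pc
  }
  ap <- c(0, 0, 0); ap[horiz] <- dir2
  ml <- vec_cross(v, ap)
  list(ap = ap, ml = ml, v = v)
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

pelvic_midpoint <- function(recording) {
  ms <- lapply(PELVIC_MARKERS, marker_xyz, recording = recording)
  (ms[[1]] + ms[[2]] + ms[[3]] + ms[[4]]) / 4
}
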