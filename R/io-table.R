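#' Read a walking trial from a delimited marker table
#'
#' The table has one row per frame and columns `<LABEL>_<axis>` with `axis`
#' one of `x`, `y`, `z` (an optional `frame` column is honoured). Comment
#' lines of the form `# key: value` before the header may carry
#' `sample_rate`, `units`, `subject_id`, `group`, `plegic_side` and
#' `vertical_axis`; values given in `layout` take precedence. Coordinates
#' stored in millimetres are converted to metres, either because the units
#' field says `mm` or, failing that, because the coordinate magnitudes exceed
#' 50 (no plausible laboratory coordinate in metres does).
#'
#' @param path Path to the delimited text file.
#' @param layout Optional list overriding the header fields:
#'   `sample_rate` (Hz), `units` (`"m"` or `"mm"`), `subject_id`, `group`,
#'   `plegic_side`, `vertical_axis`, `aliases` (named character vector),
#'   `sep` (field separator, default `","`).
#' @param anthropometrics Optional [anthropometrics()] to attach.
#' @return A [gait_recording()].
#' @export
read_marker_table <- function(path, layout = list(), anthropometrics = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  sep <- layout$sep %||% ","
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) abort("Marker table needs a header row and at least one frame.")

  meta <- parse_kv_header(hdr)
  for (k in names(layout)) meta[[k]] <- layout[[k]]

  cols <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  cols <- trimws(cols)
  check_axis_suffixes(cols)

  fields <- strsplit(body[-1], sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    abort(sprintf("Ragged rows: expected %d fields, found rows with %s.",
                  length(cols), paste(unique(nf[nf != length(cols)]), collapse = ", ")))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                nrow = length(fields), byrow = TRUE)
  raw <- do.call(rbind, fields)
  bad <- is.na(mat) & !(toupper(trimws(raw)) %in% c("NA", "NAN", ""))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric cell '%s' at data row %d, column '%s'.",
                  raw[bad][1], ij[1], cols[ij[2]]))
  }
  dat <- tibble::as_tibble(as.data.frame(mat))
  names(dat) <- cols

  units <- tolower(meta$units %||% "auto")
  axis_cols <- setdiff(cols, c("frame", "time"))
  if (identical(units, "mm") ||
      (identical(units, "auto") && max(abs(dat[axis_cols]), na.rm = TRUE) > 50)) {
    dat[axis_cols] <- dat[axis_cols] / 1000
  }

  sr <- as.numeric(meta$sample_rate %||% NA)
  if (!is.finite(sr)) abort("Sample rate missing: supply `layout$sample_rate` or a '# sample_rate:' header.")

  if (is.null(anthropometrics) && !is.null(meta$mass_kg)) {
    anthropometrics <- anthropometrics(
      mass = as.numeric(meta$mass_kg),
      leg_length = as.numeric(meta$leg_length_m %||% NA))
  }

  gait_recording(
    dat[setdiff(names(dat), "time")],
    sample_rate = sr,
    subject_id = meta$subject_id %||% meta$id %||% "unknown",
    anthropometrics = anthropometrics,
    group = meta$group %||% "unknown",
    plegic_side = meta$plegic_side %||% "none",
    vertical_axis = meta$vertical_axis %||% "z",
    aliases = meta$aliases %||% DEFAULT_MARKER_ALIASES
  )
}

parse_kv_header <- function(hdr) {
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

check_axis_suffixes <- function(cols) {
  for (cn in setdiff(cols, c("frame", "time"))) {
    m <- regmatches(cn, regexec("^(.*)_([A-Za-z]+)$", cn))[[1]]
    if (length(m) != 3 || !tolower(m[3]) %in% c("x", "y", "z")) {
      abort(paste0("Column '", cn, "' does not end in a valid axis suffix (_x, _y, _z)."))
    }
  }
  invisible(TRUE)
}

#' Write a walking trial to a delimited marker table
#'
#' Writes the recording's metadata as `# key: value` comment lines followed
#' by a CSV table (`frame,<LABEL>_x,...`), in metres, with enough digits that
#' [read_marker_table()] reproduces every coordinate to better than 1e-9 m.
#'
#' @param recording A [gait_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_table <- function(recording, path) {
  stopifnot(inherits(recording, "gait_recording"))
  labs <- marker_labels(recording)
  if (length(labs) == 0) abort("Recording has no markers to write.")
  dat <- recording$data
  axis_cols <- setdiff(names(dat), c("frame", "time"))
  hdr <- c(
    sprintf("# sample_rate: %.10g", recording$sample_rate),
    "# units: m",
    sprintf("# subject_id: %s", recording$subject_id),
    sprintf("# group: %s", recording$group),
    sprintf("# plegic_side: %s", recording$plegic_side),
    sprintf("# vertical_axis: %s", recording$vertical_axis)
  )
  a <- recording$anthropometrics
  if (!is.null(a)) {
    hdr <- c(hdr, sprintf("# mass_kg: %.10g", a$mass))
    if (is.finite(a$leg_length)) {
      hdr <- c(hdr, sprintf("# leg_length_m: %.10g", a$leg_length))
    }
  }
  body_cols <- c("frame", axis_cols)
  rows <- apply(dat[body_cols], 1, function(r) {
    paste(formatC(r, format = "g", digits = 15), collapse = ",")
  })
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, paste(body_cols, collapse = ","), rows), con)
  invisible(path)
}
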