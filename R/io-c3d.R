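# Minimal C3D support. C3D is the standard binary container of optoelectronic
# motion-capture systems: a 512-byte-block file with a header, a parameter
# section (group/parameter records) and per-frame 3D point data. No installed
# R package parses it, so the subset needed for marker work is implemented
# here: Intel byte order, floating-point or 16-bit-integer point data, the
# POINT group's USED/RATE/SCALE/UNITS/LABELS parameters, millimetre or metre
# units. Analog channels (e.g. force plates) are ignored.

C3D_BLOCK <- 512L

#' Read a walking trial from a C3D file
#'
#' Reads marker trajectories, sampling rate and units from a standard C3D
#' motion-capture file (Intel processor type; float or scaled-integer point
#' data). Positions stored in millimetres are converted to metres using the
#' `POINT:UNITS` parameter. Marker labels are mapped to canonical Plug-In
#' Gait names through the alias table.
#'
#' @param path Path to a `.c3d` file.
#' @param subject_id,group,plegic_side,anthropometrics Subject metadata to
#'   attach (C3D files do not reliably carry it).
#' @param vertical_axis Laboratory vertical axis, default `"z"`.
#' @param aliases Marker-label alias table (see [gait_recording()]).
#' @return A [gait_recording()].
#' @export
read_c3d <- function(path, subject_id = "unknown", group = "unknown",
                     plegic_side = "none", anthropometrics = NULL,
                     vertical_axis = "z", aliases = DEFAULT_MARKER_ALIASES) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 2L * C3D_BLOCK) abort("File too short to be a C3D file.")
  if (as.integer(raw[2]) != 0x50) abort("Not a C3D file (magic byte 0x50 missing).")
  param_block <- as.integer(raw[1])

  hdr_i16 <- function(word) readBin(raw[(2 * word - 1):(2 * word)], "integer",
                                    size = 2, endian = "little")
  hdr_f32 <- function(word) readBin(raw[(2 * word - 1):(2 * word + 2)], "double",
                                    size = 4, endian = "little")
  n_points <- hdr_i16(2)
  first_frame <- hdr_i16(4)
  last_frame <- hdr_i16(5)
  scale_hdr <- hdr_f32(7)
  data_block <- hdr_i16(9)
  rate_hdr <- hdr_f32(11)

  p0 <- (param_block - 1L) * C3D_BLOCK
  proc <- as.integer(raw[p0 + 4L])
  if (proc != 84L) {
    abort(sprintf("Unsupported C3D processor type %d (only Intel/PC, 84).", proc))
  }
  params <- parse_c3d_params(raw, p0)
  pt <- params$POINT %||% list()

  labels <- pt$LABELS %||% abort("C3D has no POINT:LABELS parameter.")
  labels <- trimws(labels)
  rate <- as.numeric(pt$RATE %||% rate_hdr)
  scale <- as.numeric(pt$SCALE %||% scale_hdr)
  units <- tolower(trimws(pt$UNITS %||% "mm"))
  n_used <- as.integer(pt$USED %||% n_points)
  n_frames <- last_frame - first_frame + 1L
  if (!is.null(pt$FRAMES) && is.finite(pt$FRAMES[1]) && pt$FRAMES[1] > 0) {
    n_frames <- as.integer(pt$FRAMES[1])
  }
  if (n_used < 1 || n_frames < 1) abort("C3D contains no point data.")
  labels <- labels[seq_len(min(length(labels), n_used))]

  d0 <- (data_block - 1L) * C3D_BLOCK
  vals_per_frame <- 4L * n_used
  if (scale < 0) {
    need <- 4L * vals_per_frame * n_frames
    v <- readBin(raw[(d0 + 1L):(d0 + need)], "double", n = vals_per_frame * n_frames,
                 size = 4, endian = "little")
  } else {
    need <- 2L * vals_per_frame * n_frames
    v <- readBin(raw[(d0 + 1L):(d0 + need)], "integer", n = vals_per_frame * n_frames,
                 size = 2, endian = "little")
    v <- v * scale
  }
  arr <- matrix(v, nrow = vals_per_frame)  # columns = frames
  factor <- if (units == "mm") 1e-3 else 1
  dat <- list()
  for (j in seq_len(n_used)) {
    base <- 4L * (j - 1L)
    dat[[paste0(labels[j], "_x")]] <- arr[base + 1L, ] * factor
    dat[[paste0(labels[j], "_y")]] <- arr[base + 2L, ] * factor
    dat[[paste0(labels[j], "_z")]] <- arr[base + 3L, ] * factor
  }
  gait_recording(tibble::as_tibble(dat), sample_rate = rate,
                 subject_id = subject_id, group = group,
                 plegic_side = plegic_side,
                 anthropometrics = anthropometrics,
                 vertical_axis = vertical_axis, aliases = aliases)
}

# Walk the parameter section records; returns list(GROUP = list(PARAM = value)).
parse_c3d_params <- function(raw, p0) {
  groups <- list()          # id -> name
  values <- list()          # group name -> named list
  pos <- p0 + 4L            # first record (1-based offset into raw)
  repeat {
    if (pos + 1L > length(raw)) break
    nlen <- readBin(raw[pos + 1L], "integer", size = 1, signed = TRUE)
    if (nlen == 0L) break
    gid <- readBin(raw[pos + 2L], "integer", size = 1, signed = TRUE)
    nm <- rawToChar(raw[(pos + 3L):(pos + 2L + abs(nlen))])
    off_pos <- pos + 2L + abs(nlen)
    offset <- readBin(raw[(off_pos + 1L):(off_pos + 2L)], "integer",
                      size = 2, endian = "little")
    if (gid < 0) {                      # group definition
      groups[[as.character(-gid)]] <- toupper(nm)
    } else {                            # parameter of group gid
      q <- off_pos + 2L
      type <- readBin(raw[q + 1L], "integer", size = 1, signed = TRUE)
      ndim <- as.integer(raw[q + 2L])
      dims <- if (ndim > 0) as.integer(raw[(q + 3L):(q + 2L + ndim)]) else integer(0)
      q <- q + 2L + ndim
      nel <- prod(c(dims, 1L))
      val <- switch(as.character(type),
        "-1" = {
          chars <- raw[(q + 1L):(q + nel)]
          if (ndim >= 2) {
            wid <- dims[1]
            vapply(seq_len(nel %/% wid), function(j) {
              rawToChar(chars[((j - 1L) * wid + 1L):(j * wid)])
            }, character(1))
          } else rawToChar(chars)
        },
        "1" = as.integer(raw[(q + 1L):(q + nel)]),
        "2" = readBin(raw[(q + 1L):(q + 2L * nel)], "integer", n = nel,
                      size = 2, endian = "little"),
        "4" = readBin(raw[(q + 1L):(q + 4L * nel)], "double", n = nel,
                      size = 4, endian = "little"),
        abort(sprintf("Unknown C3D parameter type %d.", type)))
      gname <- groups[[as.character(gid)]] %||% as.character(gid)
      if (is.null(values[[gname]])) values[[gname]] <- list()
      values[[gname]][[toupper(nm)]] <- val
    }
    if (offset == 0L) break
    pos <- off_pos + 2L + offset
  }
  # group records can appear after their parameters; remap numeric keys
  fixed <- list()
  for (key in names(values)) {
    gname <- groups[[key]] %||% key
    fixed[[gname]] <- c(fixed[[gname]] %||% list(), values[[key]])
  }
  fixed
}

#' Write a walking trial to a C3D file
#'
#' Writes an Intel-format C3D with floating-point point data and the POINT
#' group parameters (USED, FRAMES, RATE, SCALE, UNITS, LABELS). Intended for
#' interchange and for exercising [read_c3d()]; analog data are not written.
#'
#' @param recording A [gait_recording()].
#' @param path Output path.
#' @param units Coordinate units to store, `"m"` or `"mm"`.
#' @return Invisibly, `path`.
#' @export
write_c3d <- function(recording, path, units = c("m", "mm")) {
  stopifnot(inherits(recording, "gait_recording"))
  units <- match.arg(units)
  labs <- marker_labels(recording)
  if (length(labs) == 0) abort("Recording has no markers to write.")
  nf <- n_frames(recording)
  if (nf > 32767) abort("C3D writer supports at most 32767 frames.")
  np <- length(labs)
  factor <- if (units == "mm") 1e3 else 1

  param <- c3d_param_section(recording, labs, units, nf)
  n_param_blocks <- length(param) / C3D_BLOCK
  data_block <- 2L + n_param_blocks

  con <- file(path, open = "wb")
  on.exit(close(con))
  # -- header block
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  writeBin(as.raw(c(2L, 0x50)), con)      # parameter block pointer, magic
  w16(np); w16(0L); w16(1L); w16(nf); w16(0L)
  f32(-1)                                  # scale < 0: float data
  w16(data_block); w16(0L)
  f32(recording$sample_rate)
  writeBin(raw(C3D_BLOCK - 24L), con)      # pad header to 512 bytes
  # -- parameter section
  writeBin(param, con)
  # -- point data: x, y, z, residual per point per frame
  lab_mat <- lapply(labs, marker_xyz, recording = recording)
  out <- numeric(4L * np * nf)
  for (j in seq_len(np)) {
    m <- lab_mat[[j]] * factor
    base <- 4L * (j - 1L)
    idx <- rep((seq_len(nf) - 1L) * 4L * np, each = 3L) + base + rep(1:3, nf)
    out[idx] <- as.numeric(t(m))
  }
  writeBin(out, con, size = 4, endian = "little")
  invisible(path)
}

c3d_param_section <- function(recording, labs, units, nf) {
  lab_w <- max(nchar(labs), 4L)
  lab_padded <- formatC(labs, width = -lab_w)  # left-justified, space padded

  rec_group <- function(id, name) {
    nm <- charToRaw(name)
    c(as.raw(length(nm)), signed_raw(-id), nm, int16_raw(1L), as.raw(0L))
  }
  rec_param <- function(id, name, type, dims, data_raw, last = FALSE) {
    nm <- charToRaw(name)
    body <- c(as.raw(type_byte(type)), as.raw(length(dims)), as.raw(dims),
              data_raw, as.raw(0L))
    off <- if (last) 0L else length(body)
    c(as.raw(length(nm)), signed_raw(id), nm, int16_raw(off), body)
  }
  type_byte <- function(type) switch(type, char = 255L, int16 = 2L, float = 4L)
  f32_raw <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  int16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  signed_raw <- function(x) as.raw(bitwAnd(as.integer(x), 255L))

  recs <- c(
    rec_group(1L, "POINT"),
    rec_param(1L, "USED", "int16", integer(0), int16_raw(length(labs))),
    rec_param(1L, "FRAMES", "int16", integer(0), int16_raw(nf)),
    rec_param(1L, "RATE", "float", integer(0), f32_raw(recording$sample_rate)),
    rec_param(1L, "SCALE", "float", integer(0), f32_raw(-1)),
    rec_param(1L, "UNITS", "char", length(charToRaw(units)),
              charToRaw(units)),
    rec_param(1L, "LABELS", "char", c(lab_w, length(labs)),
              charToRaw(paste(lab_padded, collapse = "")), last = TRUE)
  )
  n_blocks <- ceiling((length(recs) + 4L) / C3D_BLOCK)
  head <- as.raw(c(1L, 0x50, n_blocks, 84L))  # 84 = Intel processor type
  body <- c(head, recs)
  c(body, raw(n_blocks * C3D_BLOCK - length(body)))
}
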