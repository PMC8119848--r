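#' Continuous multichannel EEG recording
#'
#' Container for a continuous recording: a channels-by-samples matrix in
#' microvolts plus sampling rate, channel labels, electrode positions and
#' subject metadata (group, lesion side, optional clinical score).
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel labels, one per row.
#' @param positions data.frame with columns `label`, `x`, `y`, `z` (unit
#'   sphere) or NULL to take positions from the built-in template.
#' @param group `"control"` or `"stroke"`.
#' @param lesion_side `"left"`, `"right"` or `"none"`.
#' @param subject_id free-text identifier.
#' @param fma optional upper-extremity motor Fugl-Meyer score.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels, positions = NULL,
                          group = c("control", "stroke"),
                          lesion_side = c("none", "left", "right"),
                          subject_id = "subject", fma = NA_real_) {
  group <- match.arg(group)
  lesion_side <- match.arg(lesion_side)
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (length(labels) != nrow(data)) stop("labels must match data rows")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (is.null(positions)) {
    tmpl <- standard_montage(64)
    miss <- setdiff(labels, tmpl$label)
    if (length(miss)) {
      warning("no positions for channels ", paste(miss, collapse = ", "),
              "; using template where available")
    }
    positions <- tmpl[match(labels, tmpl$label), , drop = FALSE]
    positions$label <- labels
  }
  if (!all(c("label", "x", "y", "z") %in% names(positions)))
    stop("positions needs columns label, x, y, z")
  positions <- positions[match(labels, positions$label), , drop = FALSE]
  structure(list(data = unname(data), fs = fs, labels = as.character(labels),
                 positions = positions, group = group,
                 lesion_side = lesion_side, subject_id = subject_id,
                 fma = fma),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s: %d ch x %d samples @ %g Hz, %.1f s, group=%s, lesion=%s>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, x$group, x$lesion_side))
  invisible(x)
}

#' Epoched EEG data
#'
#' @param data epochs x channels x samples array (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels channel labels.
#' @param rejected_channels labels flagged and removed/interpolated.
#' @param rejected_epochs indices of epochs flagged and dropped.
#' @param meta list of subject metadata carried through the pipeline.
#' @return object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, labels, rejected_channels = character(0),
                       rejected_epochs = integer(0), meta = list()) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(labels))
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 rejected_channels = rejected_channels,
                 rejected_epochs = rejected_epochs, meta = meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs: %d epochs x %d ch x %d samples @ %g Hz>\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

# ---------------------------------------------------------------------------
# File I/O. Three formats: the package's internal container, EDF, and
# BrainVision (read-only). EDF and BrainVision support is minimal but
# self-contained; no reader package for either exists in this R installation.

#' Write a recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path output file (`.rds` for internal, `.edf` for EDF).
#' @param format `"internal"` (lossless RDS container with named fields
#'   data/fs/labels/group/lesion_side) or `"edf"` (16-bit EDF, lossy
#'   quantization at ~1e-4 relative).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("internal", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "internal") {
    obj <- list(data = rec$data, fs = rec$fs, labels = rec$labels,
                positions = rec$positions, group = rec$group,
                lesion_side = rec$lesion_side, subject_id = rec$subject_id,
                fma = rec$fma, container = "restnet-recording-v1")
    saveRDS(obj, path)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path input file.
#' @param format `"internal"`, `"edf"` or `"brainvision"` (pass the `.vhdr`
#'   header file).
#' @param ... metadata overrides (`group`, `lesion_side`, `subject_id`, `fma`)
#'   for formats that do not carry them.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("internal", "edf", "brainvision"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "internal") {
    obj <- tryCatch(readRDS(path), error = function(e)
      stop("malformed internal container: ", conditionMessage(e)))
    if (!identical(obj$container, "restnet-recording-v1"))
      stop("not a restnet recording container: ", path)
    eeg_recording(obj$data, obj$fs, obj$labels, obj$positions, obj$group,
                  obj$lesion_side, obj$subject_id, obj$fma)
  } else if (format == "edf") {
    read_edf(path, ...)
  } else {
    read_brainvision(path, ...)
  }
}

# --- EDF ---------------------------------------------------------------------

edf_pad <- function(x, n) {
  s <- formatC(as.character(x), width = n, flag = "-")
  substr(s, 1, n)
}

write_edf <- function(rec, path) {
  nch <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer sampling rate")
  fs <- as.integer(round(fs))
  nsamp <- ncol(rec$data)
  nrec <- nsamp %/% fs
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  used <- nrec * fs
  x <- rec$data[, seq_len(used), drop = FALSE]

  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  span <- pmax - pmin
  pmin[span == 0] <- pmin[span == 0] - 1
  pmax[span == 0] <- pmax[span == 0] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(edf_pad(s, n), con, nchars = n, eos = NULL)
  wr("0", 8)
  wr(paste("X X X", rec$subject_id), 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (nch + 1)), 8)
  wr("", 44)
  wr(as.character(nrec), 8)
  wr("1", 8)
  wr(as.character(nch), 4)
  for (lab in rec$labels) wr(lab, 16)
  for (i in seq_len(nch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(formatC(pmin[i], digits = 7, format = "g"), 8)
  for (i in seq_len(nch)) wr(formatC(pmax[i], digits = 7, format = "g"), 8)
  for (i in seq_len(nch)) wr(as.character(dmin), 8)
  for (i in seq_len(nch)) wr(as.character(dmax), 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(as.character(fs), 8)
  for (i in seq_len(nch)) wr("", 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nch)) {
      dig <- round((x[i, idx] - pmin[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) stop("truncated EDF header: ", path)
    trimws(s)
  }
  rd(8)                                    # version
  subject <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  nch <- suppressWarnings(as.integer(rd(4)))
  if (is.na(nrec) || is.na(dur) || is.na(nch) || nch < 1)
    stop("malformed EDF header: ", path)
  labels <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)            # units
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  ns <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(ns)) != 1) stop("EDF reader requires a common sampling rate")
  fs <- ns[1] / dur

  total <- nrec * sum(ns)
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little")
  if (length(raw) < total) stop("truncated EDF data: ", path)
  data <- matrix(0, nch, nrec * ns[1])
  k <- 0
  for (r in seq_len(nrec)) {
    for (i in seq_len(nch)) {
      seg <- raw[(k + 1):(k + ns[i])]; k <- k + ns[i]
      data[i, ((r - 1) * ns[i] + 1):(r * ns[i])] <-
        (seg - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  parts <- strsplit(subject, " +")[[1]]
  sid <- if (length(parts) >= 4) parts[4] else "subject"
  eeg_recording(data, fs, labels, subject_id = sid, ...)
}

# --- BrainVision (read-only) -------------------------------------------------

read_brainvision <- function(vhdr_path, ...) {
  lines <- tryCatch(readLines(vhdr_path, warn = FALSE), error = function(e)
    stop("cannot read BrainVision header: ", conditionMessage(e)))
  get_kv <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  datafile <- get_kv("DataFile")
  fmt <- get_kv("DataFormat")
  orient <- get_kv("DataOrientation")
  nch <- as.integer(get_kv("NumberOfChannels"))
  interval <- as.numeric(get_kv("SamplingInterval"))   # microseconds
  if (is.na(datafile) || is.na(nch) || is.na(interval))
    stop("malformed BrainVision header: ", vhdr_path)
  fs <- 1e6 / interval

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != nch) stop("BrainVision channel count mismatch")
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_parts, `[`, "", 1)
  resolution <- vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)

  data_path <- file.path(dirname(vhdr_path), datafile)
  if (!file.exists(data_path)) stop("BrainVision data file missing: ", data_path)

  if (identical(fmt, "ASCII")) {
    vals <- as.matrix(utils::read.table(data_path))
    data <- if (identical(orient, "VECTORIZED")) {
      if (nrow(vals) != nch) stop("truncated BrainVision ASCII data")
      unname(vals)
    } else t(unname(vals))
  } else {
    binfmt <- get_kv("BinaryFormat")
    size <- switch(binfmt, INT_16 = 2L, IEEE_FLOAT_32 = 4L,
                   stop("unsupported BinaryFormat: ", binfmt))
    what <- if (binfmt == "INT_16") integer() else numeric()
    nbytes <- file.info(data_path)$size
    n <- as.integer(nbytes / size)
    if (n %% nch != 0) stop("truncated BrainVision binary data: ", data_path)
    raw <- readBin(data_path, what, n = n, size = size, endian = "little")
    data <- if (identical(orient, "VECTORIZED"))
      matrix(raw, nrow = nch, byrow = TRUE) else matrix(raw, nrow = nch)
    data <- data * resolution
  }
  eeg_recording(data, fs, labels, ...)
}
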