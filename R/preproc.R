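## Sensor-level preprocessing: epoching, variance/kurtosis rejection, bad-channel
## interpolation, lesioned-hemisphere flipping, common-average re-referencing,
## and 5-Hz band separation. An optional user-supplied cleaning callback stands
## in for ICA-based artifact removal, which is outside this pipeline.

#' Cut a recording into consecutive non-overlapping epochs
#'
#' Windows start at the beginning of the recording and continue until a
#' complete window can no longer be formed; each epoch is zero-meaned per
#' channel.
#'
#' @param rec an [eeg_recording()].
#' @param window epoch length in seconds (default 2).
#' @return an [eeg_epochs()] with `floor(duration / window)` epochs.
#' @export
epoch_recording <- function(rec, window = 2.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- window * rec$fs
  if (abs(len - round(len)) > 1e-9) stop("window * fs must be an integer")
  len <- as.integer(round(len))
  n_ep <- ncol(rec$data) %/% len
  if (n_ep < 1) stop("recording shorter than one epoch window")
  nch <- nrow(rec$data)
  data <- array(0, c(n_ep, nch, len))
  for (e in seq_len(n_ep)) {
    seg <- rec$data[, ((e - 1) * len + 1):(e * len), drop = FALSE]
    data[e, , ] <- seg - rowMeans(seg)
  }
  eeg_epochs(data, rec$fs, rec$labels,
             meta = list(group = rec$group, lesion_side = rec$lesion_side,
                         subject_id = rec$subject_id, fma = rec$fma,
                         positions = rec$positions))
}

## sample excess kurtosis
.kurtosis <- function(x) {
  m <- mean(x); v <- mean((x - m)^2)
  if (v == 0) return(0)
  mean((x - m)^4) / v^2 - 3
}

#' Flag bad channels and epochs by variance/kurtosis outliers
#'
#' A channel is flagged if its variance or kurtosis, aggregated (averaged)
#' across epochs, exceeds the mean + `z_thresh` standard deviations of the
#' distribution over channels; epochs are then flagged the same way across the
#' retained channels. Deterministic single pass, channels first.
#'
#' @param ep an [eeg_epochs()].
#' @param z_thresh outlier threshold in standard deviations (default 2).
#' @return list with `bad_channels` (labels) and `bad_epochs` (indices).
#' @export
detect_bad <- function(ep, z_thresh = 2.0) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  if (d[1] < 3 || d[2] < 3) stop("need at least 3 channels and 3 epochs")

  ch_var <- ch_kur <- matrix(0, d[1], d[2])
  for (e in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- ep$data[e, c, ]
    ch_var[e, c] <- stats::var(x)
    ch_kur[e, c] <- .kurtosis(x)
  }
  flag_tail <- function(v) {
    v > mean(v) + z_thresh * stats::sd(v)
  }
  chan_bad <- flag_tail(colMeans(ch_var)) | flag_tail(colMeans(ch_kur))
  keep <- which(!chan_bad)
  ep_bad <- flag_tail(rowMeans(ch_var[, keep, drop = FALSE])) |
    flag_tail(rowMeans(ch_kur[, keep, drop = FALSE]))
  list(bad_channels = ep$labels[chan_bad], bad_epochs = which(ep_bad))
}

#' Replace bad channels by inverse-distance-weighted neighbors
#'
#' Each bad channel is rebuilt from good channels within an angular radius on
#' the unit sphere, weighted by inverse squared Euclidean distance.
#'
#' @param ep an [eeg_epochs()] whose `meta$positions` carries electrode
#'   coordinates.
#' @param bad character vector of bad channel labels.
#' @param radius neighborhood radius in radians of arc (default 0.35).
#' @param power inverse-distance exponent (default 2).
#' @return an [eeg_epochs()] with bad channels replaced and recorded in
#'   `rejected_channels`.
#' @export
interpolate_channels <- function(ep, bad, radius = 0.35, power = 2) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (length(bad) == 0) return(ep)
  if (!all(bad %in% ep$labels)) stop("unknown channels: ",
                                     paste(setdiff(bad, ep$labels), collapse = ", "))
  pos <- ep$meta$positions
  if (is.null(pos)) stop("no electrode positions available for interpolation")
  pos <- pos[match(ep$labels, pos$label), ]
  P <- as.matrix(pos[, c("x", "y", "z")])
  good <- setdiff(ep$labels, bad)
  if (length(good) == 0) stop("all channels bad; nothing to interpolate from")

  out <- ep
  for (lab in bad) {
    i <- match(lab, ep$labels)
    d <- sqrt(colSums((t(P) - P[i, ])^2))
    ang <- 2 * asin(pmin(d / 2, 1))
    nb <- which(ep$labels %in% good & ang <= radius & ang > 0)
    if (length(nb) == 0) stop("no good neighbors within radius for channel ", lab)
    w <- 1 / d[nb]^power
    w <- w / sum(w)
    for (e in seq_len(dim(ep$data)[1])) {
      out$data[e, i, ] <- as.numeric(w %*% ep$data[e, nb, , drop = TRUE])
    }
  }
  out$rejected_channels <- union(ep$rejected_channels, bad)
  out
}

#' Drop flagged epochs
#'
#' @param ep an [eeg_epochs()].
#' @param bad integer indices of epochs to drop.
#' @return an [eeg_epochs()] without the flagged epochs (recorded in
#'   `rejected_epochs`).
#' @export
drop_epochs <- function(ep, bad) {
  if (length(bad) == 0) return(ep)
  keep <- setdiff(seq_len(dim(ep$data)[1]), bad)
  if (length(keep) == 0) stop("all epochs flagged")
  out <- ep
  out$data <- ep$data[keep, , , drop = FALSE]
  out$rejected_epochs <- union(ep$rejected_epochs, bad)
  out
}

#' Swap hemispheres so the lesion is on the left
#'
#' If `lesion_side == "right"`, homologous channel pairs (odd/even 10-20
#' labels) are swapped and the lesion side relabelled `"left"`; midline
#' channels are untouched. For left or no lesion this is the identity. An
#' involution: flipping twice restores the input.
#'
#' @param rec an [eeg_recording()].
#' @return an [eeg_recording()] with the lesioned hemisphere on the left.
#' @export
flip_hemispheres <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$lesion_side != "right") return(rec)
  pairs <- homologous_pairs(rec$labels)
  lateral <- setdiff(rec$labels, midline_labels(rec$labels))
  unmapped <- setdiff(lateral, c(pairs$left, pairs$right))
  if (length(unmapped) > 0)
    stop("lateral channels without homolog: ", paste(unmapped, collapse = ", "))
  out <- rec
  li <- match(pairs$left, rec$labels)
  ri <- match(pairs$right, rec$labels)
  out$data[li, ] <- rec$data[ri, ]
  out$data[ri, ] <- rec$data[li, ]
  out$lesion_side <- "left"
  out
}

#' Common-average re-reference, reintroducing the recording reference
#'
#' The recording reference electrode (implicitly an all-zero channel) is
#' appended, then every channel is re-referenced to the mean across channels.
#' After re-referencing, the channel mean at every sample is zero.
#'
#' @param ep an [eeg_epochs()].
#' @param reference_label label of the original reference (default `"FCz"`);
#'   must not already be present. `NULL` re-references without reinsertion.
#' @return an [eeg_epochs()] with one extra channel (unless `reference_label`
#'   is NULL).
#' @export
rereference_car <- function(ep, reference_label = "FCz") {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  out <- ep
  if (!is.null(reference_label)) {
    if (reference_label %in% ep$labels)
      stop("reference channel already present: ", reference_label)
    data <- array(0, c(d[1], d[2] + 1, d[3]))
    data[, seq_len(d[2]), ] <- ep$data
    out$data <- data
    out$labels <- c(ep$labels, reference_label)
    pos <- ep$meta$positions
    if (!is.null(pos) && !(reference_label %in% pos$label)) {
      ref_pos <- data.frame(label = reference_label,
                            x = 0, y = sin(0.125 * 81 * pi / 180),
                            z = cos(0.125 * 81 * pi / 180))
      out$meta$positions <- rbind(pos[, c("label", "x", "y", "z")], ref_pos)
    }
    d <- dim(out$data)
  }
  for (e in seq_len(d[1])) {
    seg <- matrix(out$data[e, , ], d[2], d[3])
    out$data[e, , ] <- seg - rep(colMeans(seg), each = d[2])
  }
  out
}

#' Separate epoched data into frequency bands
#'
#' Applies the zero-phase Butterworth bandpass per epoch and channel, one
#' output per band.
#'
#' @param ep an [eeg_epochs()].
#' @param bands band table (see [default_bands()]).
#' @param order Butterworth prototype order (default 4).
#' @return named list of [eeg_epochs()], one per band.
#' @export
split_bands <- function(ep, bands = default_bands(), order = 4) {
  stopifnot(inherits(ep, "eeg_epochs"))
  validate_bands(bands)
  if (any(bands$hi >= ep$fs / 2)) stop("band above Nyquist")
  d <- dim(ep$data)
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    des <- butter_design(order = order, lo = bands$lo[b], hi = bands$hi[b],
                         fs = ep$fs, type = "band")
    bd <- ep
    for (e in seq_len(d[1])) {
      bd$data[e, , ] <- filtfilt_sos(des$sos, matrix(ep$data[e, , ], d[2], d[3]))
    }
    out[[b]] <- bd
  }
  out
}

#' Concatenate epochs back into a continuous matrix
#'
#' @param ep an [eeg_epochs()].
#' @return list with `data` (channels x samples) and `junctions` (sample
#'   indices where consecutive epochs meet, for boundary masking).
#' @export
concatenate_epochs <- function(ep) {
  d <- dim(ep$data)
  data <- matrix(0, d[2], d[1] * d[3])
  for (e in seq_len(d[1])) {
    data[, ((e - 1) * d[3] + 1):(e * d[3])] <- matrix(ep$data[e, , ], d[2], d[3])
  }
  junctions <- if (d[1] > 1) (seq_len(d[1] - 1)) * d[3] else integer(0)
  list(data = data, junctions = junctions, fs = ep$fs, labels = ep$labels)
}

#' Full sensor-level preprocessing chain
#'
#' Flip lesioned hemisphere to the left, epoch, reject channels/epochs,
#' interpolate bad channels, optionally apply a user-supplied cleaning
#' callback (in place of ICA artifact removal), and re-reference to the
#' common average.
#'
#' @param rec an [eeg_recording()].
#' @param window epoch window in seconds.
#' @param z_thresh rejection threshold in SD.
#' @param reference_label reference electrode to reinsert at CAR.
#' @param interp_radius interpolation neighborhood radius in radians; sparse
#'   montages need a larger value (e.g. 0.8 for 19 channels).
#' @param cleaning_fn optional function `eeg_epochs -> eeg_epochs` applied
#'   after interpolation.
#' @return an [eeg_epochs()], cleaned and re-referenced.
#' @export
preprocess_recording <- function(rec, window = 2.0, z_thresh = 2.0,
                                 reference_label = "FCz", interp_radius = 0.35,
                                 cleaning_fn = NULL) {
  rec <- flip_hemispheres(rec)
  ep <- epoch_recording(rec, window)
  bad <- detect_bad(ep, z_thresh)
  ep <- interpolate_channels(ep, bad$bad_channels, radius = interp_radius)
  ep <- drop_epochs(ep, bad$bad_epochs)
  if (!is.null(cleaning_fn)) ep <- cleaning_fn(ep)
  rereference_car(ep, reference_label)
}
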