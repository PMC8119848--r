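## Idealized 10-20 / 10-10 montage on the unit sphere. Positions are generated
## from row (anterior-posterior) and column (lateral) angles; they are not
## digitized head coordinates, but they respect the conventions every
## downstream step relies on: odd labels left, even labels right, trailing 'z'
## midline, homologous pairs exactly mirror-symmetric in x.

.montage_rows <- list(
  Fp = 0.90, AF = 0.70, F = 0.50, FT = 0.28, FC = 0.25, T = 0.00, C = 0.00,
  TP = -0.28, CP = -0.25, P = -0.50, PO = -0.70, O = -0.90
)

.lat_frac <- c("1" = 0.25, "2" = 0.25, "3" = 0.50, "4" = 0.50,
               "5" = 0.70, "6" = 0.70, "7" = 0.90, "8" = 0.90,
               "9" = 1.10, "10" = 1.10)

.label_pos <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) == 0) stop("unparseable electrode label: ", label)
  row <- m[2]; col <- m[3]
  ## T7/T8 and TP/FT sit on the C/CP/FC rows at extreme laterality
  apf <- .montage_rows[[row]]
  if (is.null(apf)) stop("unknown electrode row in label: ", label)
  if (col == "z") {
    lat <- 0
  } else {
    lat <- .lat_frac[[col]]
    if (row %in% c("T")) lat <- 0.90
    if (as.integer(col) %% 2 == 1) lat <- -lat   # odd = left
  }
  a <- apf * 81 * pi / 180   # anterior-posterior angle from vertex
  b <- lat * 81 * pi / 180   # lateral angle (positive right)
  c(x = sin(b), y = cos(b) * sin(a), z = cos(b) * cos(a))
}

#' Standard synthetic EEG montage
#'
#' A 64- or 19-channel 10-20/10-10 style montage with unit-sphere coordinates
#' (x right, y anterior, z up). The reference electrode FCz is not included
#' (it is reintroduced at common-average re-referencing).
#'
#' @param n_channels 64 (default) or 19.
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
standard_montage <- function(n_channels = 64) {
  labels64 <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8"
  )
  labels19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T7", "C3", "Cz", "C4", "T8",
                "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
  labels <- switch(as.character(n_channels),
                   "64" = labels64, "19" = labels19,
                   stop("n_channels must be 64 or 19"))
  pos <- t(vapply(labels, .label_pos, numeric(3)))
  data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Homologous electrode pairs of a montage
#'
#' Pairs left (odd-numbered) with right (even-numbered) labels by swapping the
#' trailing digit `d` with `d + 1`; midline labels (trailing `z`) are excluded.
#'
#' @param labels character vector of electrode labels.
#' @return data.frame with columns `left`, `right`.
#' @export
homologous_pairs <- function(labels) {
  left <- character(0); right <- character(0)
  for (lab in labels) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)([0-9]+)$", lab))[[1]]
    if (length(m) == 0) next
    d <- as.integer(m[3])
    if (d %% 2 == 1) {
      partner <- paste0(m[2], d + 1)
      if (partner %in% labels) {
        left <- c(left, lab); right <- c(right, partner)
      }
    }
  }
  data.frame(left = left, right = right, stringsAsFactors = FALSE)
}

#' Midline labels of a montage
#' @param labels character vector of electrode labels.
#' @return character vector of labels ending in `z`.
#' @export
midline_labels <- function(labels) labels[grepl("z$", labels)]

#' Hemisphere of each label
#' @param labels character vector of electrode or region labels.
#' @return factor with levels left, right, midline.
#' @export
label_hemisphere <- function(labels) {
  h <- ifelse(grepl("z$", labels), "midline",
              ifelse(grepl("[13579]$", labels) & !grepl("(10)$", labels), "left", "right"))
  factor(h, levels = c("left", "right", "midline"))
}
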