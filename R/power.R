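## Electrode-level spectral analysis: Welch power with epochs as the measure of
## consistency, normalized band power (percent of 1-50 Hz total, removing
## electrode-impedance/population-size gain), directional asymmetry over
## homologous pairs, and group contrasts with BH-FDR.

#' Welch power spectral density with epochs as segments
#'
#' Each retained epoch is one Welch segment (no sub-windowing): per-epoch
#' tapered periodograms are averaged across epochs. Frequency resolution is
#' `1 / window`. The taper is power-normalized so that the integrated PSD
#' equals the mean per-epoch signal power (Parseval).
#'
#' @param ep an [eeg_epochs()].
#' @param taper `"hann"` (default, controls leakage) or `"rectangular"`.
#' @return list with `psd` (channels x frequency bins, uV^2/Hz), `freq` (Hz)
#'   and `df` (bin width).
#' @export
welch_psd <- function(ep, taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  if (d[1] < 1) stop("no epochs to average")
  n <- d[3]
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) else rep(1, n)
  wnorm <- sum(w^2)
  n_keep <- floor(n / 2) + 1
  freq <- (seq_len(n_keep) - 1) * ep$fs / n
  psd <- matrix(0, d[2], n_keep)
  for (e in seq_len(d[1])) {
    seg <- matrix(ep$data[e, , ], d[2], n) * rep(w, each = d[2])
    sp <- Mod(t(stats::mvfft(t(seg))))^2
    psd <- psd + sp[, seq_len(n_keep), drop = FALSE]
  }
  psd <- psd / d[1] / (ep$fs * wnorm)
  ## one-sided: double everything except DC (and Nyquist for even n)
  dbl <- rep(2, n_keep); dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_keep] <- 1
  psd <- psd * rep(dbl, each = d[2])
  rownames(psd) <- ep$labels
  list(psd = psd, freq = freq, df = ep$fs / n)
}

#' Absolute band power from a PSD
#'
#' Sums PSD bins with `lo <= f < hi` per band (the last band is closed at its
#' upper edge so the bands partition the spectrum) and multiplies by the bin
#' width, giving uV^2.
#'
#' @param spectrum output of [welch_psd()].
#' @param bands band table.
#' @return electrodes x bands matrix of absolute power (uV^2).
#' @export
band_power <- function(spectrum, bands = default_bands()) {
  validate_bands(bands)
  if (max(bands$hi) > max(spectrum$freq) + 1e-9) stop("band outside spectrum range")
  nb <- nrow(bands)
  out <- matrix(0, nrow(spectrum$psd), nb,
                dimnames = list(rownames(spectrum$psd), bands$name))
  for (b in seq_len(nb)) {
    sel <- spectrum$freq >= bands$lo[b] - 1e-9 & spectrum$freq < bands$hi[b] - 1e-9
    if (b == nb) sel <- sel | abs(spectrum$freq - bands$hi[b]) < 1e-9
    out[, b] <- rowSums(spectrum$psd[, sel, drop = FALSE]) * spectrum$df
  }
  out
}

#' Normalize band power to percent of total
#'
#' `NP = 100 * sum(F) / sum(Total)`: each electrode's band powers as a
#' percentage of its total power across the analyzed spectrum, removing any
#' dependence on electrode gain. Rows sum to 100.
#'
#' @param absolute electrodes x bands matrix from [band_power()].
#' @return matrix of the same shape, rows summing to 100.
#' @export
normalize_power <- function(absolute) {
  tot <- rowSums(absolute)
  zero <- which(tot <= 0)
  if (length(zero) > 0) {
    nm <- rownames(absolute)
    stop("zero total power at electrode(s): ",
         paste(if (is.null(nm)) zero else nm[zero], collapse = ", "))
  }
  100 * absolute / tot
}

#' Per-subject band power table
#'
#' Convenience wrapper: Welch PSD, absolute and normalized band power.
#'
#' @param ep an [eeg_epochs()].
#' @param bands band table.
#' @param taper Welch taper.
#' @return list of class `band_power_table` with `absolute`, `normalized`,
#'   `sum_total` and `bands`.
#' @export
band_power_table <- function(ep, bands = default_bands(), taper = "hann") {
  spec <- welch_psd(ep, taper)
  absolute <- band_power(spec, bands)
  structure(list(absolute = absolute, normalized = normalize_power(absolute),
                 sum_total = rowSums(absolute), bands = bands),
            class = "band_power_table")
}

#' Electrode directional asymmetry
#'
#' `EDA = 100 * mean((NP_L - NP_R) / (NP_L + NP_R))` over homologous electrode
#' pairs, per band; midline electrodes are ignored. Positive values mean
#' larger normalized power in the left (lesioned) hemisphere.
#'
#' @param np_table electrodes x bands normalized power with electrode labels
#'   as rownames.
#' @param pair_map data.frame with columns `left`, `right` (see
#'   [homologous_pairs()]); default derived from the rownames.
#' @return data.frame with `band`, `value` (percent, in \[-100, 100\]) and
#'   `n_pairs`.
#' @export
electrode_directional_asymmetry <- function(np_table, pair_map = NULL) {
  labels <- rownames(np_table)
  if (is.null(pair_map)) pair_map <- homologous_pairs(labels)
  if (nrow(pair_map) == 0) stop("no homologous pairs available")
  li <- match(pair_map$left, labels)
  ri <- match(pair_map$right, labels)
  if (anyNA(li) || anyNA(ri)) stop("pair map references unknown electrodes")
  nb <- ncol(np_table)
  value <- numeric(nb); n_pairs <- integer(nb)
  for (b in seq_len(nb)) {
    l <- np_table[li, b]; r <- np_table[ri, b]
    s <- l + r
    ok <- s != 0
    if (any(!ok)) warning("skipping pair(s) with zero total power in band ", b)
    value[b] <- 100 * mean((l[ok] - r[ok]) / s[ok])
    n_pairs[b] <- sum(ok)
  }
  data.frame(band = colnames(np_table) %||% seq_len(nb), value = value,
             n_pairs = n_pairs, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Electrode-wise group contrast with FDR control
#'
#' Two-sample t test (pooled by default, Welch optional) at every electrode
#' within every band, with Benjamini-Hochberg correction across electrodes
#' within each band.
#'
#' @param tables list of per-subject electrodes x bands matrices (same
#'   dimensions and ordering).
#' @param groups character/factor of group labels, one per subject (2 levels).
#' @param alpha FDR level (default 0.05).
#' @param var_equal pooled-variance t (default TRUE) or Welch.
#' @return list with matrices `t`, `p`, and logical `significant`
#'   (electrodes x bands).
#' @export
groupwise_electrode_test <- function(tables, groups, alpha = 0.05, var_equal = TRUE) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, length(tables) == length(groups))
  if (min(table(groups)) < 2) stop("need at least 2 subjects per group")
  dims <- dim(tables[[1]])
  arr <- array(unlist(tables), c(dims, length(tables)))
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  tmat <- pmat <- matrix(NA_real_, dims[1], dims[2],
                         dimnames = dimnames(tables[[1]]))
  for (i in seq_len(dims[1])) for (b in seq_len(dims[2])) {
    x <- arr[i, b, g1]; y <- arr[i, b, g2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) { tmat[i, b] <- 0; pmat[i, b] <- 1 }
      next
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    tmat[i, b] <- unname(tt$statistic)
    pmat[i, b] <- tt$p.value
  }
  sig <- matrix(FALSE, dims[1], dims[2], dimnames = dimnames(pmat))
  for (b in seq_len(dims[2])) {
    ok <- !is.na(pmat[, b])
    if (any(ok)) sig[ok, b] <- stats::p.adjust(pmat[ok, b], "BH") <= alpha
  }
  if (anyNA(tmat)) warning("degenerate variance at some electrodes; masked out")
  list(t = tmat, p = pmat, significant = sig)
}
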