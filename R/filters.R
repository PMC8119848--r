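## IIR filtering primitives. No DSP package ships with this environment, so the
## Butterworth design (analog prototype -> band transform -> bilinear) and the
## zero-phase forward-backward application are implemented here on top of the
## compiled recursions in stats::filter. Filters are applied as cascaded
## second-order sections; the expanded order-8 direct form is numerically
## fragile for narrow bands.

#' Design a digital Butterworth filter
#'
#' Returns the filter as second-order sections (`sos`, the numerically stable
#' form used for application) plus the expanded transfer-function coefficients
#' `b`/`a` for reference. For `type = "band"` the realized filter has
#' `2 * order` poles (the conventional "order-4 bandpass"). Designed by the
#' bilinear transform with frequency pre-warping.
#'
#' @param order filter order of the lowpass prototype (default 4).
#' @param lo,hi corner frequencies in Hz. For `type = "low"` only `hi` is used,
#'   for `type = "high"` only `lo`.
#' @param fs sampling rate in Hz.
#' @param type one of `"band"`, `"low"`, `"high"`.
#' @return list with `sos` (sections x 6 matrix: b0 b1 b2 a0 a1 a2), `b`, `a`.
#' @keywords internal
#' @export
butter_design <- function(order = 4, lo = NULL, hi = NULL, fs, type = c("band", "low", "high")) {
  type <- match.arg(type)
  if (fs <= 0) stop("fs must be positive")
  nyq <- fs / 2
  check_edge <- function(f, nm) {
    if (is.null(f) || !is.finite(f) || f <= 0 || f >= nyq)
      stop("invalid band edge ", nm, ": must lie in (0, fs/2)")
  }
  ## analog lowpass prototype poles (unit cutoff)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  warp <- function(f) 2 * fs * tan(pi * f / fs)

  if (type == "band") {
    check_edge(lo, "lo"); check_edge(hi, "hi")
    if (lo >= hi) stop("invalid band: lo must be < hi")
    w1 <- warp(lo); w2 <- warp(hi)
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    ## lowpass -> bandpass: s -> (s^2 + w0^2) / (bw * s)
    p <- c()
    for (pk in p_lp) {
      disc <- sqrt((pk * bw / 2)^2 - w0^2 + 0i)
      p <- c(p, pk * bw / 2 + disc, pk * bw / 2 - disc)
    }
    n_z1 <- order                              # zeros at z = 1 (from s = 0)
    g_f <- sqrt(lo * hi)                       # normalize at band center
  } else if (type == "low") {
    check_edge(hi, "hi")
    p <- p_lp * warp(hi)
    n_z1 <- 0
    g_f <- 0
  } else {
    check_edge(lo, "lo")
    p <- warp(lo) / p_lp
    n_z1 <- order
    g_f <- nyq * 0.999
  }

  ## bilinear transform: s -> 2 fs (z-1)/(z+1); zeros at infinity land on z=-1
  fs2 <- 2 * fs
  pd <- (1 + p / fs2) / (1 - p / fs2)
  n_zm1 <- length(p) - n_z1                    # zeros at z = -1

  ## build second-order sections: conjugate pole pairs (plus a real pole for
  ## odd orders), each paired with zeros drawn from the {+1, -1} pool
  cplx <- pd[Im(pd) > 1e-12]
  realp <- Re(pd[abs(Im(pd)) <= 1e-12])
  pool <- c(rep(1, n_z1), rep(-1, n_zm1))
  sections <- list()
  take_zeros <- function(n) {
    ## prefer one of each sign per section (bandpass); fall back to the pool
    out <- numeric(0)
    for (i in seq_len(n)) {
      pick <- if (any(pool > 0) && any(pool < 0)) {
        if (i %% 2 == 1) which(pool > 0)[1] else which(pool < 0)[1]
      } else seq_along(pool)[1]
      out <- c(out, pool[pick])
      pool <<- pool[-pick]
    }
    out
  }
  for (pk in cplx) {
    z2 <- take_zeros(2)
    sections[[length(sections) + 1]] <- c(
      1, -sum(z2), prod(z2),
      1, -2 * Re(pk), Mod(pk)^2)
  }
  for (pk in realp) {
    z1 <- if (length(pool)) take_zeros(1) else 0
    sections[[length(sections) + 1]] <- c(1, -z1, 0, 1, -pk, 0)
  }
  sos <- do.call(rbind, sections)

  ## unity gain at the reference frequency
  zref <- exp(-1i * 2 * pi * g_f / fs)
  resp <- function(coefs) {
    zz <- zref^(0:2)
    sum(coefs[1:3] * zz) / sum(coefs[4:6] * zz)
  }
  gain <- Mod(prod(vapply(seq_len(nrow(sos)), function(i) resp(sos[i, ]), 0i)))
  sos[1, 1:3] <- sos[1, 1:3] / gain

  ## expanded b/a for reference
  conv <- function(u, v) {
    out <- rep(0, length(u) + length(v) - 1)
    for (i in seq_along(u)) out[i:(i + length(v) - 1)] <- out[i:(i + length(v) - 1)] + u[i] * v
    out
  }
  b <- 1; a <- 1
  for (i in seq_len(nrow(sos))) {
    nz <- if (sos[i, 3] == 0 && sos[i, 6] == 0) 2 else 3
    b <- conv(b, sos[i, seq_len(nz)])
    a <- conv(a, sos[i, 3 + seq_len(nz)])
  }
  list(sos = sos, b = b, a = a)
}

## single-pass IIR filter (direct form) via stats::filter
filter_ba <- function(b, a, x) {
  n <- length(x)
  xp <- c(rep(0, length(b) - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[length(b):(length(b) - 1 + n)]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    as.numeric(y)
  } else v
}

filter_sos <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    x <- filter_ba(sos[i, 1:3], sos[i, 4:6], x)
  }
  x
}

#' Zero-phase forward-backward filtering
#'
#' Applies the second-order-section cascade twice (forward then time-reversed),
#' squaring the magnitude response and cancelling the phase. Transients are
#' controlled by odd-reflection padding at both ends, as in common filtfilt
#' implementations.
#'
#' @param sos sections x 6 coefficient matrix from [butter_design()].
#' @param x numeric vector, or matrix filtered row-wise.
#' @return filtered data, same shape as `x`.
#' @export
filtfilt_sos <- function(sos, x) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- filtfilt_sos(sos, x[i, ])
    return(out)
  }
  n <- length(x)
  pad <- 3 * (2 * nrow(sos) + 1)
  if (n <= pad) pad <- n - 1
  if (pad > 0) {
    pre <- 2 * x[1] - x[(pad + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - pad)]
    xx <- c(pre, x, post)
  } else xx <- x
  y <- filter_sos(sos, xx)
  y <- rev(filter_sos(sos, rev(y)))
  if (pad > 0) y[(pad + 1):(pad + n)] else y
}

#' Zero-phase Butterworth bandpass
#'
#' Fourth-order (per direction) Butterworth bandpass applied forward and
#' backward, the standard zero-phase band separation for EEG.
#'
#' @param x numeric vector or channels-by-samples matrix.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 4).
#' @return filtered data, same shape as `x`.
#' @export
bandpass <- function(x, lo, hi, fs, order = 4) {
  d <- butter_design(order = order, lo = lo, hi = hi, fs = fs, type = "band")
  filtfilt_sos(d$sos, x)
}

#' Zero-phase Butterworth lowpass
#' @inheritParams bandpass
#' @param cutoff corner frequency in Hz.
#' @return filtered data, same shape as `x`.
#' @export
lowpass <- function(x, cutoff, fs, order = 4) {
  d <- butter_design(order = order, hi = cutoff, fs = fs, type = "low")
  filtfilt_sos(d$sos, x)
}
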