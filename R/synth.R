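## Synthetic resting-state EEG cohorts with planted band powers, hemispheric
## asymmetries and envelope correlations, plus the ground truth needed for
## parameter-recovery tests.

#' Default 5-Hz band set
#'
#' Ten non-overlapping 5-Hz bands spanning 1-50 Hz; the first band starts at
#' 1 Hz because of the broadband 1-Hz high-pass.
#'
#' @return data.frame with columns `lo`, `hi`, `name`.
#' @export
default_bands <- function() {
  lo <- c(1, seq(5, 45, by = 5))
  hi <- seq(5, 50, by = 5)
  data.frame(lo = lo, hi = hi, name = paste0(lo, "-", hi, "Hz"),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("lo", "hi") %in% names(bands)))
  if (any(bands$lo >= bands$hi)) stop("bands must have lo < hi")
  if (is.unsorted(bands$lo, strictly = TRUE) || any(bands$hi[-nrow(bands)] > bands$lo[-1]))
    stop("bands must be ascending and non-overlapping")
  invisible(bands)
}

# --- Gauss-Hermite calibration of the envelope nonlinearity ------------------

gauss_hermite <- function(n = 30) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = sqrt(2) * e$values[ord],              # nodes for N(0,1)
       w = (e$vectors[1, ord]^2))                # weights summing to 1
}

## corr(|mu + s*z1|, |mu + s*z2|) for bivariate standard normal (z1,z2) with
## correlation rho, by 2-D Gauss-Hermite quadrature.
envelope_corr_of_latent <- function(rho, mu = 1, s = 0.5, gh = gauss_hermite(30)) {
  e1 <- abs(mu + s * gh$x)
  m1 <- sum(gh$w * e1)
  m2 <- sum(gh$w * e1^2)
  if (abs(rho) >= 1) rho <- sign(rho) * (1 - 1e-12)
  cross <- 0
  for (i in seq_along(gh$x)) {
    z2 <- rho * gh$x[i] + sqrt(1 - rho^2) * gh$x
    cross <- cross + gh$w[i] * sum(gh$w * e1[i] * abs(mu + s * z2))
  }
  (cross - m1^2) / (m2 - m1^2)
}

## inverse of the above: latent Gaussian correlation achieving a target
## envelope correlation.
latent_corr_for_target <- function(target, mu = 1, s = 0.5, gh = gauss_hermite(30)) {
  if (abs(target) >= 1) stop("target envelope correlation must satisfy |r| < 1")
  lo_val <- envelope_corr_of_latent(-0.9999, mu, s, gh)
  if (target <= lo_val) return(-0.9999)
  stats::uniroot(function(r) envelope_corr_of_latent(r, mu, s, gh) - target,
                 c(-0.9999, 0.9999), tol = 1e-6)$root
}

# --- envelope and carrier generators -----------------------------------------

#' Generate correlated, low-pass amplitude envelopes
#'
#' Latent white Gaussian series are correlated via the Cholesky factor of a
#' calibrated latent correlation matrix, low-pass filtered (Butterworth, zero
#' phase), standardized, and mapped through the shifted rectifier
#' `e = |mu + sigma z|`. The latent correlation is calibrated numerically so
#' that the empirical envelope correlations hit `target`.
#'
#' @param n_regions number of envelopes.
#' @param n_samples series length.
#' @param target `n_regions x n_regions` target envelope-correlation matrix
#'   (symmetric, unit diagonal, positive semidefinite).
#' @param fs sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz (default 2, the slow dynamics of EEG
#'   power envelopes).
#' @param seed optional integer; `NULL` uses the current RNG stream.
#' @param mu,sigma shift and scale of the rectifier (modulation depth
#'   `sigma/mu`).
#' @return `n_regions x n_samples` matrix of non-negative envelopes.
#' @export
make_correlated_envelopes <- function(n_regions, n_samples, target = diag(n_regions),
                                      fs, cutoff = 2, seed = NULL,
                                      mu = 1, sigma = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  target <- as.matrix(target)
  stopifnot(nrow(target) == n_regions, ncol(target) == n_regions)
  if (max(abs(target - t(target))) > 1e-8) stop("target must be symmetric")
  if (max(abs(diag(target) - 1)) > 1e-8) stop("target must have unit diagonal")

  if (n_regions == 1) {
    latent <- matrix(stats::rnorm(n_samples), 1)
  } else {
    gh <- gauss_hermite(30)
    L <- diag(n_regions)
    for (i in seq_len(n_regions - 1)) for (j in (i + 1):n_regions) {
      r <- target[i, j]
      L[i, j] <- L[j, i] <- if (r == 0) 0 else latent_corr_for_target(r, mu, sigma, gh)
    }
    ch <- tryCatch(chol(L), error = function(e)
      stop("target correlation matrix is not positive definite (after latent calibration)"))
    latent <- t(matrix(stats::rnorm(n_samples * n_regions), n_samples) %*% ch)
  }
  env <- matrix(0, n_regions, n_samples)
  for (r in seq_len(n_regions)) {
    z <- lowpass(latent[r, ], cutoff, fs)
    z <- (z - mean(z)) / stats::sd(z)
    env[r, ] <- abs(mu + sigma * z)
  }
  env
}

#' Generate a band-limited oscillatory source with a prescribed envelope
#'
#' A constant-modulus band-limited analytic carrier (Fourier coefficients drawn
#' only inside the band, then normalized to unit magnitude) is amplitude
#' modulated by `envelope`. The carrier band is inset from the nominal band
#' edges by a fifth of the bandwidth so the modulation sidebands stay inside
#' the band; the Hilbert envelope of the output therefore tracks `envelope`
#' closely (r >= 0.9 by construction for slow envelopes).
#'
#' @param duration length in seconds.
#' @param fs sampling rate in Hz.
#' @param band numeric `c(lo, hi)` in Hz, inside `(0, fs/2)`.
#' @param envelope non-negative amplitude series of length `duration * fs`,
#'   or a single constant.
#' @param seed optional integer; `NULL` uses the current RNG stream.
#' @return zero-mean numeric vector of length `duration * fs`.
#' @export
make_band_limited_source <- function(duration, fs, band, envelope = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- band[1]; hi <- band[2]
  if (!(lo > 0 && hi > lo && hi < fs / 2)) stop("invalid band: need 0 < lo < hi < fs/2")
  n <- round(duration * fs)
  if (n < 2 * fs / lo) stop("duration too short for the requested band")
  if (length(envelope) == 1) envelope <- rep(envelope, n)
  if (length(envelope) != n) stop("envelope length must equal duration * fs")
  if (any(envelope < 0)) stop("envelope must be non-negative")
  if (all(envelope == 0)) return(numeric(n))

  margin <- (hi - lo) / 5
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= (lo + margin) & f <= (hi - margin)
  if (!any(sel)) sel <- f >= lo & f <= hi
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  k <- sum(sel)
  spec[sel] <- complex(real = stats::rnorm(k), imaginary = stats::rnorm(k))
  a <- stats::fft(spec, inverse = TRUE) / n        # analytic (one-sided) signal
  mod <- Mod(a)
  a <- a / pmax(mod, 1e-12 * max(mod))             # constant-envelope carrier
  s <- envelope * Re(a)
  s - mean(s)
}

#' Analytic-signal amplitude envelope
#'
#' Absolute value of the Hilbert transform (analytic signal magnitude),
#' computed by one-sided FFT masking.
#'
#' @param x numeric vector or channels-by-samples matrix.
#' @return envelope(s), same shape as `x`, non-negative.
#' @export
hilbert_envelope <- function(x) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- hilbert_envelope(x[i, ])
    return(out)
  }
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# --- subject and cohort simulation -------------------------------------------

#' Specification of one synthetic subject
#'
#' @param group `"control"` or `"stroke"`.
#' @param lesion_side `"left"`, `"right"` or `"none"`.
#' @param band_power_profile relative source amplitude per band (length =
#'   number of bands).
#' @param asymmetry_factor per-band left/right source amplitude ratio
#'   (1 = symmetric, > 0).
#' @param envelope_corr_targets data.frame with columns `i`, `j` (region
#'   indices), `band` (band index) and `rho` (target envelope correlation,
#'   |rho| < 1).
#' @param snr source-to-background power ratio (> 0; `Inf` = no noise).
#' @param seed integer seed for this subject's signals.
#' @param bands band definition table (see [default_bands()]).
#' @return list of class `subject_spec`.
#' @export
subject_spec <- function(group = "control", lesion_side = "none",
                         band_power_profile = NULL, asymmetry_factor = NULL,
                         envelope_corr_targets = NULL, snr = 1, seed = 1,
                         bands = default_bands()) {
  nb <- nrow(bands)
  if (is.null(band_power_profile)) band_power_profile <- 1 / sqrt(rowMeans(bands[, c("lo", "hi")]))
  if (is.null(asymmetry_factor)) asymmetry_factor <- rep(1, nb)
  if (length(band_power_profile) != nb || length(asymmetry_factor) != nb)
    stop("profiles must have one entry per band")
  if (any(asymmetry_factor <= 0)) stop("asymmetry_factor must be positive")
  if (!is.null(envelope_corr_targets) && nrow(envelope_corr_targets) > 0) {
    stopifnot(all(c("i", "j", "band", "rho") %in% names(envelope_corr_targets)))
    if (any(abs(envelope_corr_targets$rho) >= 1)) stop("|target correlation| must be < 1")
  }
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  structure(list(group = group, lesion_side = lesion_side,
                 band_power_profile = band_power_profile,
                 asymmetry_factor = asymmetry_factor,
                 envelope_corr_targets = envelope_corr_targets,
                 snr = snr, seed = as.integer(seed), bands = bands),
            class = "subject_spec")
}

#' Mirror-symmetric synthetic region layout
#'
#' Places `floor(n/2)` region centroids on the left hemisphere of the unit
#' sphere (mirrored exactly on the right); an odd count adds one midline
#' region. Labels are `L01..`, `R01..`, `M01`.
#'
#' @param n_regions total number of regions.
#' @return data.frame with `label`, `hemisphere`, `homolog`, `x`, `y`, `z`.
#' @export
region_layout <- function(n_regions) {
  n_half <- n_regions %/% 2
  ap <- seq(-0.7, 0.7, length.out = max(n_half, 2))[seq_len(n_half)]
  lat <- rep(c(0.45, 0.8), length.out = n_half)
  a <- ap * 81 * pi / 180
  b <- lat * 81 * pi / 180
  lx <- -sin(b); ly <- cos(b) * sin(a); lz <- cos(b) * cos(a)
  lab_l <- sprintf("L%02d", seq_len(n_half))
  lab_r <- sprintf("R%02d", seq_len(n_half))
  out <- data.frame(
    label = c(lab_l, lab_r),
    hemisphere = rep(c("left", "right"), each = n_half),
    homolog = c(lab_r, lab_l),
    x = c(lx, -lx), y = c(ly, ly), z = c(lz, lz),
    stringsAsFactors = FALSE)
  if (n_regions %% 2 == 1) {
    out <- rbind(out, data.frame(label = "M01", hemisphere = "midline",
                                 homolog = NA_character_, x = 0, y = 0, z = 1))
  }
  out
}

#' Gaussian volume-conduction mixing matrix
#'
#' Spreads each region source to nearby sensors with a Gaussian spatial kernel
#' in Euclidean distance on the unit sphere; emulates the several-centimetre
#' spatial blur of scalp EEG.
#'
#' @param montage data.frame with sensor `x`, `y`, `z`.
#' @param regions data.frame with region `x`, `y`, `z` (see [region_layout()]).
#' @param width kernel width on the unit sphere (default 0.4, roughly a 4-cm
#'   spread on a 10-cm head).
#' @return sensors x regions matrix, each column peaking at 1.
#' @export
mixing_matrix <- function(montage, regions, width = 0.4) {
  A <- matrix(0, nrow(montage), nrow(regions))
  for (r in seq_len(nrow(regions))) {
    d2 <- (montage$x - regions$x[r])^2 + (montage$y - regions$y[r])^2 +
      (montage$z - regions$z[r])^2
    A[, r] <- exp(-d2 / (2 * width^2))
  }
  A
}

## 1/f (power ~ f^-1) background noise, one channel per row
pink_noise <- function(n_channels, n_samples, fs) {
  f <- (seq_len(n_samples) - 1) * fs / n_samples
  amp <- rep(0, n_samples)
  pos <- f > 0 & f <= fs / 2
  amp[pos] <- 1 / sqrt(pmax(f[pos], 1))            # flat below 1 Hz
  out <- matrix(0, n_channels, n_samples)
  for (i in seq_len(n_channels)) {
    spec <- complex(real = stats::rnorm(n_samples), imaginary = stats::rnorm(n_samples)) * amp
    x <- Re(stats::fft(spec, inverse = TRUE) / n_samples)
    out[i, ] <- x - mean(x)
  }
  out
}

#' Simulate one subject's recording
#'
#' Band-limited region sources (with planted per-band power, left-hemisphere
#' asymmetry and envelope correlations) are mixed linearly to the sensors and
#' buried in 1/f background noise at the requested SNR.
#'
#' @param spec a [subject_spec()].
#' @param montage sensor table from [standard_montage()].
#' @param n_regions number of regions (even = fully paired).
#' @param duration recording length in seconds (default 180).
#' @param fs sampling rate in Hz (default 1000).
#' @param mixing optional sensors x regions matrix; default Gaussian kernel
#'   from [mixing_matrix()]. `"identity"` requires `n_regions == nrow(montage)`.
#' @param kernel_width Gaussian kernel width for the default mixing.
#' @param subject_id identifier stored in the recording.
#' @return list with elements `recording` ([eeg_recording()]) and `truth`
#'   (planted asymmetry signs/factors per band, planted edges, mixing matrix,
#'   region layout, region source series).
#' @export
simulate_subject <- function(spec, montage = standard_montage(64), n_regions = 10,
                             duration = 180, fs = 1000, mixing = NULL,
                             kernel_width = 0.4, subject_id = "subject") {
  stopifnot(inherits(spec, "subject_spec"))
  set.seed(spec$seed)
  regions <- region_layout(n_regions)
  n <- round(duration * fs)
  bands <- spec$bands
  nb <- nrow(bands)
  left_idx <- which(regions$hemisphere == "left")

  S <- matrix(0, n_regions, n)
  for (b in seq_len(nb)) {
    if (spec$band_power_profile[b] == 0) next
    target <- diag(n_regions)
    ect <- spec$envelope_corr_targets
    if (!is.null(ect)) {
      rows <- ect[ect$band == b, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        target[rows$i[k], rows$j[k]] <- rows$rho[k]
        target[rows$j[k], rows$i[k]] <- rows$rho[k]
      }
    }
    env <- make_correlated_envelopes(n_regions, n, target, fs)
    amp <- rep(spec$band_power_profile[b], n_regions)
    amp[left_idx] <- amp[left_idx] * spec$asymmetry_factor[b]
    for (r in seq_len(n_regions)) {
      s <- make_band_limited_source(duration, fs, c(bands$lo[b], bands$hi[b]), env[r, ])
      rms <- sqrt(mean(s^2))
      if (rms > 0) s <- s / rms               # planted band power is exact
      S[r, ] <- S[r, ] + amp[r] * s
    }
  }

  if (is.null(mixing)) {
    A <- mixing_matrix(montage, regions, kernel_width)
  } else if (identical(mixing, "identity")) {
    if (n_regions != nrow(montage)) stop("identity mixing needs n_regions == n_sensors")
    A <- diag(n_regions)
  } else {
    A <- as.matrix(mixing)
    if (ncol(A) != n_regions || nrow(A) != nrow(montage)) stop("mixing dimension mismatch")
  }
  X <- A %*% S
  if (is.finite(spec$snr)) {
    noise <- pink_noise(nrow(X), n, fs)
    sig_pow <- mean(X^2)
    noise <- noise * sqrt(sig_pow / spec$snr / mean(noise^2))
    X <- X + noise
  }
  X <- X * (20 / sqrt(mean(X^2)))                  # ~20 uV RMS, arbitrary gain

  rec <- eeg_recording(X, fs, montage$label, montage, group = spec$group,
                       lesion_side = spec$lesion_side, subject_id = subject_id)
  truth <- list(
    asymmetry_factor = spec$asymmetry_factor,
    eda_sign = sign(spec$asymmetry_factor - 1),
    band_power_profile = spec$band_power_profile,
    edges = spec$envelope_corr_targets,
    mixing = A, regions = regions, bands = bands,
    region_series = S)
  list(recording = rec, truth = truth)
}

#' Planted group effects for a synthetic cohort
#'
#' Defaults encode the study's qualitative findings as the generative truth:
#' controls have a 1/f band-power profile, symmetric hemispheres, and moderate
#' envelope coupling on a fixed connected edge set (a four-region clique
#' spanning both hemispheres) in every band;
#' stroke subjects lose source power in the 10-20 Hz bands, lose
#' left-hemisphere amplitude in the 15-50 Hz bands, lose envelope coupling in
#' the 10-20 Hz bands and gain it at 35-40 Hz.
#'
#' @param bands band table.
#' @param n_regions region count (paired layout, see [region_layout()]).
#' @param power_deficit_bands,power_deficit amplitude scaling of stroke source
#'   power (bands indices; default 10-20 Hz at amplitude x0.7 = half power).
#' @param asym_bands,asym_factor stroke left-hemisphere amplitude ratio
#'   (default 15-50 Hz at 0.6).
#' @param conn_rho baseline planted envelope correlation.
#' @param conn_deficit_bands,conn_deficit_rho stroke planted correlation in
#'   the deficit bands.
#' @param conn_gain_bands,conn_gain_rho stroke planted correlation in the
#'   gain band.
#' @param snr source-to-noise power ratio for every subject.
#' @param subject_sd log-normal between-subject variability of band power.
#' @return list of class `cohort_effects`.
#' @export
cohort_effects <- function(bands = default_bands(), n_regions = 10,
                           power_deficit_bands = 3:4, power_deficit = sqrt(0.5),
                           asym_bands = 4:10, asym_factor = 0.6,
                           conn_rho = 0.6,
                           conn_deficit_bands = 3:4, conn_deficit_rho = 0.15,
                           conn_gain_bands = 8, conn_gain_rho = 0.85,
                           snr = 1, subject_sd = 0.1) {
  n_half <- n_regions %/% 2
  if (n_half < 3) stop("need at least 6 regions for the planted edge set")
  ## planted edges: a connected 4-clique spanning both hemispheres (about half
  ## the edges interhemispheric, as in observed stroke difference networks),
  ## mirror-symmetric within hemispheres so control CDA stays near zero
  nodes <- c(1, 2, n_half + 1, n_half + 2)
  pr <- utils::combn(4, 2)
  edges <- cbind(nodes[pr[1, ]], nodes[pr[2, ]])
  structure(list(bands = bands, n_regions = n_regions,
                 power_deficit_bands = power_deficit_bands,
                 power_deficit = power_deficit,
                 asym_bands = asym_bands, asym_factor = asym_factor,
                 conn_rho = conn_rho,
                 conn_deficit_bands = conn_deficit_bands,
                 conn_deficit_rho = conn_deficit_rho,
                 conn_gain_bands = conn_gain_bands,
                 conn_gain_rho = conn_gain_rho,
                 snr = snr, subject_sd = subject_sd,
                 edges = edges),
            class = "cohort_effects")
}

#' Simulate a two-group cohort
#'
#' @param n_control,n_stroke group sizes (defaults 11 and 14, the study's
#'   cohort).
#' @param effects a [cohort_effects()] configuration.
#' @param montage sensor table.
#' @param duration,fs recording length (s) and sampling rate (Hz).
#' @param seed integer master seed; each subject gets a derived seed.
#' @return list of per-subject lists (`recording`, `truth`); attribute
#'   `effects` carries the planted configuration.
#' @export
simulate_cohort <- function(n_control = 11, n_stroke = 14,
                            effects = cohort_effects(),
                            montage = standard_montage(64),
                            duration = 180, fs = 1000, seed = 1) {
  stopifnot(n_control >= 1, n_stroke >= 1)
  bands <- effects$bands
  nb <- nrow(bands)
  base_profile <- 1 / sqrt(rowMeans(bands[, c("lo", "hi")]))
  edge_df <- function(rho_per_band) {
    do.call(rbind, lapply(seq_len(nb), function(b) {
      data.frame(i = effects$edges[, 1], j = effects$edges[, 2],
                 band = b, rho = rho_per_band[b])
    }))
  }
  ctrl_rho <- rep(effects$conn_rho, nb)
  strk_rho <- ctrl_rho
  strk_rho[effects$conn_deficit_bands] <- effects$conn_deficit_rho
  strk_rho[effects$conn_gain_bands] <- effects$conn_gain_rho

  set.seed(seed)
  subject_seeds <- sample.int(2^31 - 2, n_control + n_stroke)
  subject_jitter <- stats::rnorm(n_control + n_stroke, 0, effects$subject_sd)

  out <- vector("list", n_control + n_stroke)
  for (s in seq_len(n_control + n_stroke)) {
    is_stroke <- s > n_control
    profile <- base_profile * exp(subject_jitter[s])
    asym <- rep(1, nb)
    if (is_stroke) {
      profile[effects$power_deficit_bands] <-
        profile[effects$power_deficit_bands] * effects$power_deficit
      asym[effects$asym_bands] <- effects$asym_factor
    }
    sp <- subject_spec(
      group = if (is_stroke) "stroke" else "control",
      lesion_side = if (is_stroke) "left" else "none",
      band_power_profile = profile, asymmetry_factor = asym,
      envelope_corr_targets = edge_df(if (is_stroke) strk_rho else ctrl_rho),
      snr = effects$snr, seed = subject_seeds[s], bands = bands)
    out[[s]] <- simulate_subject(
      sp, montage, effects$n_regions, duration, fs,
      subject_id = sprintf("%s%02d", if (is_stroke) "S" else "C",
                           if (is_stroke) s - n_control else s))
  }
  attr(out, "effects") <- effects
  out
}

#' Write a subject's ground truth as JSON
#'
#' @param truth the `truth` element from [simulate_subject()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  keep <- truth[c("asymmetry_factor", "eda_sign", "band_power_profile", "edges")]
  keep$regions <- truth$regions[, c("label", "hemisphere", "homolog")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
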