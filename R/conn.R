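## Leakage-corrected amplitude-envelope connectivity: symmetric multivariate
## orthogonalization (removes shared zero-lag components without privileging a
## seed), Hilbert envelopes, Pearson envelope correlation with Fisher z, and a
## phase-randomization Monte-Carlo null that converts connectivity to bias-
## corrected z-scores comparable across frequency bands.

#' Symmetric multivariate orthogonalization
#'
#' Finds the set of mutually uncorrelated (zero-lag orthogonal) series closest
#' in total squared error to the input, by the iterative closest-orthonormal-
#' basis scheme: alternately (1) fit the closest orthonormal basis to the
#' scaled signals via polar decomposition (SVD) and (2) refit each region's
#' scale by projection. Runs a fixed number of iterations (default 20) with no
#' early stopping.
#'
#' @param X regions x samples matrix; region count must not exceed the rank
#'   of the data.
#' @param iterations fixed iteration count (default 20).
#' @return regions x samples matrix with pairwise zero-lag correlations < 1e-6.
#' @export
symmetric_orthogonalize <- function(X, iterations = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two regions")
  Xc <- X - rowMeans(X)
  sv <- svd(t(Xc), nu = 0, nv = 0)
  if (sv$d[n] < 1e-10 * sv$d[1])
    stop("rank deficiency: region count exceeds the rank of the data")
  A <- t(Xc)                                  # samples x regions
  d <- rep(1, n)
  P <- NULL
  for (it in seq_len(iterations)) {
    s <- svd(A %*% diag(d, n))
    P <- s$u %*% t(s$v)                       # closest orthonormal basis
    d <- colSums(A * P)                       # per-region scale refit
  }
  Y <- P %*% diag(d, n)
  t(Y)
}

#' Envelope correlation and Fisher z
#'
#' Pearson correlation matrix of amplitude envelopes with `atanh` transform of
#' the off-diagonal entries. Perfect correlations (|r| = 1) map to `NA` rather
#' than infinity; zero-variance envelopes yield `NA` edges with a warning.
#'
#' @param envelopes regions x samples matrix of non-negative envelopes.
#' @param sample_mask optional logical vector (length = samples) selecting the
#'   samples entering the correlation (used to exclude epoch-junction
#'   transients).
#' @return list with symmetric matrices `r` and `fisher_z` (diagonal `NA`).
#' @export
envelope_correlation <- function(envelopes, sample_mask = NULL) {
  E <- as.matrix(envelopes)
  if (nrow(E) < 2) stop("need at least two regions")
  if (!is.null(sample_mask)) E <- E[, sample_mask, drop = FALSE]
  sds <- apply(E, 1, stats::sd)
  if (any(sds == 0)) warning("zero-variance envelope; its edges set to NA")
  r <- suppressWarnings(stats::cor(t(E)))
  r[!is.finite(r)] <- NA
  diag(r) <- NA
  z <- r
  perfect <- !is.na(r) & abs(r) >= 1 - 1e-12
  z[perfect] <- NA
  z[!is.na(z)] <- atanh(z[!is.na(z)])
  list(r = r, fisher_z = z)
}

#' Phase-randomization surrogate
#'
#' Replaces the phase of every Fourier coefficient with an independent uniform
#' draw (independently per region and per frequency bin; DC and Nyquist stay
#' real) while keeping the amplitude spectrum exactly, so each region's power
#' spectrum and autocovariance are preserved but cross-region envelope
#' coupling is destroyed in expectation.
#'
#' @param X regions x samples matrix.
#' @param seed optional integer; `NULL` uses the current RNG stream.
#' @return surrogate matrix, same shape.
#' @export
phase_randomize <- function(X, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- ncol(X)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  out <- X
  for (i in seq_len(nrow(X))) {
    F <- stats::fft(X[i, ])
    ph <- stats::runif(half, 0, 2 * pi)
    rot <- exp(1i * ph)
    F[2:(half + 1)] <- Mod(F[2:(half + 1)]) * rot
    F[n:(n - half + 1)] <- Conj(F[2:(half + 1)])
    if (n %% 2 == 0) F[n / 2 + 1] <- Mod(F[n / 2 + 1]) * sample(c(-1, 1), 1)
    out[i, ] <- Re(stats::fft(F, inverse = TRUE) / n)
  }
  out
}

#' Monte-Carlo surrogate null for envelope connectivity
#'
#' Repeatedly phase-randomizes the region series and re-runs the full
#' downstream pipeline (orthogonalization unless `skip_orthogonalization`,
#' Hilbert envelope, correlation, Fisher z), accumulating the per-edge mean
#' and SD of the null Fisher-z distribution.
#'
#' @param X regions x samples matrix (band-limited region series).
#' @param n_iter Monte-Carlo iterations (study default 1000; desk-scale
#'   default 200).
#' @param seed integer seed.
#' @param orth_iterations orthogonalization iterations.
#' @param skip_orthogonalization drop the orthogonalization step in the null
#'   pipeline (speed option, default FALSE).
#' @param sample_mask optional sample mask forwarded to the correlation.
#' @return list of class `surrogate_null` with `mean`, `sd` (regions x
#'   regions), `n_iterations`, `seed`.
#' @export
surrogate_null <- function(X, n_iter = 200, seed = 1, orth_iterations = 20,
                           skip_orthogonalization = FALSE, sample_mask = NULL) {
  if (n_iter < 2) stop("n_iter must be at least 2")
  set.seed(seed)
  n <- nrow(X)
  s1 <- matrix(0, n, n); s2 <- matrix(0, n, n)
  for (it in seq_len(n_iter)) {
    Xs <- phase_randomize(X)
    if (!skip_orthogonalization) Xs <- symmetric_orthogonalize(Xs, orth_iterations)
    z <- envelope_correlation(hilbert_envelope(Xs), sample_mask)$fisher_z
    z[is.na(z)] <- 0
    s1 <- s1 + z
    s2 <- s2 + z^2
  }
  mu <- s1 / n_iter
  sd <- sqrt(pmax(s2 / n_iter - mu^2, 0) * n_iter / (n_iter - 1))
  diag(mu) <- NA; diag(sd) <- NA
  structure(list(mean = mu, sd = sd, n_iterations = n_iter, seed = seed),
            class = "surrogate_null")
}

#' Bias-correct Fisher-z connectivity against a surrogate null
#'
#' `z = (fisher_z - null mean) / null SD` per edge, converting connectivity to
#' a z-score relative to the phase-randomization null and removing the
#' band-dependent correlation bias of finite windows.
#'
#' @param fisher_z regions x regions Fisher-z matrix.
#' @param null a [surrogate_null()].
#' @return regions x regions matrix of bias-corrected z-scores.
#' @export
bias_correct <- function(fisher_z, null) {
  stopifnot(inherits(null, "surrogate_null"),
            all(dim(fisher_z) == dim(null$mean)))
  sd <- null$sd
  bad <- !is.na(sd) & sd == 0
  if (any(bad)) {
    warning("zero surrogate SD at ", sum(bad) / 2, " edge(s); set to NA")
    sd[bad] <- NA
  }
  (fisher_z - null$mean) / sd
}

#' Per-band connectivity for one subject
#'
#' The full region-level chain for one band: symmetric orthogonalization,
#' Hilbert envelopes, envelope correlation, Fisher z, surrogate null and bias
#' correction. Samples within `junction_pad` of an epoch junction are excluded
#' from the correlations (filter transients concentrate there).
#'
#' @param X regions x samples band-limited region series (epochs
#'   concatenated).
#' @param junctions sample indices of epoch junctions (from
#'   [concatenate_epochs()]).
#' @param junction_pad samples masked on each side of a junction (default 12 =
#'   3x filter order).
#' @param n_null surrogate iterations.
#' @param seed surrogate seed.
#' @param orth_iterations orthogonalization iterations.
#' @param skip_null skip bias correction (returns `z_bias_corrected = NULL`).
#' @param skip_orthogonalization drop orthogonalization from the observed AND
#'   null pipelines (rarely wanted).
#' @param null_skip_orthogonalization drop orthogonalization from the
#'   surrogate pipeline only, keeping it for the observed data (speed option;
#'   default off so the null matches the observed pipeline).
#' @return list with `r`, `fisher_z`, `z_bias_corrected`, `null`.
#' @export
band_connectivity <- function(X, junctions = integer(0), junction_pad = 12,
                              n_null = 200, seed = 1, orth_iterations = 20,
                              skip_null = FALSE, skip_orthogonalization = FALSE,
                              null_skip_orthogonalization = FALSE) {
  n_samp <- ncol(X)
  mask <- rep(TRUE, n_samp)
  for (j in junctions) {
    lo <- max(1, j - junction_pad + 1); hi <- min(n_samp, j + junction_pad)
    mask[lo:hi] <- FALSE
  }
  Xo <- if (skip_orthogonalization) X else symmetric_orthogonalize(X, orth_iterations)
  ec <- envelope_correlation(hilbert_envelope(Xo), mask)
  if (skip_null) {
    return(list(r = ec$r, fisher_z = ec$fisher_z, z_bias_corrected = NULL, null = NULL))
  }
  nul <- surrogate_null(X, n_iter = n_null, seed = seed,
                        orth_iterations = orth_iterations,
                        skip_orthogonalization = skip_orthogonalization ||
                          null_skip_orthogonalization,
                        sample_mask = mask)
  list(r = ec$r, fisher_z = ec$fisher_z,
       z_bias_corrected = bias_correct(ec$fisher_z, nul), null = nul)
}

# ---------------------------------------------------------------------------

## index helpers over a hemisphere map (character vector "left"/"right"/
## "midline" aligned with matrix rows)
.homolog_index <- function(labels, hemispheres, homologs) {
  match(homologs, labels)
}

#' Connectivity directional asymmetry
#'
#' `CDA = 100 * mean((C_L - C_R) / (C_L + C_R))` over homologous
#' within-hemisphere edge pairs: every left-hemisphere edge (i, j) is paired
#' with the mirrored right-hemisphere edge (i', j'). Inter-hemispheric edges
#' and edges between a region and its own mirror are excluded. Positive values
#' mean stronger connectivity in the left (lesioned) hemisphere.
#'
#' @param C regions x regions connectivity matrix (one band).
#' @param hemispheres character vector (`"left"`, `"right"`, `"midline"`) per
#'   region, aligned with the rows of `C`.
#' @param homolog_index integer vector: row index of each region's mirror
#'   (`NA` for midline).
#' @return list with `value` (percent) and `n_pairs`.
#' @export
connectivity_directional_asymmetry <- function(C, hemispheres, homolog_index) {
  n <- nrow(C)
  stopifnot(length(hemispheres) == n, length(homolog_index) == n)
  left <- which(hemispheres == "left")
  num <- c(); den <- c()
  if (length(left) >= 2) {
    pr <- utils::combn(left, 2)
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      im <- homolog_index[i]; jm <- homolog_index[j]
      if (is.na(im) || is.na(jm)) next
      cl <- C[i, j]; cr <- C[im, jm]
      if (is.na(cl) || is.na(cr)) next
      num <- c(num, cl - cr); den <- c(den, cl + cr)
    }
  }
  ok <- den != 0
  if (any(!ok)) warning("skipping ", sum(!ok), " edge pair(s) with zero C_L + C_R")
  if (!any(ok)) return(list(value = NA_real_, n_pairs = 0L))
  list(value = 100 * mean(num[ok] / den[ok]), n_pairs = sum(ok))
}

#' Within-hemisphere connectivity spectrum
#'
#' Mean connectivity (bias-corrected z) over all edges with both endpoints in
#' one hemisphere, per band.
#'
#' @param stack regions x regions x bands array of bias-corrected z.
#' @param hemispheres per-region hemisphere labels.
#' @param hemisphere `"left"` or `"right"`.
#' @return numeric vector, one mean connectivity value per band.
#' @export
connectivity_spectrum <- function(stack, hemispheres, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  idx <- which(hemispheres == hemisphere)
  if (length(idx) < 2) stop("need at least two regions in the hemisphere")
  nb <- dim(stack)[3]
  vapply(seq_len(nb), function(b) {
    M <- stack[idx, idx, b]
    mean(M[upper.tri(M)], na.rm = TRUE)
  }, 0)
}

#' Correlation of a connectivity spectrum with a reference
#'
#' Pearson correlation across bands between a subject's spectrum and a
#' reference (typically the control-group mean spectrum), Fisher z-transformed
#' with |r| capped just below 1 so the result stays finite.
#'
#' @param spectrum subject spectrum (length = bands).
#' @param reference reference spectrum (same length).
#' @return Fisher z of the correlation.
#' @export
spectrum_correlation <- function(spectrum, reference) {
  if (length(spectrum) < 2 || length(spectrum) != length(reference))
    stop("spectra must have equal length >= 2")
  if (stats::sd(spectrum) == 0 || stats::sd(reference) == 0)
    stop("constant spectrum: correlation undefined")
  r <- stats::cor(spectrum, reference)
  cap <- 1 - 1e-12
  atanh(max(min(r, cap), -cap))
}
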