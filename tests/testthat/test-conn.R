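# Orthogonalization, envelopes, envelope correlation, surrogates, bias
# correction, connectivity asymmetry and spectra.

test_that("orthogonalization leaves an already-orthogonal set unchanged", {
  n <- 600
  t <- seq_len(n)
  X <- rbind(sin(2 * pi * t / 50), cos(2 * pi * t / 50), sin(2 * pi * t / 25))
  X <- X - rowMeans(X)
  # make rows exactly orthogonal via Gram-Schmidt
  X[2, ] <- X[2, ] - sum(X[2, ] * X[1, ]) / sum(X[1, ]^2) * X[1, ]
  X[3, ] <- X[3, ] - sum(X[3, ] * X[1, ]) / sum(X[1, ]^2) * X[1, ] -
    sum(X[3, ] * X[2, ]) / sum(X[2, ]^2) * X[2, ]
  Y <- symmetric_orthogonalize(X)
  expect_lt(max(abs(Y - X)), 1e-8 * max(abs(X)))
})

test_that("two-signal case matches the closed-form Loewdin oracle", {
  set.seed(1)
  n <- 2000
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)   # r ~ 0.5, equal norms
  a <- a / sd(a); b <- b / sd(b)
  X <- rbind(a - mean(a), b - mean(b))
  Y <- symmetric_orthogonalize(X)
  oracle <- loewdin_pair_oracle(X)
  expect_lt(max(abs(Y - oracle)), 1e-6)
  expect_lt(abs(cor(Y[1, ], Y[2, ])), 1e-6)
})

test_that("orthogonalization residual correlations vanish on random inputs", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(8 * 3000), 8) + rep(1, 8) %o% rnorm(3000)  # shared leak
    Y <- symmetric_orthogonalize(X)
    r <- cor(t(Y))
    expect_lt(max(abs(r[upper.tri(r)])), 1e-6)
  }
})

test_that("rank-deficient input is rejected before iterating", {
  set.seed(2)
  x <- rnorm(500)
  expect_error(symmetric_orthogonalize(rbind(x, x, rnorm(500))),
               "rank deficiency")
})

test_that("Hilbert envelope recovers sinusoid amplitude and modulators", {
  fs <- 1000
  t <- seq_len(10 * fs) / fs
  env <- hilbert_envelope(sin(2 * pi * 10 * t))
  expect_gt(median(env), 0.99)
  expect_lt(median(env), 1.01)
  expect_true(all(hilbert_envelope(rep(0, 1000)) == 0))
  mod <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  am <- mod * sin(2 * pi * 20 * t)
  expect_gte(cor(hilbert_envelope(am)[1000:9000], mod[1000:9000]), 0.99)
})

test_that("envelope correlation handles perfect, absent and exact cases", {
  set.seed(3)
  e <- abs(rnorm(5000)) + 0.1
  ec <- envelope_correlation(rbind(e, e))
  expect_equal(ec$r[1, 2], 1)
  expect_true(is.na(ec$fisher_z[1, 2]))       # atanh(1) guarded to missing
  e2 <- abs(rnorm(5000)) + 0.1
  ec2 <- envelope_correlation(rbind(e, e2))
  expect_lt(abs(ec2$r[1, 2]), 0.05)
  # atanh closed form
  x <- rnorm(100000)
  y <- 0.5 * x + sqrt(0.75) * rnorm(100000)
  ec3 <- envelope_correlation(rbind(x, y))
  expect_equal(ec3$fisher_z[1, 2], atanh(ec3$r[1, 2]))
  expect_lt(abs(ec3$fisher_z[1, 2] - 0.5493), 0.02)
  expect_warning(envelope_correlation(rbind(e, rep(1, 5000))), "zero-variance")
})

test_that("phase randomization preserves each amplitude spectrum exactly", {
  set.seed(4)
  X <- matrix(rnorm(3 * 1024), 3)
  Xs <- phase_randomize(X, seed = 5)
  for (i in 1:3) {
    expect_lt(max(abs(Mod(fft(Xs[i, ])) - Mod(fft(X[i, ])))) / max(Mod(fft(X[i, ]))),
              1e-10)
    expect_true(all(abs(Im(fft(Xs[i, ])[1])) < 1e-8))
  }
  # Wiener-Khinchin: the circular autocovariance is preserved exactly; the
  # linear acf agrees up to O(lag/n) boundary terms
  circ_acov <- function(x) Re(fft(Mod(fft(x))^2, inverse = TRUE)) / length(x)^2
  expect_equal(circ_acov(Xs[1, ])[1:21], circ_acov(X[1, ])[1:21],
               tolerance = 1e-10)
  ac1 <- acf(X[1, ], lag.max = 20, plot = FALSE, demean = FALSE)$acf
  ac2 <- acf(Xs[1, ], lag.max = 20, plot = FALSE, demean = FALSE)$acf
  expect_lt(max(abs(ac1 - ac2)), 0.1)
})

test_that("surrogates destroy cross-region envelope coupling on average", {
  fs <- 100
  env <- make_correlated_envelopes(1, 40 * fs, diag(1), fs, seed = 6)[1, ]
  x <- make_band_limited_source(40, fs, c(10, 15), env, seed = 7)
  y <- make_band_limited_source(40, fs, c(10, 15), env, seed = 8)
  X <- rbind(x, y)
  r0 <- envelope_correlation(hilbert_envelope(X))$r[1, 2]
  expect_gt(r0, 0.9)
  rs <- vapply(1:50, function(s) {
    Xs <- phase_randomize(X, seed = s)
    envelope_correlation(hilbert_envelope(Xs))$r[1, 2]
  }, 0)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(50) + 0.02)
})

test_that("surrogate null is seeded, positive-SD, and centered for white noise", {
  set.seed(9)
  X <- matrix(rnorm(6 * 2000), 6)
  n1 <- surrogate_null(X, n_iter = 60, seed = 42)
  n2 <- surrogate_null(X, n_iter = 60, seed = 42)
  expect_identical(n1$mean, n2$mean)
  expect_identical(n1$sd, n2$sd)
  off <- upper.tri(n1$sd)
  expect_true(all(n1$sd[off] > 0))
  # CLT bound on the null mean of independent regions
  expect_true(all(abs(n1$mean[off]) < 3 * n1$sd[off] / sqrt(60) + 0.05))
})

test_that("bias correction maps the null mean to zero and guards zero SD", {
  nul <- structure(list(mean = matrix(c(NA, 0.3, 0.3, NA), 2),
                        sd = matrix(c(NA, 0.1, 0.1, NA), 2),
                        n_iterations = 10L, seed = 1L),
                   class = "surrogate_null")
  fz <- matrix(c(NA, 0.3, 0.3, NA), 2)
  expect_equal(bias_correct(fz, nul)[1, 2], 0)
  nul$sd[1, 2] <- nul$sd[2, 1] <- 0
  expect_warning(z <- bias_correct(fz, nul), "zero surrogate SD")
  expect_true(is.na(z[1, 2]))
})

test_that("a strongly planted edge dominates the corrected z matrix", {
  fs <- 100
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    target <- diag(4); target[1, 2] <- target[2, 1] <- 0.8
    env <- make_correlated_envelopes(4, 40 * fs, target, fs)
    X <- t(vapply(1:4, function(r)
      make_band_limited_source(40, fs, c(10, 15), env[r, ]), numeric(40 * fs)))
    bc <- band_connectivity(X, n_null = 40, seed = s)
    z <- bc$z_bias_corrected
    max_edge <- which(z == max(z, na.rm = TRUE), arr.ind = TRUE)[1, ]
    all(sort(max_edge) == c(1, 2))
  }, TRUE)
  expect_true(all(hits))
})

test_that("orthogonalized envelope correlation is robust to region gain", {
  # the scale-refit scheme is not exactly gain-invariant; deviations stay small
  set.seed(10)
  X <- matrix(rnorm(5 * 3000), 5) + rep(1, 5) %o% rnorm(3000)
  r1 <- envelope_correlation(hilbert_envelope(symmetric_orthogonalize(X)))$r
  X2 <- X; X2[3, ] <- 3 * X[3, ]
  r2 <- envelope_correlation(hilbert_envelope(symmetric_orthogonalize(X2)))$r
  expect_lt(max(abs(r1 - r2), na.rm = TRUE), 0.05)
})

test_that("CDA evaluates homologous edge pairs with the stated sign", {
  hem <- c("left", "left", "right", "right")
  hom <- c(3L, 4L, 1L, 2L)
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 3                     # left edge
  C[3, 4] <- C[4, 3] <- 1                     # mirrored right edge
  out <- connectivity_directional_asymmetry(C, hem, hom)
  expect_equal(out$value, 50)
  expect_equal(out$n_pairs, 1L)
  # mirror-symmetric connectivity: zero asymmetry
  C[3, 4] <- C[4, 3] <- 3
  expect_equal(connectivity_directional_asymmetry(C, hem, hom)$value, 0)
  # relabeling hemispheres flips the sign
  C[3, 4] <- C[4, 3] <- 1
  hem_sw <- c("right", "right", "left", "left")
  expect_equal(connectivity_directional_asymmetry(C, hem_sw, hom)$value, -50)
})

test_that("connectivity spectra and their correlations behave as stated", {
  set.seed(11)
  nb <- 10
  stack <- array(rnorm(6 * 6 * nb), c(6, 6, nb))
  for (b in seq_len(nb)) {
    stack[, , b] <- (stack[, , b] + t(stack[, , b])) / 2
    diag(stack[, , b]) <- NA
  }
  hem <- rep(c("left", "right"), each = 3)
  sp <- connectivity_spectrum(stack, hem, "left")
  expect_length(sp, nb)
  # hand oracle for one band: mean of the 3 within-left edges
  expect_equal(sp[4], mean(stack[1:3, 1:3, 4][upper.tri(diag(3))]))
  # self-correlation is capped, not infinite
  z_self <- spectrum_correlation(sp, sp)
  expect_true(is.finite(z_self))
  expect_equal(z_self, atanh(1 - 1e-12))
  # exact anticorrelation on toy spectra
  expect_equal(spectrum_correlation(1:10, 10:1), atanh(-(1 - 1e-12)))
  # hand Pearson on two printed toy vectors
  a <- c(2, 4, 4, 4, 5, 5, 7, 9, 3, 1)
  b <- c(1, 3, 5, 2, 6, 4, 8, 8, 2, 2)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(spectrum_correlation(a, b), atanh(r_hand))
  expect_error(spectrum_correlation(rep(1, 10), 1:10), "constant spectrum")
})
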