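# Synthetic cohort generator: spectral placement, envelope control, planted
# asymmetries, determinism.

test_that("band-limited source concentrates >= 90% power in its band", {
  fs <- 1000
  s <- make_band_limited_source(60, fs, c(10, 15), envelope = 1, seed = 2)
  sp <- Mod(fft(s))^2
  f <- (seq_along(s) - 1) * fs / length(s)
  frac <- sum(sp[f >= 10 & f <= 15]) / sum(sp[f > 0 & f <= fs / 2])
  expect_gte(frac, 0.9)
  expect_lt(abs(mean(s)), 1e-12)
})

test_that("zero envelope gives the all-zero signal", {
  s <- make_band_limited_source(10, 200, c(5, 10), envelope = 0, seed = 1)
  expect_true(all(s == 0))
})

test_that("Hilbert envelope of a source tracks the requested envelope", {
  fs <- 500
  env <- make_correlated_envelopes(1, 30 * fs, diag(1), fs, seed = 4)[1, ]
  s <- make_band_limited_source(30, fs, c(10, 15), env, seed = 5)
  expect_gte(cor(hilbert_envelope(s), env), 0.9)
})

test_that("two sources sharing an envelope have correlated envelopes", {
  fs <- 500
  env <- make_correlated_envelopes(1, 30 * fs, diag(1), fs, seed = 6)[1, ]
  s1 <- make_band_limited_source(30, fs, c(10, 15), env, seed = 7)
  s2 <- make_band_limited_source(30, fs, c(10, 15), env, seed = 8)
  expect_gte(cor(hilbert_envelope(s1), hilbert_envelope(s2)), 0.9)
})

test_that("invalid band or envelope is rejected", {
  expect_error(make_band_limited_source(10, 100, c(40, 60), 1, 1), "invalid band")
  expect_error(make_band_limited_source(10, 100, c(5, 10), rep(1, 7), 1), "length")
  expect_error(make_band_limited_source(10, 100, c(5, 10), rep(-1, 1000), 1),
               "non-negative")
})

test_that("correlated envelopes hit their targets within 0.1", {
  fs <- 100; n <- 60 * fs
  target <- diag(3)
  target[1, 2] <- target[2, 1] <- 0.6
  target[2, 3] <- target[3, 2] <- -0.3
  env <- make_correlated_envelopes(3, n, target, fs, seed = 9)
  expect_true(all(env >= 0))
  emp <- cor(t(env))
  expect_lt(abs(emp[1, 2] - 0.6), 0.1)
  expect_lt(abs(emp[2, 3] + 0.3), 0.1)
  expect_lt(abs(emp[1, 3]), 0.1)
})

test_that("identity target yields near-independent envelopes", {
  fs <- 100
  env <- make_correlated_envelopes(4, 60 * fs, diag(4), fs, seed = 10)
  emp <- cor(t(env))
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.1)
})

test_that("near-unity targets survive the calibration (Monte Carlo)", {
  fs <- 100
  target <- matrix(c(1, 0.99, 0.99, 1), 2)
  r <- vapply(1:20, function(s) {
    env <- make_correlated_envelopes(2, 60 * fs, target, fs, seed = s)
    cor(env[1, ], env[2, ])
  }, 0)
  expect_true(all(r >= 0.85))
})

test_that("single region needs no correlation structure", {
  env <- make_correlated_envelopes(1, 500, diag(1), fs = 100, seed = 1)
  expect_equal(dim(env), c(1L, 500L))
})

test_that("non-PSD target is rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(make_correlated_envelopes(3, 1000, bad, fs = 100, seed = 1),
               "positive definite")
})

test_that("identity mixing with symmetric spec gives equal homologous band powers", {
  mont <- standard_montage(19)
  sp <- subject_spec(snr = Inf, seed = 11, asymmetry_factor = rep(1, 10))
  sim <- simulate_subject(sp, mont, n_regions = 19, duration = 20, fs = 200,
                          mixing = "identity")
  regions <- sim$truth$regions
  n_half <- sum(regions$hemisphere == "left")
  ep <- epoch_recording(sim$recording)
  # rectangular taper: exact Parseval accounting of the planted source power
  # (a Hann taper samples the envelope unevenly on short recordings)
  tot <- band_power_table(ep, taper = "rectangular")$sum_total
  for (k in seq_len(n_half)) {
    expect_lt(abs(tot[k] - tot[k + n_half]) / tot[k], 0.05)
  }
})

test_that("planted asymmetry drives every homologous pair's band-power sign", {
  mont <- standard_montage(19)
  asym <- rep(1, 10); asym[4] <- 2        # 15-20 Hz band, left amplitude x2
  sp <- subject_spec(snr = Inf, seed = 12, asymmetry_factor = asym)
  sim <- simulate_subject(sp, mont, n_regions = 18, duration = 20, fs = 200)
  # direct band-power computation at the sensors
  ep <- epoch_recording(sim$recording)
  absb <- band_power_table(ep)$absolute
  pairs <- homologous_pairs(rownames(absb))
  diffs <- absb[pairs$left, 4] - absb[pairs$right, 4]
  expect_true(all(diffs > 0))
})

test_that("same spec and seed reproduce the recording bit for bit", {
  mont <- standard_montage(19)
  sp <- subject_spec(seed = 13, snr = 2)
  a <- simulate_subject(sp, mont, n_regions = 6, duration = 5, fs = 200)
  b <- simulate_subject(sp, mont, n_regions = 6, duration = 5, fs = 200)
  expect_identical(a$recording$data, b$recording$data)
})

test_that("cohort sizes and reproducibility match the requested design", {
  mont <- standard_montage(19)
  eff <- cohort_effects(n_regions = 6)
  coh <- simulate_cohort(11, 14, eff, mont, duration = 2, fs = 200, seed = 3)
  expect_length(coh, 25)
  expect_equal(sum(vapply(coh, function(s) s$recording$group, "") == "stroke"), 14)
  coh2 <- simulate_cohort(11, 14, eff, mont, duration = 2, fs = 200, seed = 3)
  expect_identical(coh[[7]]$recording$data, coh2[[7]]$recording$data)
})

test_that("null effect config leaves group band powers at chance (Monte Carlo)", {
  mont <- standard_montage(19)
  eff <- cohort_effects(n_regions = 6, power_deficit = 1, asym_factor = 1,
                        conn_deficit_rho = 0.6, conn_gain_rho = 0.6, snr = 5)
  p <- vapply(1:8, function(s) {
    coh <- simulate_cohort(3, 3, eff, mont, duration = 4, fs = 200, seed = 100 + s)
    # recordings are gain-normalized, so compare a gain-free quantity:
    # normalized power in the 10-15 Hz band averaged over channels
    np <- vapply(coh, function(sub) {
      tb <- band_power_table(epoch_recording(sub$recording))
      mean(tb$normalized[, 3])
    }, 0)
    g <- vapply(coh, function(sub) sub$recording$group, "")
    t.test(np[g == "control"], np[g == "stroke"], var.equal = TRUE)$p.value
  }, 0)
  # no planted effect: small p-values should not dominate
  expect_lte(sum(p < 0.05), 2)
  expect_gt(mean(p), 0.15)
})
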