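# Welch PSD, band power, normalization, directional asymmetry, group tests.

test_that("integrated Welch PSD matches white-noise variance (Parseval)", {
  ep <- noise_epochs(n_epochs = 40, n_channels = 2, n_samples = 400, fs = 200,
                     seed = 1)
  sp <- welch_psd(ep)
  total <- rowSums(sp$psd) * sp$df
  expect_true(all(abs(total - 1) < 0.05))
})

test_that("a sine of amplitude A carries A^2/2 band power", {
  fs <- 200; n <- 400; A <- 3
  t <- seq_len(20 * fs) / fs
  rec <- eeg_recording(matrix(A * sin(2 * pi * 12 * t), 1),
                       fs, "Cz", subject_id = "sine")
  ep <- epoch_recording(rec, 2)
  sp <- welch_psd(ep)
  sel <- sp$freq >= 10 & sp$freq < 15
  expect_lt(abs(sum(sp$psd[1, sel]) * sp$df - A^2 / 2) / (A^2 / 2), 0.05)
})

test_that("zero signal gives a zero PSD and welch errors without epochs", {
  ep <- noise_epochs(n_epochs = 3, n_channels = 2, seed = 2)
  ep$data[] <- 0
  expect_true(all(welch_psd(ep)$psd == 0))
})

test_that("band power sums half-open bins: flat PSD gives the bandwidth ratio", {
  freq <- seq(0, 100, by = 0.5)
  psd <- matrix(1, 2, length(freq))
  spectrum <- list(psd = psd, freq = freq, df = 0.5)
  bp <- band_power(spectrum)
  expect_equal(unname(bp[1, "1-5Hz"] / bp[1, "5-10Hz"]), 4 / 5)
  # partition: band powers add up to the 1-50 total
  sel <- freq >= 1 & freq < 50
  expect_equal(sum(bp[1, ]), (sum(sel) + 1) * 0.5)  # + closing 50-Hz bin
})

test_that("a single active bin lands in exactly one band", {
  freq <- seq(0, 100, by = 0.5)
  psd <- matrix(0, 1, length(freq))
  psd[1, freq == 12] <- 7
  bp <- band_power(list(psd = psd, freq = freq, df = 0.5))
  expect_equal(unname(bp[1, "10-15Hz"]), 3.5)
  expect_equal(sum(bp[1, colnames(bp) != "10-15Hz"]), 0)
})

test_that("normalized power implements NP = 100 * bandsum / total", {
  absolute <- matrix(c(3, 1), 1, dimnames = list("Cz", c("a", "b")))
  np <- normalize_power(absolute)
  expect_equal(unname(np[1, ]), c(75, 25))
  one <- matrix(c(0, 5, 0), 1)
  expect_equal(unname(normalize_power(one)[1, ]), c(0, 100, 0))
  set.seed(3)
  many <- matrix(abs(rnorm(40)), 4, dimnames = list(c("C3", "C4", "Cz", "Pz"), NULL))
  expect_true(all(abs(rowSums(normalize_power(many)) - 100) < 1e-6))
  zero <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("C3", "C4"), NULL))
  expect_error(normalize_power(zero), "C4")
})

test_that("normalized power is invariant to a global gain change", {
  rec <- noise_recording(n_channels = 4, duration = 12, fs = 200, seed = 4)
  ep1 <- epoch_recording(rec)
  rec$data <- rec$data * 17.3
  ep2 <- epoch_recording(rec)
  expect_equal(band_power_table(ep1)$normalized, band_power_table(ep2)$normalized,
               tolerance = 1e-10)
})

test_that("EDA evaluates the signed homologous-pair mean", {
  np <- matrix(50, 4, 2, dimnames = list(c("C3", "C4", "P3", "P4"), c("a", "b")))
  eda <- electrode_directional_asymmetry(np)
  expect_equal(eda$value, c(0, 0))
  np2 <- matrix(c(60, 40), 2, 1, dimnames = list(c("C3", "C4"), "a"))
  expect_equal(electrode_directional_asymmetry(np2)$value, 20)
  np3 <- matrix(c(0, 40, 30, 30), 2, 2, byrow = FALSE,
                dimnames = list(c("C3", "C4"), c("a", "b")))
  expect_equal(electrode_directional_asymmetry(np3)$value, c(-100, 0))
})

test_that("EDA is antisymmetric under hemisphere swap", {
  set.seed(5)
  labels <- c("F3", "F4", "C3", "C4", "P3", "P4", "Cz")
  np <- matrix(abs(rnorm(7 * 3)) + 1, 7, 3, dimnames = list(labels, NULL))
  swapped <- np[c(2, 1, 4, 3, 6, 5, 7), ]
  rownames(swapped) <- labels
  expect_equal(electrode_directional_asymmetry(swapped)$value,
               -electrode_directional_asymmetry(np)$value)
})

test_that("zero-power pairs are skipped with a warning and n reduced", {
  np <- matrix(c(60, 40, 0, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("C3", "P3"), NULL))
  np <- rbind(np, matrix(c(40, 60, 0, 0), 2, 2, byrow = TRUE,
                         dimnames = list(c("C4", "P4"), NULL)))
  expect_warning(eda <- electrode_directional_asymmetry(np), "zero total power")
  expect_equal(eda$n_pairs[2], 1L)
})

test_that("identical groups give t = 0 and an empty FDR mask", {
  tab <- matrix(seq_len(12), 4, 3, dimnames = list(c("C3", "C4", "P3", "P4"), NULL))
  tables <- rep(list(tab), 6)
  res <- groupwise_electrode_test(tables, rep(c("a", "b"), each = 3))
  expect_true(all(res$t == 0, na.rm = TRUE))
  expect_false(any(res$significant))
})

test_that("a planted single-electrode effect survives FDR in 5/5 seeds", {
  labels <- standard_montage(64)$label[1:8]
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    tables <- lapply(1:12, function(i) {
      tb <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(labels, NULL))
      if (i > 6) tb[5, 2] <- tb[5, 2] + 6
      tb
    })
    res <- groupwise_electrode_test(tables, rep(c("ctrl", "strk"), each = 6))
    res$significant[5, 2]
  }, TRUE)
  expect_true(all(hits))
})

test_that("the FDR mask grows monotonically with alpha", {
  set.seed(6)
  labels <- standard_montage(64)$label[1:10]
  tables <- lapply(1:10, function(i) {
    tb <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(labels, NULL))
    if (i > 5) tb[1:3, 1] <- tb[1:3, 1] + 2
    tb
  })
  g <- rep(c("a", "b"), each = 5)
  m1 <- groupwise_electrode_test(tables, g, alpha = 0.01)$significant
  m2 <- groupwise_electrode_test(tables, g, alpha = 0.10)$significant
  expect_true(all(m2[m1]))
})
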