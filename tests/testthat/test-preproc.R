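# Epoching, rejection, interpolation, hemisphere flipping, re-referencing,
# band separation.

test_that("a 180-s recording yields 90 two-second epochs, zero-meaned", {
  rec <- noise_recording(n_channels = 3, duration = 180, fs = 200, seed = 1)
  ep <- epoch_recording(rec, 2)
  expect_equal(dim(ep$data)[1], 90L)
  expect_lt(max(abs(apply(ep$data, c(1, 2), mean))), 1e-12)
})

test_that("trailing partial window is dropped and short recordings error", {
  rec <- noise_recording(n_channels = 3, duration = 181, fs = 200, seed = 2)
  expect_equal(dim(epoch_recording(rec, 2)$data)[1], 90L)
  short <- noise_recording(n_channels = 3, duration = 1.9, fs = 200, seed = 3)
  expect_error(epoch_recording(short, 2), "shorter than one epoch")
})

test_that("epoching then concatenation reconstructs the span minus epoch means", {
  rec <- noise_recording(n_channels = 3, duration = 6, fs = 100, seed = 4)
  ep <- epoch_recording(rec, 2)
  cc <- concatenate_epochs(ep)
  manual <- rec$data[, 1:600]
  for (e in 1:3) {
    idx <- ((e - 1) * 200 + 1):(e * 200)
    manual[, idx] <- manual[, idx] - rowMeans(manual[, idx, drop = FALSE])
  }
  expect_equal(cc$data, manual, tolerance = 1e-12)
  expect_equal(cc$junctions, c(200L, 400L))
})

test_that("a planted high-variance channel is flagged", {
  ep <- noise_epochs(n_epochs = 12, n_channels = 6, seed = 5)
  ep$data[, 4, ] <- ep$data[, 4, ] * 10     # 100x variance
  bad <- detect_bad(ep)
  expect_true(ep$labels[4] %in% bad$bad_channels)
})

test_that("a planted spike epoch is flagged", {
  ep <- noise_epochs(n_epochs = 12, n_channels = 6, seed = 6)
  ep$data[7, , ] <- ep$data[7, , ] + 30 * sign(sin(seq_len(400) / 3))
  bad <- detect_bad(ep)
  expect_true(7L %in% bad$bad_epochs)
})

test_that("homogeneous noise is flagged only at the criterion's tail rate", {
  rates <- vapply(1:20, function(s) {
    ep <- noise_epochs(n_epochs = 10, n_channels = 8, n_samples = 200, seed = 100 + s)
    bad <- detect_bad(ep)
    (length(bad$bad_channels) + length(bad$bad_epochs)) / 18
  }, 0)
  # a >2 SD criterion on 18 items flags a small tail fraction, not everything
  expect_lt(mean(rates), 0.3)
})

test_that("interpolation reconstructs a channel carrying its neighbors' signal", {
  set.seed(7)
  mont <- standard_montage(64)
  labels <- c("C3", "C1", "CP3", "FC3", "C5", "Cz")
  idx <- match(labels, mont$label)
  common <- sin(2 * pi * 10 * seq_len(800) / 200)
  data <- array(0, c(4, 6, 200))
  for (e in 1:4) for (c in 1:6) {
    data[e, c, ] <- common[((e - 1) * 200 + 1):(e * 200)] + 0.1 * rnorm(200)
  }
  ep <- eeg_epochs(data, 200, labels, meta = list(positions = mont[idx, ]))
  truth <- ep$data[, 1, ]
  ep$data[, 1, ] <- rnorm(4 * 200) * 5      # destroy C3
  fixed <- interpolate_channels(ep, "C3")
  expect_gt(cor(as.vector(fixed$data[, 1, ]), as.vector(truth)), 0.95)
  expect_equal(fixed$data[, 2, ], ep$data[, 2, ])   # good channels untouched
})

test_that("empty bad set is the identity and all-bad errors", {
  ep <- noise_epochs(n_epochs = 4, n_channels = 4, seed = 8)
  expect_identical(interpolate_channels(ep, character(0)), ep)
  expect_error(interpolate_channels(ep, ep$labels), "nothing to interpolate")
})

test_that("isolated bad channel with no neighbors in radius errors by name", {
  ep <- noise_epochs(n_epochs = 4, n_channels = 4, seed = 9)
  expect_error(interpolate_channels(ep, ep$labels[1], radius = 1e-4),
               ep$labels[1])
})

test_that("hemisphere flipping is an involution and moves C4 to C3", {
  mont <- standard_montage(64)
  set.seed(10)
  data <- matrix(rnorm(64 * 400), 64)
  marker <- sin(2 * pi * 7 * seq_len(400) / 100)
  data[match("C4", mont$label), ] <- marker
  rec <- eeg_recording(data, 100, mont$label, mont, group = "stroke",
                       lesion_side = "right")
  flipped <- flip_hemispheres(rec)
  expect_equal(flipped$lesion_side, "left")
  expect_equal(flipped$data[match("C3", mont$label), ], marker)
  # flipping the flipped data restores the original
  flipped$lesion_side <- "right"
  twice <- flip_hemispheres(flipped)
  expect_equal(twice$data, rec$data)
  # left or no lesion: identity
  rec_l <- eeg_recording(data, 100, mont$label, mont, group = "stroke",
                         lesion_side = "left")
  expect_identical(flip_hemispheres(rec_l), rec_l)
})

test_that("common-average re-reference zeroes the channel mean and adds FCz", {
  ep <- noise_epochs(n_epochs = 5, n_channels = 6, seed = 11)
  car <- rereference_car(ep)
  expect_equal(length(car$labels), 7L)
  expect_true("FCz" %in% car$labels)
  for (e in 1:5) {
    expect_lt(max(abs(colMeans(matrix(car$data[e, , ], 7, 400)))), 1e-10)
  }
  # idempotent once the reference exists
  again <- rereference_car(car, reference_label = NULL)
  expect_equal(again$data, car$data, tolerance = 1e-12)
  expect_error(rereference_car(car), "already present")
})

test_that("re-referencing preserves pairwise channel differences", {
  ep <- noise_epochs(n_epochs = 3, n_channels = 5, seed = 12)
  car <- rereference_car(ep)
  d_before <- ep$data[2, 1, ] - ep$data[2, 3, ]
  d_after <- car$data[2, 1, ] - car$data[2, 3, ]
  expect_equal(d_before, d_after, tolerance = 1e-12)
})

test_that("default band split yields ten bands with bandwidth-scaled variance", {
  ep <- noise_epochs(n_epochs = 6, n_channels = 3, n_samples = 1000, fs = 500,
                     seed = 13)
  out <- split_bands(ep)
  expect_length(out, 10L)
  v <- vapply(out, function(b) mean(b$data^2), 0)
  # white input: band variance roughly proportional to bandwidth (first band
  # 4 Hz); short 2-s epochs leave low-frequency edge transients, so loosely
  expect_gt(v[2] / v[6], 0.6)
  expect_lt(v[2] / v[6], 1.6)
  expect_lt(v[1] / v[2], 1.2)
})

test_that("a single broad band approximately reproduces the broadband input", {
  ep <- noise_epochs(n_epochs = 3, n_channels = 2, n_samples = 1000, fs = 500,
                     seed = 14)
  # pre-filter so the input actually lives in 1-50 Hz
  for (e in 1:3) ep$data[e, , ] <- bandpass(matrix(ep$data[e, , ], 2, 1000), 2, 40, 500)
  out <- split_bands(ep, data.frame(lo = 1, hi = 50, name = "broad"))
  expect_length(out, 1L)
  expect_gt(cor(as.vector(out[[1]]$data), as.vector(ep$data)), 0.98)
})
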