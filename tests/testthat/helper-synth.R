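# Shared fixture builders. Everything is generated in code at test time; no
# stored data files.

# a small white-noise recording on real montage labels (positions resolve from
# the built-in template)
noise_recording <- function(n_channels = 4, duration = 10, fs = 200, seed = 1,
                            group = "control", lesion_side = "none") {
  set.seed(seed)
  labels <- standard_montage(64)$label[seq_len(n_channels)]
  eeg_recording(matrix(rnorm(n_channels * duration * fs), n_channels),
                fs = fs, labels = labels, group = group,
                lesion_side = lesion_side, subject_id = paste0("T", seed))
}

# epoched white noise straight from a matrix
noise_epochs <- function(n_epochs = 10, n_channels = 4, n_samples = 400,
                         fs = 200, seed = 1) {
  set.seed(seed)
  labels <- standard_montage(64)$label[seq_len(n_channels)]
  data <- array(rnorm(n_epochs * n_channels * n_samples),
                c(n_epochs, n_channels, n_samples))
  eeg_epochs(data, fs, labels,
             meta = list(positions = standard_montage(64)[seq_len(n_channels), ]))
}

# closed-form symmetric (Loewdin) orthogonalization oracle for a signal pair:
# directions from the inverse square root of the 2x2 Gram matrix, scales by
# projection (the fixed point of the iterative scheme for equal-norm pairs)
loewdin_pair_oracle <- function(X) {
  A <- t(X - rowMeans(X))              # samples x 2
  G <- crossprod(A)                    # 2x2 Gram
  e <- eigen(G, symmetric = TRUE)
  Gmh <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  P <- A %*% Gmh                       # orthonormal directions (polar factor)
  d <- colSums(A * P)                  # scale refit
  t(P %*% diag(d))
}

# mirror-paired toy atlas: n left cortical VOIs (+ mirrored right), given sizes
# and collinear x-centroids
toy_cortical_atlas <- function(sizes, xs) {
  n <- length(sizes)
  left <- data.frame(label = sprintf("L%02d", seq_len(n)), hemisphere = "left",
                     size = sizes, x = xs, y = 0, z = 0, class = "cortical",
                     homolog = sprintf("R%02d", seq_len(n)),
                     stringsAsFactors = FALSE)
  right <- left
  right$label <- left$homolog
  right$homolog <- left$label
  right$hemisphere <- "right"
  right$x <- -left$x
  rbind(left, right)
}
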