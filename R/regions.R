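## Atlas handling: reduction of an AAL-like parcellation to a rank-compatible
## volume-of-interest (VOI) set, projection of sensor data through a supplied
## linear inverse operator, and PCA extraction of one time course per VOI.

#' Synthetic AAL-shaped atlas
#'
#' Builds an atlas with the structure of the 116-region AAL parcellation:
#' 45 cerebrum VOIs per hemisphere of which 6 per hemisphere are subcortical
#' (12 total), 9 cerebellar VOIs per hemisphere, and 8 midline vermis VOIs.
#' Centroids are placed deterministically on a mirror-symmetric grid; sizes
#' (voxel counts) vary deterministically so the merge order is well defined.
#'
#' @return data.frame of class `atlas_spec` with columns `label`,
#'   `hemisphere`, `size`, `x`, `y`, `z` (mm), `class`, `homolog`.
#' @export
synthetic_aal_atlas <- function() {
  n_cort <- 39; n_sub <- 6; n_cer <- 9; n_verm <- 8
  mk <- function(prefix, n, hemi, class, x_off, seed_sizes, y_span, z_base) {
    i <- seq_len(n)
    data.frame(
      label = sprintf("%s_%02d_%s", prefix, i, toupper(substr(hemi, 1, 1))),
      hemisphere = hemi, size = seed_sizes,
      x = x_off * (1 + 0.2 * sin(i)), y = seq(-70, 70, length.out = max(n, 2))[i],
      z = z_base + 15 * cos(i), class = class,
      homolog = NA_character_, stringsAsFactors = FALSE)
  }
  cort_sizes <- 200 + ((seq_len(n_cort) * 37) %% 150)
  sub_sizes <- 80 + ((seq_len(n_sub) * 23) %% 40)
  cer_sizes <- 120 + ((seq_len(n_cer) * 31) %% 60)
  verm_sizes <- 40 + ((seq_len(n_verm) * 13) %% 30)

  left_c <- mk("Cortex", n_cort, "left", "cortical", -45, cort_sizes, 140, 30)
  right_c <- mk("Cortex", n_cort, "right", "cortical", 45, cort_sizes, 140, 30)
  left_s <- mk("Subcort", n_sub, "left", "subcortical", -20, sub_sizes, 60, 0)
  right_s <- mk("Subcort", n_sub, "right", "subcortical", 20, sub_sizes, 60, 0)
  left_b <- mk("Cerebellum", n_cer, "left", "cerebellar", -25, cer_sizes, 50, -40)
  right_b <- mk("Cerebellum", n_cer, "right", "cerebellar", 25, cer_sizes, 50, -40)
  verm <- mk("Vermis", n_verm, "midline", "vermis", 0, verm_sizes, 40, -45)
  verm$x <- 0

  pair <- function(l, r) {
    l$homolog <- r$label; r$homolog <- l$label
    rbind(l, r)
  }
  atlas <- rbind(pair(left_c, right_c), pair(left_s, right_s),
                 pair(left_b, right_b), verm)
  rownames(atlas) <- NULL
  class(atlas) <- c("atlas_spec", "data.frame")
  atlas
}

#' Reduce an atlas to a rank-compatible VOI set
#'
#' Cerebellar VOIs are merged to one per hemisphere and vermis VOIs to one;
#' subcortical VOIs are untouched. Left cortical VOIs are reduced iteratively
#' to `target_cortical_per_hemi` by merging the smallest VOI into its
#' nearest-centroid same-hemisphere cortical neighbor (merged size = sum,
#' merged centroid = size-weighted mean); the identical merge sequence is then
#' mirrored in the right hemisphere, keeping the VOI distribution symmetric.
#' Ties (smallest size, nearest centroid) break lexicographically by label.
#'
#' @param atlas an atlas table (see [synthetic_aal_atlas()]).
#' @param target_cortical_per_hemi cortical VOIs to keep per hemisphere
#'   (default 23, the rank limit of a 61-channel dataset once subcortical,
#'   cerebellar and vermis VOIs are counted).
#' @return reduced atlas table; attribute `merges` records the left-hemisphere
#'   merge sequence.
#' @export
reduce_atlas <- function(atlas, target_cortical_per_hemi = 23) {
  stopifnot(is.data.frame(atlas))
  a <- as.data.frame(atlas)

  merge_all <- function(df, new_label) {
    data.frame(label = new_label, hemisphere = df$hemisphere[1],
               size = sum(df$size),
               x = sum(df$x * df$size) / sum(df$size),
               y = sum(df$y * df$size) / sum(df$size),
               z = sum(df$z * df$size) / sum(df$size),
               class = df$class[1], homolog = NA_character_,
               stringsAsFactors = FALSE)
  }

  out <- a[a$class == "subcortical", , drop = FALSE]
  for (h in c("left", "right")) {
    cer <- a[a$class == "cerebellar" & a$hemisphere == h, , drop = FALSE]
    if (nrow(cer) > 0) out <- rbind(out, merge_all(cer, paste0("Cerebellum_", toupper(substr(h, 1, 1)))))
  }
  verm <- a[a$class == "vermis", , drop = FALSE]
  if (nrow(verm) > 0) out <- rbind(out, merge_all(verm, "Vermis"))

  left <- a[a$class == "cortical" & a$hemisphere == "left", , drop = FALSE]
  right <- a[a$class == "cortical" & a$hemisphere == "right", , drop = FALSE]
  if (nrow(left) != nrow(right)) stop("cortical hemispheres are not paired")
  if (target_cortical_per_hemi > nrow(left))
    stop("target exceeds current cortical VOI count")
  ## right-homolog lookup keyed by original left label
  homolog_of <- stats::setNames(left$homolog, left$label)
  merges <- list()

  while (nrow(left) > target_cortical_per_hemi) {
    ord <- order(left$size, left$label)
    i <- ord[1]
    d <- sqrt((left$x - left$x[i])^2 + (left$y - left$y[i])^2 + (left$z - left$z[i])^2)
    d[i] <- Inf
    nn <- order(d, left$label)[1]
    merges[[length(merges) + 1]] <- c(from = left$label[i], into = left$label[nn])
    w <- left$size[c(i, nn)]
    left$x[nn] <- sum(left$x[c(i, nn)] * w) / sum(w)
    left$y[nn] <- sum(left$y[c(i, nn)] * w) / sum(w)
    left$z[nn] <- sum(left$z[c(i, nn)] * w) / sum(w)
    left$size[nn] <- sum(w)
    left <- left[-i, , drop = FALSE]
  }
  ## mirror the merge sequence on the right
  right_by_label <- stats::setNames(seq_len(nrow(right)), right$label)
  keep_r <- rep(TRUE, nrow(right))
  for (m in merges) {
    i <- right_by_label[[homolog_of[[m["from"]]]]]
    nn <- right_by_label[[homolog_of[[m["into"]]]]]
    w <- right$size[c(i, nn)]
    right$x[nn] <- sum(right$x[c(i, nn)] * w) / sum(w)
    right$y[nn] <- sum(right$y[c(i, nn)] * w) / sum(w)
    right$z[nn] <- sum(right$z[c(i, nn)] * w) / sum(w)
    right$size[nn] <- sum(w)
    keep_r[i] <- FALSE
  }
  right <- right[keep_r, , drop = FALSE]
  left$homolog <- homolog_of[left$label]
  right$homolog <- names(homolog_of)[match(right$label, homolog_of)]

  out <- rbind(out, left, right)
  rownames(out) <- NULL
  class(out) <- c("atlas_spec", "data.frame")
  attr(out, "merges") <- merges
  out
}

#' Project sensor data to voxel space through a linear inverse operator
#'
#' Pure linear application of a supplied (precomputed) inverse operator. If
#' the operator maps to dipole triplets (3 rows per voxel,
#' `nrow == 3 * n_voxels`), each triplet is collapsed to a single series by
#' PCA (first principal component).
#'
#' @param data channels x samples matrix (e.g. from [concatenate_epochs()]).
#' @param inverse_operator voxels x sensors (or `3*voxels` x sensors) matrix.
#' @param triplets logical: rows are xyz dipole triplets (default FALSE).
#' @return voxels x samples matrix.
#' @export
project_to_regions <- function(data, inverse_operator, triplets = FALSE) {
  inverse_operator <- as.matrix(inverse_operator)
  if (ncol(inverse_operator) != nrow(data))
    stop("inverse operator dimension mismatch: expected ", nrow(data), " sensor columns")
  v <- inverse_operator %*% data
  if (!triplets) return(v)
  if (nrow(v) %% 3 != 0) stop("triplet operator rows must be a multiple of 3")
  nvox <- nrow(v) / 3
  out <- matrix(0, nvox, ncol(v))
  for (k in seq_len(nvox)) {
    out[k, ] <- voi_timecourse(v[(3 * k - 2):(3 * k), , drop = FALSE])$series
  }
  out
}

#' Collapse voxel series to a single VOI time course by PCA
#'
#' First principal component score series of the voxel set (covariance PCA on
#' the concatenated samples). The sign is fixed so that the component
#' correlates non-negatively with the voxel-mean series.
#'
#' @param voxels voxels x samples matrix.
#' @return list with `series` (length = samples) and `explained_variance`
#'   (first eigenvalue over the eigenvalue sum).
#' @export
voi_timecourse <- function(voxels) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) < 1) stop("need at least one voxel")
  x <- voxels - rowMeans(voxels)
  if (nrow(voxels) == 1) {
    if (stats::var(x[1, ]) == 0) stop("zero variance in VOI")
    return(list(series = x[1, ], explained_variance = 1))
  }
  C <- tcrossprod(x) / (ncol(x) - 1)
  if (sum(diag(C)) == 0) stop("zero variance in VOI")
  e <- eigen(C, symmetric = TRUE)
  w <- e$vectors[, 1]
  series <- as.numeric(crossprod(x, w))
  m <- colMeans(x)
  if (stats::sd(m) > 0 && stats::cor(series, m) < 0) series <- -series
  list(series = series, explained_variance = e$values[1] / sum(e$values))
}

#' Extract one time course per VOI
#'
#' @param voxel_series voxels x samples matrix.
#' @param voxel_voi integer/character VOI assignment, one entry per voxel row.
#' @return list with `data` (VOIs x samples), `labels`, and
#'   `explained_variance` per VOI.
#' @export
voi_series <- function(voxel_series, voxel_voi) {
  stopifnot(length(voxel_voi) == nrow(voxel_series))
  vois <- unique(voxel_voi)
  data <- matrix(0, length(vois), ncol(voxel_series))
  ev <- numeric(length(vois))
  for (k in seq_along(vois)) {
    pc <- voi_timecourse(voxel_series[voxel_voi == vois[k], , drop = FALSE])
    data[k, ] <- pc$series
    ev[k] <- pc$explained_variance
  }
  list(data = data, labels = as.character(vois), explained_variance = ev)
}
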