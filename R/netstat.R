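## Network Based Statistic: edge-wise t maps, supra-threshold connected
## components, and permutation control of the family-wise error rate based on
## component extent (number of edges).

#' Critical t value for an NBS threshold
#'
#' Inverse Student-t quantile for a given two-tailed (or one-tailed) alpha,
#' reported to three decimals: e.g. alpha = 0.01 two-tailed gives 3.169 at
#' df = 10 and 3.012 at df = 13; alpha = 0.02 two-tailed gives 2.5 at df = 23.
#'
#' @param alpha significance level (0 < alpha < 1).
#' @param df degrees of freedom (>= 1).
#' @param tails `"two"` (default) or `"one"`.
#' @return critical t, rounded to 3 decimals.
#' @export
critical_t <- function(alpha, df, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(is.finite(df) && df >= 1)) stop("df must be >= 1")
  a <- if (tails == "two") alpha / 2 else alpha
  round(stats::qt(1 - a, df), 3)
}

#' Edge-wise t map over subject connectivity matrices
#'
#' One-sample t of each edge's bias-corrected z against zero, or pooled
#' two-sample t between groups. Zero-variance edges give `NA`.
#'
#' @param stacks list of per-subject regions x regions matrices (one band).
#' @param design `"one_sample"` or `"two_sample"`.
#' @param groups group labels (required for two-sample).
#' @return symmetric regions x regions t matrix (diagonal `NA`).
#' @export
edge_t_map <- function(stacks, design = c("one_sample", "two_sample"), groups = NULL) {
  design <- match.arg(design)
  n <- dim(stacks[[1]])[1]
  V <- .edge_values(stacks, n)
  g1 <- NULL
  if (design == "two_sample") {
    groups <- as.factor(groups)
    stopifnot(nlevels(groups) == 2, length(groups) == length(stacks))
    if (min(table(groups)) < 2) stop("two-sample design needs >= 2 per group")
    g1 <- groups == levels(groups)[1]
  } else if (length(stacks) < 2) stop("one-sample design needs >= 2 subjects")
  .edge_t_matrix(.t_from_values(V, design, g1), n)
}

## edges (upper triangle, column-major) x subjects value matrix
.edge_values <- function(stacks, n) {
  ut <- upper.tri(matrix(0, n, n))
  matrix(vapply(stacks, function(m) m[ut], numeric(sum(ut))),
         nrow = sum(ut), ncol = length(stacks))
}

## vectorized edge-wise t statistics from an edge x subject matrix
.t_from_values <- function(V, design, g1 = NULL) {
  if (design == "one_sample") {
    ns <- ncol(V)
    m <- rowMeans(V)
    s2 <- (rowSums(V^2) - ns * m^2) / (ns - 1)
    t <- m / sqrt(s2 / ns)
  } else {
    x <- V[, g1, drop = FALSE]; y <- V[, !g1, drop = FALSE]
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- (rowSums(x^2) - nx * mx^2) / (nx - 1)
    vy <- (rowSums(y^2) - ny * my^2) / (ny - 1)
    sp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t <- (mx - my) / sqrt(sp * (1 / nx + 1 / ny))
  }
  t[!is.finite(t)] <- NA
  t
}

.edge_t_matrix <- function(tvec, n) {
  tmat <- matrix(NA_real_, n, n)
  tmat[upper.tri(tmat)] <- tvec
  tmat[lower.tri(tmat)] <- t(tmat)[lower.tri(tmat)]
  tmat
}

#' Connected components of the supra-threshold graph
#'
#' Keeps edges with `t > threshold` (positive sign) or `t < -threshold`
#' (negative sign) and returns the connected components of the resulting
#' undirected graph; extent is the number of edges in a component.
#'
#' @param tmat symmetric t matrix.
#' @param threshold positive t threshold.
#' @param sign `"positive"` or `"negative"`.
#' @return list of components, each a list with `edges` (two-column matrix of
#'   region indices) and `extent`.
#' @export
supra_threshold_components <- function(tmat, threshold, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (threshold <= 0) stop("threshold must be positive")
  keep <- if (sign == "positive") tmat > threshold else tmat < -threshold
  keep[is.na(keep)] <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  edges <- which(keep, arr.ind = TRUE)
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_edgelist(matrix(as.integer(edges), ncol = 2), directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (cid in seq_len(comp$no)) {
    verts <- which(comp$membership == cid)
    if (length(verts) < 2) next
    in_comp <- edges[, 1] %in% verts & edges[, 2] %in% verts
    out[[length(out) + 1]] <- list(edges = unname(edges[in_comp, , drop = FALSE]),
                                   extent = sum(in_comp))
  }
  out[order(-vapply(out, `[[`, 0, "extent"))]
}

#' Network Based Statistic
#'
#' Observed supra-threshold components are evaluated against the permutation
#' null distribution of the maximum component extent: group labels are
#' shuffled (two-sample) or each subject's matrix is randomly sign-flipped
#' (one-sample). `p_fwer = (1 + #{perm max extent >= observed}) / (1 +
#' n_perm)`, which includes the observed statistic in the null and is valid at
#' any permutation count.
#'
#' @param stacks list of per-subject regions x regions matrices (one band).
#' @param design `"one_sample"` or `"two_sample"`.
#' @param groups group labels for two-sample designs.
#' @param threshold edge t threshold (see [critical_t()]).
#' @param sign test positively or negatively signed edges.
#' @param n_perm permutations (default 5000; desk-scale tests use 200).
#' @param seed integer seed.
#' @return list of class `network_result`: `components` (each with `edges`,
#'   `extent`, `p_fwer`), `threshold`, `design`, `sign`, `n_permutations`,
#'   `seed`, `null_max_extent`.
#' @export
nbs <- function(stacks, design = c("one_sample", "two_sample"), groups = NULL,
                threshold, sign = c("positive", "negative"),
                n_perm = 5000, seed = 1) {
  design <- match.arg(design)
  sign <- match.arg(sign)
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  n_sub <- length(stacks)
  n <- dim(stacks[[1]])[1]
  V <- .edge_values(stacks, n)
  g1 <- NULL
  if (design == "two_sample") {
    groups <- as.factor(groups)
    stopifnot(nlevels(groups) == 2, length(groups) == n_sub)
    g1 <- groups == levels(groups)[1]
  }
  observed_t <- .edge_t_matrix(.t_from_values(V, design, g1), n)
  observed <- supra_threshold_components(observed_t, threshold, sign)

  max_extent <- function(tm) {
    comps <- supra_threshold_components(tm, threshold, sign)
    if (length(comps) == 0) 0L else comps[[1]]$extent
  }
  distinct <- if (design == "one_sample") 2^n_sub else choose(n_sub, sum(g1))
  if (distinct < n_perm)
    warning("fewer distinct permutations (", distinct, ") than n_perm requested")

  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    tvec <- if (design == "one_sample") {
      flips <- sample(c(-1, 1), n_sub, replace = TRUE)
      .t_from_values(V * rep(flips, each = nrow(V)), "one_sample")
    } else {
      .t_from_values(V, "two_sample", sample(g1))
    }
    null_max[p] <- max_extent(.edge_t_matrix(tvec, n))
  }
  components <- lapply(observed, function(cmp) {
    cmp$p_fwer <- (1 + sum(null_max >= cmp$extent)) / (1 + n_perm)
    cmp
  })
  structure(list(components = components, threshold = threshold,
                 design = design, sign = sign, n_permutations = n_perm,
                 seed = seed, t_map = observed_t, null_max_extent = null_max),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("<network_result: %s, %s sign, threshold t=%g, %d permutations>\n",
              x$design, x$sign, x$threshold, x$n_permutations))
  if (length(x$components) == 0) {
    cat("  no supra-threshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      cmp <- x$components[[i]]
      cat(sprintf("  component %d: extent %d edges, p_fwer = %.4f\n",
                  i, cmp$extent, cmp$p_fwer))
    }
  }
  invisible(x)
}
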