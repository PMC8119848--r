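## Group-level inference: two-way mixed ANOVA (between factor: group; within
## factor: frequency band) with Mauchly sphericity test and Greenhouse-Geisser
## correction, Holm-Sidak step-down family correction, a bootstrap Tukey post
## hoc, and simple regression of derived measures on the clinical motor score.

#' Two-way mixed ANOVA with sphericity handling
#'
#' Classical mixed-design (split-plot) sums of squares with one between-subject
#' factor and one within-subject factor. Mauchly's test is run on the pooled
#' within-group covariance of orthonormal contrasts; when it rejects at 0.05
#' the within and interaction p-values are Greenhouse-Geisser corrected
#' (`p_corrected`), otherwise `p_corrected` equals the uncorrected p.
#'
#' @param values subjects x bands numeric matrix (balanced: same bands for all
#'   subjects).
#' @param group group label per subject (>= 2 subjects per group).
#' @return list of class `anova_result`: `effects` data.frame (term, F, df1,
#'   df2, p, epsilon, p_corrected), `mauchly_w`, `mauchly_p`, `epsilon`.
#' @export
mixed_anova <- function(values, group) {
  Y <- as.matrix(values)
  group <- as.factor(group)
  N <- nrow(Y); k <- ncol(Y); a <- nlevels(group)
  stopifnot(length(group) == N, a >= 2, k >= 2)
  if (min(table(group)) < 2) stop("need >= 2 subjects per group")

  gm <- mean(Y)
  subj_means <- rowMeans(Y)
  band_means <- colMeans(Y)
  n_g <- as.numeric(table(group))
  grp_means <- tapply(subj_means, group, mean)
  cell_means <- apply(Y, 2, function(col) tapply(col, group, mean))  # groups x bands

  ss_total <- sum((Y - gm)^2)
  ss_between_subj <- k * sum((subj_means - gm)^2)
  ss_group <- k * sum(n_g * (grp_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_band <- N * sum((band_means - gm)^2)
  ss_int <- sum(n_g * (cell_means - outer(as.numeric(grp_means), rep(1, k)) -
                         outer(rep(1, a), band_means) + gm)^2)
  ss_error <- ss_total - ss_between_subj - ss_band - ss_int

  df_group <- a - 1; df_subj <- N - a
  df_band <- k - 1; df_int <- (a - 1) * (k - 1); df_err <- (N - a) * (k - 1)
  ms_group <- ss_group / df_group; ms_subj <- ss_subj_within / df_subj
  ms_band <- ss_band / df_band; ms_int <- ss_int / df_int; ms_err <- ss_error / df_err

  F_group <- ms_group / ms_subj
  F_band <- ms_band / ms_err
  F_int <- ms_int / ms_err
  p_group <- stats::pf(F_group, df_group, df_subj, lower.tail = FALSE)
  p_band <- stats::pf(F_band, df_band, df_err, lower.tail = FALSE)
  p_int <- stats::pf(F_int, df_int, df_err, lower.tail = FALSE)

  ## pooled within-group covariance of the repeated measures
  S <- matrix(0, k, k)
  for (g in levels(group)) {
    Yg <- Y[group == g, , drop = FALSE]
    S <- S + crossprod(scale(Yg, center = TRUE, scale = FALSE))
  }
  S <- S / (N - a)
  ## orthonormal contrasts
  M <- stats::contr.helmert(k)
  M <- qr.Q(qr(M))
  Sc <- t(M) %*% S %*% M

  eps_lb <- 1 / (k - 1)
  tr <- sum(diag(Sc))
  eig <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  singular <- N - a < k - 1 || min(eig) <= 1e-12 * max(eig)
  if (tr <= 0 || !is.finite(tr)) {
    epsilon <- eps_lb; mauchly_w <- NA_real_; mauchly_p <- NA_real_
    warning("degenerate contrast covariance; lower-bound epsilon used")
  } else {
    epsilon <- min(tr^2 / ((k - 1) * sum(Sc^2)), 1)
    if (k == 2) {
      mauchly_w <- 1; mauchly_p <- 1
    } else if (singular) {
      warning("singular contrast covariance (bands >= subjects?); ",
              "lower-bound epsilon used, Mauchly unavailable")
      epsilon <- eps_lb
      mauchly_w <- 0; mauchly_p <- 0
    } else {
      mauchly_w <- prod(eig) / (tr / (k - 1))^(k - 1)
      dd <- k - 1
      ne <- N - a
      f <- 1 - (2 * dd^2 + dd + 2) / (6 * dd * ne)
      chi <- -f * ne * log(mauchly_w)
      df_m <- dd * (dd + 1) / 2 - 1
      mauchly_p <- stats::pchisq(chi, df_m, lower.tail = FALSE)
    }
  }

  use_gg <- is.finite(mauchly_p) && mauchly_p < 0.05
  p_band_gg <- stats::pf(F_band, epsilon * df_band, epsilon * df_err, lower.tail = FALSE)
  p_int_gg <- stats::pf(F_int, epsilon * df_int, epsilon * df_err, lower.tail = FALSE)

  effects <- data.frame(
    term = c("group", "frequency", "interaction"),
    F = c(F_group, F_band, F_int),
    df1 = c(df_group, if (use_gg) epsilon * df_band else df_band,
            if (use_gg) epsilon * df_int else df_int),
    df2 = c(df_subj, if (use_gg) epsilon * df_err else df_err,
            if (use_gg) epsilon * df_err else df_err),
    p = c(p_group, p_band, p_int),
    epsilon = c(NA, epsilon, epsilon),
    p_corrected = c(p_group,
                    if (use_gg) p_band_gg else p_band,
                    if (use_gg) p_int_gg else p_int),
    stringsAsFactors = FALSE)
  structure(list(effects = effects, mauchly_w = mauchly_w, mauchly_p = mauchly_p,
                 epsilon = epsilon,
                 ss = c(group = ss_group, subj_within = ss_subj_within,
                        frequency = ss_band, interaction = ss_int,
                        error = ss_error, total = ss_total)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way mixed ANOVA (Mauchly W =",
      format(x$mauchly_w, digits = 4), ", p =",
      format(x$mauchly_p, digits = 4), ", GG epsilon =",
      format(x$epsilon, digits = 4), ")\n")
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sorted p-values are compared to `1 - (1 - alpha)^(1 / (m - i + 1))`;
#' rejection stops at the first failure, so the rejection set is monotone.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame with `p`, `threshold`, `reject` in the input order, plus
#'   Sidak-adjusted p-values `p_adjusted` (monotone step-down).
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  ord <- order(p)
  thr <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  rej_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] < thr[i]) rej_sorted[i] <- TRUE else break
  }
  adj_sorted <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(adj_sorted), 1)
  out <- data.frame(p = p, threshold = NA_real_, reject = NA,
                    p_adjusted = NA_real_)
  out$threshold[ord] <- thr
  out$reject[ord] <- rej_sorted
  out$p_adjusted[ord] <- adj_sorted
  out
}

#' Bootstrap Tukey post hoc test
#'
#' Observed pairwise studentized-range statistics (Tukey-Kramer form,
#' `q = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))`) are referred to a
#' non-parametric null built by pooling the group-centered residuals and
#' resampling each group with replacement from the pool; the p-value per pair
#' is the fraction of bootstrap maximum-q values at least as large (+1
#' convention).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param n_boot bootstrap iterations (study default 10000).
#' @param seed integer seed.
#' @return data.frame with `group1`, `group2`, `q`, `p`.
#' @export
bootstrap_tukey <- function(groups, n_boot = 10000, seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs >= 2 values")
  if (any(vapply(groups, stats::sd, 0) == 0)) stop("degenerate group variance")
  set.seed(seed)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ng <- length(groups)
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  mse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0)) / (sum(ns) - ng)

  pairs <- utils::combn(ng, 2)
  q_of <- function(m, v) {
    vapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      abs(m[i] - m[j]) / sqrt(v / 2 * (1 / ns[i] + 1 / ns[j]))
    }, 0)
  }
  q_obs <- q_of(means, mse)

  pool <- unlist(lapply(groups, function(x) x - mean(x)), use.names = FALSE)
  max_q <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bs <- lapply(ns, function(n) sample(pool, n, replace = TRUE))
    m <- vapply(bs, mean, 0)
    v <- sum(vapply(bs, function(x) sum((x - mean(x))^2), 0)) / (sum(ns) - ng)
    max_q[b] <- max(q_of(m, v))
  }
  p <- vapply(q_obs, function(q) (1 + sum(max_q >= q)) / (1 + n_boot), 0)
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             q = q_obs, p = p, stringsAsFactors = FALSE)
}

#' Regress a derived measure on the clinical motor score
#'
#' Ordinary least squares of a per-subject measure on the upper-extremity
#' motor score. By default only stroke subjects enter the fit; optionally
#' controls are included at the ceiling score of 66 (as done for plotting).
#'
#' @param measure per-subject values.
#' @param fma motor scores, same length (`NA` for controls without scores).
#' @param group optional group labels; with `include_controls = TRUE`,
#'   controls get `fma = 66`.
#' @param include_controls include control subjects at the ceiling score.
#' @return list with `slope`, `intercept`, `r_squared`, `p` (two-sided slope
#'   test) and the `lm` fit.
#' @export
regress_on_fma <- function(measure, fma, group = NULL, include_controls = FALSE) {
  stopifnot(length(measure) == length(fma))
  use <- rep(TRUE, length(measure))
  if (!is.null(group)) {
    is_ctrl <- group == "control"
    if (include_controls) fma[is_ctrl] <- 66 else use <- !is_ctrl
  }
  use <- use & !is.na(measure) & !is.na(fma)
  if (sum(use) < 3) stop("need at least 3 subjects with measure and score")
  if (stats::sd(fma[use]) == 0) stop("constant predictor: regression undefined")
  fit <- stats::lm(measure[use] ~ fma[use])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p = sm$coefficients[2, 4], fit = fit)
}
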