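#!/usr/bin/env Rscript
# Group-level statistical battery: two-way mixed ANOVA (frequency x group) on
# electrode and connectivity directional asymmetry with Mauchly/Greenhouse-
# Geisser handling, post hoc two-sample t tests with Holm-Sidak correction,
# bootstrap Tukey across bands within the stroke group, two-sample contrast of
# connectivity-spectrum correlations, and regression of normalized power on the
# motor score.
#
# Reads results/power/ and results/connectivity/; writes results/stats/.

library(restnet)

manifest <- read.delim(file.path("results", "cohort", "manifest.tsv"))
out_dir <- file.path("results", "stats")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
groups <- manifest$group
strk <- groups == "stroke"
report <- list()

eda <- as.matrix(read.delim(file.path("results", "power", "eda.tsv"),
                            check.names = FALSE)[, -(1:2)])
an_eda <- mixed_anova(eda, groups)
cat("EDA two-way mixed ANOVA:\n"); print(an_eda)
report$eda_anova <- an_eda$effects
report$eda_mauchly <- c(W = an_eda$mauchly_w, p = an_eda$mauchly_p)

# post hoc per-band group contrasts, Holm-Sidak corrected
p_band <- vapply(seq_len(ncol(eda)), function(b)
  t.test(eda[!strk, b], eda[strk, b], var.equal = TRUE)$p.value, 0)
hs <- holm_sidak(p_band)
report$eda_posthoc <- data.frame(band = colnames(eda), p = p_band,
                                 reject = hs$reject)
cat("\nBands with group EDA differences after Holm-Sidak:\n")
print(report$eda_posthoc[hs$reject, ], row.names = FALSE)

# bootstrap Tukey across the 1-10 / 10-25 / 25-50 Hz ranges within stroke
ranges <- list(`1-10Hz` = 1:2, `10-25Hz` = 3:5, `25-50Hz` = 6:10)
tuk_groups <- lapply(ranges, function(ix) rowMeans(eda[strk, ix, drop = FALSE]))
report$eda_tukey <- bootstrap_tukey(tuk_groups, n_boot = 10000, seed = 1)
cat("\nBootstrap Tukey on stroke EDA across frequency ranges:\n")
print(report$eda_tukey, row.names = FALSE)

cda <- as.matrix(read.delim(file.path("results", "connectivity", "cda.tsv"),
                            check.names = FALSE)[, -(1:2)])
an_cda <- mixed_anova(cda, groups)
cat("\nCDA two-way mixed ANOVA:\n"); print(an_cda)
report$cda_anova <- an_cda$effects

# connectivity spectrum correlation with the control mean, per hemisphere
for (h in c("left", "right")) {
  sp <- as.matrix(read.delim(file.path("results", "connectivity",
                                       paste0("spectrum_", h, ".tsv")),
                             check.names = FALSE)[, -(1:2)])
  ref <- colMeans(sp[!strk, , drop = FALSE])
  z <- vapply(seq_len(nrow(sp)), function(s) spectrum_correlation(sp[s, ], ref), 0)
  tt <- t.test(z[!strk], z[strk], var.equal = TRUE)
  report[[paste0("spectrum_", h)]] <- list(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_control = mean(z[!strk]), mean_stroke = mean(z[strk]))
  cat(sprintf("\n%s hemisphere spectrum correlation: control %.2f vs stroke %.2f,
t(%d) = %.2f, p = %.3f\n", h, mean(z[!strk]), mean(z[strk]),
              as.integer(tt$parameter), tt$statistic, tt$p.value))
}

# regression of significantly different normalized power on the motor score
test <- readRDS(file.path("results", "power", "group_test.rds"))
bands <- default_bands()
sig_bands <- which(colSums(test$significant) > 0)
fma <- manifest$fma
reg_rows <- list()
for (b in sig_bands) {
  np <- vapply(manifest$subject, function(id) {
    tb <- read.delim(file.path("results", "power", paste0(id, "_normalized.tsv")),
                     check.names = FALSE)
    mean(tb[test$significant[, b], bands$name[b]])
  }, 0)
  fit <- regress_on_fma(np, fma, groups)
  reg_rows[[length(reg_rows) + 1]] <- data.frame(
    band = bands$name[b], slope = fit$slope, r_squared = fit$r_squared,
    p = fit$p)
}
if (length(reg_rows)) {
  report$fma_regression <- do.call(rbind, reg_rows)
  cat("\nNormalized power vs motor score (stroke subjects):\n")
  print(report$fma_regression, row.names = FALSE)
}

jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\nArtifacts under", out_dir, "\n")
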