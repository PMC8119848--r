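#!/usr/bin/env Rscript
# Network Based Statistic: one-sample networks within each group (edge
# threshold = two-tailed p = .01 critical t for the group size) and the
# between-group difference network (threshold = two-tailed p = .02 critical t),
# with permutation FWER control on component extent.
#
# Reads results/connectivity/; writes results/networks/.

library(restnet)

manifest <- read.delim(file.path("results", "cohort", "manifest.tsv"))
out_dir <- file.path("results", "networks")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

stacks <- lapply(manifest$subject, function(id)
  readRDS(file.path("results", "connectivity", paste0(id, "_stack.rds"))))
bands <- stacks[[1]]$bands
labels <- stacks[[1]]$labels
groups <- manifest$group
n_perm <- 2000
seed <- 20210323

summary_rows <- list()
results <- list()
for (b in seq_len(nrow(bands))) {
  zb <- lapply(stacks, function(st) st$z[, , b])
  per <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    thr <- critical_t(0.01, length(idx) - 1)
    per[[paste0("within_", g)]] <- nbs(zb[idx], "one_sample", threshold = thr,
                                       sign = "positive", n_perm = n_perm,
                                       seed = seed + b * 10 + 1)
  }
  thr2 <- critical_t(0.02, length(groups) - 2)
  # positive: control > stroke; negative: stroke > control
  per$between_control_gt_stroke <- nbs(zb, "two_sample", groups = groups,
                                       threshold = thr2, sign = "positive",
                                       n_perm = n_perm, seed = seed + b * 10 + 2)
  per$between_stroke_gt_control <- nbs(zb, "two_sample", groups = groups,
                                       threshold = thr2, sign = "negative",
                                       n_perm = n_perm, seed = seed + b * 10 + 3)
  results[[bands$name[b]]] <- per
  for (nm in names(per)) {
    res <- per[[nm]]
    top_p <- if (length(res$components)) res$components[[1]]$p_fwer else NA
    top_e <- if (length(res$components)) res$components[[1]]$extent else 0L
    summary_rows[[length(summary_rows) + 1]] <- data.frame(
      band = bands$name[b], test = nm, threshold = res$threshold,
      top_extent = top_e, p_fwer = top_p)
    for (ci in seq_along(res$components)) {
      cmp <- res$components[[ci]]
      g <- igraph::graph_from_edgelist(matrix(labels[cmp$edges], ncol = 2),
                                       directed = FALSE)
      igraph::write_graph(g, file.path(out_dir,
        sprintf("%s_%s_component%d.graphml",
                gsub("[^0-9A-Za-z]", "_", bands$name[b]), nm, ci)),
        format = "graphml")
    }
  }
}
summary <- do.call(rbind, summary_rows)
write.table(summary, file.path(out_dir, "nbs_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(results, file.path(out_dir, "nbs_results.rds"))

cat("NBS summary (top component per test):\n")
print(summary, row.names = FALSE)
cat("Artifacts under", out_dir, "\n")
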