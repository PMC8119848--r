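## End-to-end orchestration: recordings (simulated or read from disk) ->
## preprocessing -> electrode power -> region connectivity -> network
## statistics -> group statistics, with every intermediate product written to a
## file-based artifact tree and every stochastic stage seeded and logged.

#' Moore-Penrose pseudo-inverse
#'
#' Used to build a linear inverse operator from a known mixing (forward)
#' matrix in synthetic studies; real studies supply their own operator.
#'
#' @param A numeric matrix.
#' @param tol singular-value cutoff relative to the largest.
#' @return the pseudo-inverse of `A`.
#' @export
pseudo_inverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Per-subject, per-band region connectivity stack
#'
#' Runs the region-level connectivity chain for every band: per-epoch bandpass,
#' epoch concatenation, linear projection through the inverse operator
#' (optionally collapsing voxels to VOIs by PCA), symmetric orthogonalization,
#' Hilbert envelopes, envelope correlation with Fisher z, and surrogate bias
#' correction.
#'
#' @param ep a preprocessed [eeg_epochs()].
#' @param inverse_operator voxels x sensors matrix.
#' @param bands band table.
#' @param voxel_voi optional VOI assignment per operator row; `NULL` treats
#'   each row as one region.
#' @param region_labels labels for the resulting regions.
#' @param n_null surrogate iterations per band.
#' @param seed integer; per-band seeds are derived from it.
#' @param orth_iterations orthogonalization iterations (default 20).
#' @param junction_pad samples masked around epoch junctions.
#' @param skip_null skip the surrogate normalization (z slot stays NA).
#' @param null_skip_orthogonalization drop orthogonalization inside the
#'   surrogate pipeline only (speed option; default off so the null matches
#'   the observed pipeline).
#' @return list of class `connectivity_stack`: arrays `r`, `fisher_z`,
#'   `z` (regions x regions x bands), `labels`, `bands`.
#' @export
subject_connectivity <- function(ep, inverse_operator, bands = default_bands(),
                                 voxel_voi = NULL, region_labels = NULL,
                                 n_null = 200, seed = 1, orth_iterations = 20,
                                 junction_pad = 12, skip_null = FALSE,
                                 null_skip_orthogonalization = FALSE) {
  stopifnot(inherits(ep, "eeg_epochs"))
  nb <- nrow(bands)
  per_band <- split_bands(ep, bands)
  n_regions <- if (is.null(voxel_voi)) nrow(inverse_operator) else
    length(unique(voxel_voi))
  r <- fz <- zz <- array(NA_real_, c(n_regions, n_regions, nb))
  labels <- region_labels
  for (b in seq_len(nb)) {
    cc <- concatenate_epochs(per_band[[b]])
    vox <- project_to_regions(cc$data, inverse_operator)
    if (!is.null(voxel_voi)) {
      vs <- voi_series(vox, voxel_voi)
      X <- vs$data
      if (is.null(labels)) labels <- vs$labels
    } else {
      X <- vox
    }
    bc <- band_connectivity(X, junctions = cc$junctions,
                            junction_pad = junction_pad, n_null = n_null,
                            seed = seed + b, orth_iterations = orth_iterations,
                            skip_null = skip_null,
                            null_skip_orthogonalization = null_skip_orthogonalization)
    r[, , b] <- bc$r
    fz[, , b] <- bc$fisher_z
    if (!skip_null) zz[, , b] <- bc$z_bias_corrected
  }
  if (is.null(labels)) labels <- paste0("R", seq_len(n_regions))
  structure(list(r = r, fisher_z = fz, z = zz, labels = labels, bands = bands),
            class = "connectivity_stack")
}

#' Pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param bands band table (default ten 5-Hz bands, 1-50 Hz).
#' @param epoch_window epoch length in seconds.
#' @param z_thresh channel/epoch rejection threshold (SD).
#' @param reference_label reference electrode reintroduced at CAR.
#' @param interp_radius bad-channel interpolation radius in radians.
#' @param orth_iterations orthogonalization iterations.
#' @param n_null surrogate iterations per band (study value 1000; desk default
#'   200).
#' @param n_perm NBS permutations.
#' @param nbs_alpha_one,nbs_alpha_two two-tailed alphas defining the one- and
#'   two-sample NBS edge thresholds via [critical_t()].
#' @param nbs_threshold explicit edge t threshold overriding the alpha/df
#'   route (`NULL` = derive from alpha).
#' @param nbs_bands band indices to run NBS on (`NULL` = all).
#' @param null_skip_orthogonalization drop orthogonalization from the
#'   surrogate (null) pipeline only, for speed; default off.
#' @param junction_pad samples masked around epoch junctions.
#' @param seed master seed; all stage seeds derive from it.
#' @param simulate list of arguments for [simulate_cohort()] (`NULL` to read
#'   `input_files` instead).
#' @param input_files character vector of internal-container recording paths.
#' @param inverse_operator voxels x sensors matrix (required with
#'   `input_files`; for simulated cohorts the pseudo-inverse of the true
#'   mixing is used).
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, bands = default_bands(), epoch_window = 2,
                            z_thresh = 2, reference_label = "FCz",
                            interp_radius = 0.35,
                            orth_iterations = 20, n_null = 200, n_perm = 5000,
                            nbs_alpha_one = 0.01, nbs_alpha_two = 0.02,
                            nbs_threshold = NULL, nbs_bands = NULL,
                            null_skip_orthogonalization = FALSE,
                            junction_pad = 12, seed = 1, simulate = list(),
                            input_files = NULL, inverse_operator = NULL,
                            verbose = FALSE) {
  num_pos <- c(epoch_window = epoch_window, z_thresh = z_thresh,
               orth_iterations = orth_iterations, n_null = n_null,
               n_perm = n_perm, nbs_alpha_one = nbs_alpha_one,
               nbs_alpha_two = nbs_alpha_two)
  if (any(num_pos <= 0)) stop("all numeric pipeline parameters must be positive")
  rm(num_pos)
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 9)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.matrix_tsv <- function(M, labels, path) {
  df <- data.frame(label = labels, as.data.frame(M), check.names = FALSE)
  names(df) <- c("label", labels)
  .write_tsv(df, path)
}

#' Run the full pipeline
#'
#' Executes every stage and writes the artifact tree under `config$out_dir`:
#' per-subject band-power and normalized-power TSVs, electrode and
#' connectivity directional asymmetry TSVs, per-band connectivity z-matrices
#' (TSV) plus a per-subject RDS container, network results (JSON and GraphML),
#' a group-statistics report (JSON), and a provenance echo of the
#' configuration including every derived seed. Rerunning with the same
#' configuration reproduces identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory results (`power`, `eda`, `stacks`, `cda`,
#'   `spectra`, `networks`, `stats`, `artifacts`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (isTRUE(config$verbose)) message(msg)
  }
  fail <- function(stage, e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop("pipeline failed at stage ", stage, ": ", conditionMessage(e))
  }
  cfg_echo <- config
  cfg_echo$inverse_operator <- NULL
  cfg_echo$bands <- as.list(config$bands)
  jsonlite::write_json(cfg_echo[!vapply(cfg_echo, is.null, TRUE)],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  ## --- stage: input -----------------------------------------------------
  logf("stage input: seed=%d", config$seed)
  sim <- NULL
  inv_op <- config$inverse_operator
  recs <- tryCatch({
    if (!is.null(config$input_files)) {
      lapply(config$input_files, read_recording, format = "internal")
    } else {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- do.call(simulate_cohort, sim_args)
      dir.create(file.path(config$out_dir, "recordings"), showWarnings = FALSE)
      for (s in seq_along(sim)) {
        write_recording(sim[[s]]$recording,
                        file.path(config$out_dir, "recordings",
                                  paste0(sim[[s]]$recording$subject_id, ".rds")))
        write_ground_truth(sim[[s]]$truth,
                           file.path(config$out_dir, "recordings",
                                     paste0(sim[[s]]$recording$subject_id, "_truth.json")))
      }
      if (is.null(inv_op)) inv_op <- pseudo_inverse(sim[[1]]$truth$mixing)
      lapply(sim, `[[`, "recording")
    }
  }, error = function(e) fail("input", e))
  if (is.null(inv_op)) fail("input", simpleError("no inverse operator available"))
  groups <- vapply(recs, `[[`, "", "group")
  ids <- vapply(recs, `[[`, "", "subject_id")
  fma <- vapply(recs, function(r) r$fma %||% NA_real_, 0)

  ## --- stage: preprocess -------------------------------------------------
  logf("stage preprocess: window=%gs z=%g", config$epoch_window, config$z_thresh)
  preps <- tryCatch(
    lapply(recs, preprocess_recording, window = config$epoch_window,
           z_thresh = config$z_thresh, reference_label = config$reference_label,
           interp_radius = config$interp_radius),
    error = function(e) fail("preprocess", e))
  ## the reinserted reference channel contributes nothing to source estimation:
  ## pad the operator with a zero column when it was sized to the raw montage
  if (ncol(inv_op) == length(recs[[1]]$labels) &&
      length(preps[[1]]$labels) == ncol(inv_op) + 1) {
    inv_op <- cbind(inv_op, 0)
  }

  ## --- stage: power ------------------------------------------------------
  logf("stage power: %d bands", nrow(config$bands))
  power_dir <- file.path(config$out_dir, "power")
  dir.create(power_dir, showWarnings = FALSE)
  tables <- tryCatch(lapply(preps, band_power_table, bands = config$bands),
                     error = function(e) fail("power", e))
  for (s in seq_along(tables)) {
    .write_tsv(data.frame(electrode = rownames(tables[[s]]$absolute),
                          tables[[s]]$absolute, check.names = FALSE),
               file.path(power_dir, paste0(ids[s], "_absolute.tsv")))
    .write_tsv(data.frame(electrode = rownames(tables[[s]]$normalized),
                          tables[[s]]$normalized, check.names = FALSE),
               file.path(power_dir, paste0(ids[s], "_normalized.tsv")))
  }
  eda <- t(vapply(tables, function(tb)
    electrode_directional_asymmetry(tb$normalized)$value,
    numeric(nrow(config$bands))))
  colnames(eda) <- config$bands$name
  .write_tsv(data.frame(subject = ids, group = groups, eda, check.names = FALSE),
             file.path(power_dir, "eda.tsv"))
  power_test <- if (length(unique(groups)) == 2) {
    groupwise_electrode_test(lapply(tables, `[[`, "normalized"), groups)
  } else NULL

  ## --- stage: connectivity ----------------------------------------------
  logf("stage connectivity: n_null=%d orth_iter=%d seed base=%d",
       config$n_null, config$orth_iterations, config$seed * 1000L)
  conn_dir <- file.path(config$out_dir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  region_labels <- if (!is.null(sim)) sim[[1]]$truth$regions$label else NULL
  stacks <- tryCatch(lapply(seq_along(preps), function(s) {
    subject_connectivity(preps[[s]], inv_op, bands = config$bands,
                         region_labels = region_labels,
                         n_null = config$n_null,
                         seed = config$seed * 1000L + s * 100L,
                         orth_iterations = config$orth_iterations,
                         junction_pad = config$junction_pad,
                         null_skip_orthogonalization =
                           isTRUE(config$null_skip_orthogonalization))
  }), error = function(e) fail("connectivity", e))
  for (s in seq_along(stacks)) {
    st <- stacks[[s]]
    saveRDS(st, file.path(conn_dir, paste0(ids[s], "_stack.rds")))
    for (b in seq_len(nrow(config$bands))) {
      .matrix_tsv(st$z[, , b], st$labels,
                  file.path(conn_dir, sprintf("%s_z_%s.tsv", ids[s],
                                              gsub("[^0-9A-Za-z]", "_", config$bands$name[b]))))
    }
  }

  ## hemisphere bookkeeping for CDA and spectra
  labels <- stacks[[1]]$labels
  if (!is.null(sim)) {
    hemis <- sim[[1]]$truth$regions$hemisphere
    homol <- match(sim[[1]]$truth$regions$homolog, labels)
  } else {
    hemis <- as.character(label_hemisphere(labels))
    pm <- homologous_pairs(labels)
    homol <- rep(NA_integer_, length(labels))
    homol[match(pm$left, labels)] <- match(pm$right, labels)
    homol[match(pm$right, labels)] <- match(pm$left, labels)
  }
  nb <- nrow(config$bands)
  cda <- t(vapply(stacks, function(st) {
    vapply(seq_len(nb), function(b)
      connectivity_directional_asymmetry(st$z[, , b], hemis, homol)$value, 0)
  }, numeric(nb)))
  colnames(cda) <- config$bands$name
  .write_tsv(data.frame(subject = ids, group = groups, cda, check.names = FALSE),
             file.path(conn_dir, "cda.tsv"))

  spectra <- lapply(c(left = "left", right = "right"), function(h) {
    sp <- t(vapply(stacks, function(st)
      connectivity_spectrum(st$z, hemis, h), numeric(nb)))
    colnames(sp) <- config$bands$name
    sp
  })
  for (h in names(spectra)) {
    .write_tsv(data.frame(subject = ids, group = groups, spectra[[h]],
                          check.names = FALSE),
               file.path(conn_dir, paste0("spectrum_", h, ".tsv")))
  }
  spec_corr <- lapply(spectra, function(sp) {
    ref <- colMeans(sp[groups == "control", , drop = FALSE])
    vapply(seq_len(nrow(sp)), function(s) spectrum_correlation(sp[s, ], ref), 0)
  })

  ## --- stage: networks ---------------------------------------------------
  nbs_bands <- config$nbs_bands %||% seq_len(nb)
  logf("stage networks: n_perm=%d bands=%s", config$n_perm,
       paste(nbs_bands, collapse = ","))
  net_dir <- file.path(config$out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  networks <- tryCatch({
    out <- list()
    for (b in nbs_bands) {
      zb <- lapply(stacks, function(st) st$z[, , b])
      per_band <- list()
      for (g in unique(groups)) {
        idx <- which(groups == g)
        thr <- config$nbs_threshold %||%
          critical_t(config$nbs_alpha_one, length(idx) - 1)
        per_band[[paste0("within_", g)]] <-
          nbs(zb[idx], "one_sample", threshold = thr, sign = "positive",
              n_perm = config$n_perm, seed = config$seed * 1000L + 7L * b + 1L)
      }
      if (length(unique(groups)) == 2) {
        thr2 <- config$nbs_threshold %||%
          critical_t(config$nbs_alpha_two, length(groups) - 2)
        per_band$between <- nbs(zb, "two_sample", groups = groups,
                                threshold = thr2, sign = "positive",
                                n_perm = config$n_perm,
                                seed = config$seed * 1000L + 7L * b + 2L)
      }
      out[[config$bands$name[b]]] <- per_band
    }
    out
  }, error = function(e) fail("networks", e))
  net_json <- lapply(networks, function(per_band) lapply(per_band, function(res) {
    list(threshold = res$threshold, design = res$design, sign = res$sign,
         n_permutations = res$n_permutations, seed = res$seed,
         components = lapply(res$components, function(cmp) list(
           extent = cmp$extent, p_fwer = cmp$p_fwer,
           edges = data.frame(from = labels[cmp$edges[, 1]],
                              to = labels[cmp$edges[, 2]]))))
  }))
  jsonlite::write_json(net_json, file.path(net_dir, "networks.json"),
                       auto_unbox = TRUE, digits = NA)
  for (bn in names(networks)) for (nm in names(networks[[bn]])) {
    res <- networks[[bn]][[nm]]
    for (ci in seq_along(res$components)) {
      cmp <- res$components[[ci]]
      g <- igraph::graph_from_edgelist(
        matrix(labels[cmp$edges], ncol = 2), directed = FALSE)
      igraph::write_graph(g, file.path(net_dir,
        sprintf("%s_%s_component%d.graphml", gsub("[^0-9A-Za-z]", "_", bn), nm, ci)),
        format = "graphml")
    }
  }

  ## --- stage: stats ------------------------------------------------------
  logf("stage stats")
  stats_report <- tryCatch({
    report <- list()
    if (length(unique(groups)) == 2) {
      an_eda <- mixed_anova(eda, groups)
      an_cda <- mixed_anova(cda, groups)
      report$eda_anova <- c(as.list(an_eda$effects),
                         mauchly_w = an_eda$mauchly_w, mauchly_p = an_eda$mauchly_p)
      report$cda_anova <- c(as.list(an_cda$effects),
                         mauchly_w = an_cda$mauchly_w, mauchly_p = an_cda$mauchly_p)
      report$spectrum_correlation <- lapply(spec_corr, function(zv) {
        tt <- stats::t.test(zv[groups == "control"], zv[groups == "stroke"],
                            var.equal = TRUE)
        list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
             mean_control = mean(zv[groups == "control"]),
             mean_stroke = mean(zv[groups == "stroke"]))
      })
      if (any(!is.na(fma) & groups == "stroke")) {
        band_sig <- which(colSums(power_test$significant) > 0)
        report$fma_regression <- lapply(band_sig, function(b) {
          meas <- vapply(tables, function(tb)
            mean(tb$normalized[power_test$significant[, b], b]), 0)
          r <- regress_on_fma(meas, fma, groups)
          list(band = config$bands$name[b], slope = r$slope,
               intercept = r$intercept, r_squared = r$r_squared, p = r$p)
        })
      }
    }
    report
  }, error = function(e) fail("stats", e))
  jsonlite::write_json(stats_report, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  logf("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(power = tables, eda = eda, power_test = power_test,
                 stacks = stacks, cda = cda, spectra = spectra,
                 spectrum_correlation = spec_corr, networks = networks,
                 stats = stats_report,
                 artifacts = list.files(config$out_dir, recursive = TRUE)))
}
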