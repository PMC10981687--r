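# End-to-end orchestration over synthetic inputs: one call runs
# simulation -> quantification -> atlas -> clustering -> specificity ->
# targeting -> regulation with a single seed and a scale profile.

#' Pipeline configuration
#'
#' All thresholds default to the conventional values used throughout the
#' package: expression-call FDR 1e-4 (0.01 percent), activity alpha 0.05,
#' specificity folds 2 and 1.25 at Q < 0.01, pan-tissue coverage 0.7,
#' AU threshold 90, O/E call gates (median > 1, fold > 1.25, p < 0.01),
#' promoter window -2000/+100.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param profile `"small"` (about 64 terminals, 8 reporters, 4 tissues)
#'   or `"full"` (671-terminal lineage, 54 reporters, 11 tissues).
#' @param n_boot Bootstrap replicates for cluster confidence.
#' @param ... Overrides for any threshold component.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, profile = c("small", "full"),
                            n_boot = NULL, ...) {
  profile <- match.arg(profile)
  cfg <- list(
    seed = seed, profile = profile,
    target_fdr = 1e-4, alpha = 0.05,
    fold_quant = 2, fold_frac = 1.25, q_max = 0.01, pan_threshold = 0.7,
    au_threshold = 90,
    n_boot = if (is.null(n_boot)) switch(profile, small = 200L,
                                         full = 1000L) else n_boot,
    oe_fold = 1.25, oe_p = 0.01,
    upstream = 2000L, downstream = 100L,
    min_peaks = switch(profile, small = 1L, full = 100L),
    n_reporters = switch(profile, small = 8L, full = 54L),
    n_null_reporters = switch(profile, small = 2L, full = 8L),
    n_tissues = switch(profile, small = 4L, full = 11L),
    n_genes = switch(profile, small = 60L, full = 300L),
    leak_fraction = 0.3)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-analysis pipeline
#'
#' Generates a lineage and reporter programs for the chosen profile,
#' simulates imaging and a negative-control strain, calibrates the
#' expression cutoff, quantifies all reporters, builds the integrated
#' atlas, clusters cells with AU confidence, calls tissue-specific
#' reporters and TSGs, computes O/E preferential-targeting and leakiness
#' statistics and the TF-binding analyses. Deterministic given the
#' config seed.
#'
#' @param config A [pipeline_config()].
#' @param out Optional directory: stage tables are written as TSV.
#' @return A named list with the per-stage results and record counts.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sd0 <- as.integer(config$seed)
  model <- imaging_model()
  tree <- if (config$profile == "small")
    synthetic_lineage(64L, config$n_tissues) else celegans_lineage()
  tt <- tissue_table(data.frame(
    cell = terminal_cells(tree, surviving = TRUE),
    tissue = tree$tissue[match(terminal_cells(tree, surviving = TRUE),
                               tree$name)]))
  tissues <- tissue_labels()[seq_len(config$n_tissues)]

  # negative control and cutoff calibration
  ctrl <- simulate_negative_control(tree, model, seed = sd0 + 1L,
                                    n_embryos = 2L)
  ctrl <- subtract_background(ctrl)
  calib <- calibrate_cutoff(
    correct_depth_attenuation(ctrl$net, ctrl$z, model),
    target_fdr = config$target_fdr)

  # reporter programs: planted pan-tissue + silent controls
  n_act <- config$n_reporters - config$n_null_reporters
  reporters <- sprintf("rep%02d", seq_len(config$n_reporters))
  programs <- vector("list", config$n_reporters)
  names(programs) <- reporters
  for (i in seq_len(config$n_reporters)) {
    programs[[i]] <- if (i <= n_act)
      pan_tissue_program(reporters[i], tree,
                         tissues[((i - 1L) %% length(tissues)) + 1L],
                         seed = sd0 + 700L + i)
    else reporter_program(reporters[i])
  }
  cells_all <- tree$name
  emb <- matrix(0, length(cells_all), config$n_reporters,
                dimnames = list(cells_all, reporters))
  terms <- terminal_cells(tree, surviving = TRUE)
  l1 <- matrix(0, length(terms), config$n_reporters,
               dimnames = list(terms, reporters))
  for (i in seq_along(programs)) {
    tr <- simulate_reporter_imaging(tree, programs[[i]], model,
                                    seed = sd0 + 10L + i)
    q <- quantify_embryo(tr, model, calib)
    emb[q$cell, i] <- q$value
    lv <- simulate_l1_expression(tree, programs[[i]], model,
                                 seed = sd0 + 200L + i)
    lv[lv < calib$cutoff] <- 0
    l1[names(lv), i] <- lv
  }

  atlas <- build_atlas(emb, l1, tree)
  au <- suppressWarnings(
    au_pvalues(atlas$integrated, n_boot = config$n_boot,
               seed = sd0 + 300L))
  clusters <- extract_clusters(au, threshold = config$au_threshold)
  purity <- cluster_tissue_purity(clusters, tt)
  calls <- call_tissue_specific_all(atlas$integrated, tt,
                                    fold_quant = config$fold_quant,
                                    fold_frac = config$fold_frac,
                                    q_max = config$q_max,
                                    pan_threshold = config$pan_threshold)

  # transcriptome with planted TSGs and leaky transcription
  track_tissues <- tissue_of(tt)
  n_tsg_per <- max(2L, config$n_genes %/% (2L * length(tissues)))
  tsg_truth <- stats::setNames(rep(NA_character_, config$n_genes),
                               sprintf("g%03d", seq_len(config$n_genes)))
  k <- 1L
  for (ti in tissues) for (j in seq_len(n_tsg_per)) {
    tsg_truth[k] <- ti; k <- k + 1L
  }
  truth <- transcriptome_truth(tsg_truth,
                               leak_fraction = config$leak_fraction)
  txn <- simulate_track_transcriptome(track_tissues, truth,
                                      seed = sd0 + 400L)
  tsg_calls <- call_tsg(txn, tt, fold_quant = config$fold_quant,
                        fold_frac = config$fold_frac,
                        q_max = config$q_max,
                        pan_threshold = config$pan_threshold)
  pan <- tsg_calls[tsg_calls$pan_or_sub == "pan", , drop = FALSE]
  tsg_map <- stats::setNames(pan$tissue, pan$gene)
  tsg_map <- tsg_map[!duplicated(names(tsg_map))]

  # UTRs, targets, O/E, leakiness
  seeds8 <- .with_seed(sd0 + 500L, stats::setNames(
    vapply(seq_len(config$n_reporters), function(i)
      paste(sample(c("A", "C", "G", "U"), 8, replace = TRUE),
            collapse = ""), character(1)), reporters))
  ut <- generate_utrs_and_targets(names(tsg_truth), seeds8,
                                  density = 0.5, seed = sd0 + 501L)
  universe <- names(build_gene_universe(ut$utrs))
  mirna_tissue <- stats::setNames(
    tissues[((seq_len(n_act) - 1L) %% length(tissues)) + 1L],
    reporters[seq_len(n_act)])
  expr_tracks <- lapply(reporters[seq_len(n_act)], function(r)
    rownames(atlas$integrated)[atlas$integrated[, r] > 0])
  names(expr_tracks) <- reporters[seq_len(n_act)]
  oe <- compute_oe(ut$targets[ut$targets$mirna %in% names(expr_tracks), ],
                   tsg_map, txn, universe, mirna_tracks = NULL)
  pref <- call_preferential_targeting(oe, track_tissues, mirna_tissue,
                                      fold = config$oe_fold,
                                      p_max = config$oe_p)
  same_rate <- same_tissue_targeting_rate(pref)
  leak <- quantify_leakiness(tsg_map, txn, track_tissues)
  dens <- site_density(ut$targets, nchar(ut$utrs))

  # TF peaks and binding analyses
  n_tf <- max(3L, length(tissues))
  tfs <- sprintf("tf%02d", seq_len(n_tf))
  tss <- data.frame(gene = reporters, chrom = "chrI",
                    tss = 10000L + 5000L * seq_along(reporters),
                    strand = rep(c("+", "-"),
                                 length.out = length(reporters)))
  tf_tissue <- stats::setNames(tissues[((seq_len(n_tf) - 1L) %%
                                          length(tissues)) + 1L], tfs)
  binding <- .with_seed(sd0 + 600L, {
    b <- matrix(stats::runif(n_tf * length(reporters)) < 0.15, n_tf,
                length(reporters), dimnames = list(tfs, reporters))
    for (tf in tfs) for (mi in names(mirna_tissue))
      if (tf_tissue[[tf]] == mirna_tissue[[mi]] &&
          stats::runif(1) < 0.7) b[tf, mi] <- TRUE
    b
  })
  peaks <- simulate_tf_peaks(tss, binding, seed = sd0 + 601L)
  win <- promoter_windows(tss, upstream = config$upstream,
                          downstream = config$downstream)
  bmat <- assign_peaks_to_promoters(peaks, win,
                                    min_peaks = config$min_peaks)
  enrich <- tryCatch(
    same_tissue_binding_enrichment(bmat, tf_tissue, mirna_tissue),
    error = function(e) NULL)

  res <- list(config = config, tree = tree, tissue_table = tt,
              calibration = calib, atlas = atlas, au = au,
              clusters = clusters, purity = purity, calls = calls,
              transcriptome = txn, tsg_calls = tsg_calls,
              tsg_map = tsg_map, targets = ut$targets, oe = oe,
              preferential = pref, same_tissue = same_rate,
              leakiness = leak, site_density = dens,
              binding = bmat, binding_enrichment = enrich,
              counts = c(cells = nrow(tree),
                         terminals = sum(tree$terminal),
                         reporters = config$n_reporters,
                         specificity_calls = nrow(calls),
                         tsg_calls = nrow(tsg_calls)))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(res$atlas$integrated),
                       file.path(out, "atlas_integrated.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(res$calls, file.path(out, "specificity_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$clusters, file.path(out, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$preferential,
                       file.path(out, "preferential_targeting.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$leakiness$profiles,
                       file.path(out, "leakiness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
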