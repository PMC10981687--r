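# Tissue-specificity calling for reporters, TFs and transcriptome genes;
# expression-category comparisons; intra-family divergence; literature
# consistency.

#' Call tissue-specific expression of one feature
#'
#' A feature (reporter, TF or gene) is tissue-specific if it meets any of
#' three criteria against the 11-tissue classification:
#' (1) quantitative expression in the tissue's cells significantly higher
#' than in the rest (fold > 2 on pseudocounted means, Q < 0.01, two-sided
#' Mann-Whitney); (2) the expressing fraction in the tissue significantly
#' higher than outside (fold > 1.25, Q < 0.01, two-sided Fisher exact);
#' (3) all expressing cells (at least 3) belong to one tissue, regardless
#' of Q. Q-values are Benjamini-Hochberg corrected across the tissues of
#' the feature. Calls carry a pan/sub label: pan if the expressing
#' fraction within the tissue exceeds 70 percent.
#'
#' @param expr Named numeric vector of quantitative expression per cell.
#' @param binarized Optional named logical (default `expr > 0`).
#' @param tt A `tissue_table` covering (a subset of) the cells.
#' @param fold_quant,fold_frac Fold-change gates (defaults 2 and 1.25).
#' @param q_max Q-value gate (default 0.01).
#' @param pan_threshold Pan-tissue coverage threshold (default 0.7).
#' @param pseudocount Added to both means for the quantitative fold change
#'   (default 0.1 percentile units), avoiding zero baselines.
#' @return Data.frame, one row per tissue with a call: `tissue`,
#'   `criteria` (comma-joined subset of quantitative/fraction/exclusive),
#'   `pan_or_sub`, `fold_quant`, `q_quant`, `fold_frac`, `q_frac`,
#'   `coverage`. Zero rows if no tissue qualifies.
#' @export
call_tissue_specific <- function(expr, binarized = NULL, tt,
                                 fold_quant = 2, fold_frac = 1.25,
                                 q_max = 0.01, pan_threshold = 0.7,
                                 pseudocount = 0.1) {
  lab <- tissue_of(tt)
  cells <- intersect(names(expr), names(lab)[!is.na(lab)])
  if (length(cells) == 0) stop("no labeled cells in expression vector")
  expr <- expr[cells]
  lab <- lab[cells]
  if (length(unique(lab)) < 2) stop("need at least 2 tissues represented")
  if (is.null(binarized)) binarized <- expr > 0
  binarized <- binarized[cells]
  tissues <- unique(lab)
  p_q <- p_f <- fq <- ff <- cov <- stats::setNames(
    rep(NA_real_, length(tissues)), tissues)
  for (ti in tissues) {
    inn <- lab == ti
    if (!sum(inn)) next
    a <- expr[inn]; b <- expr[!inn]
    p_q[ti] <- if (length(unique(expr)) == 1L) 1 else suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
    fq[ti] <- (mean(a) + pseudocount) / (mean(b) + pseudocount)
    k_in <- sum(binarized[inn]); k_out <- sum(binarized[!inn])
    tab <- matrix(c(k_in, sum(inn) - k_in, k_out, sum(!inn) - k_out), 2)
    p_f[ti] <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    fr_in <- k_in / sum(inn); fr_out <- k_out / sum(!inn)
    ff[ti] <- if (fr_out == 0) ifelse(fr_in > 0, Inf, NA) else fr_in / fr_out
    cov[ti] <- fr_in
  }
  q_q <- stats::p.adjust(p_q, method = "BH")
  q_f <- stats::p.adjust(p_f, method = "BH")
  expr_cells <- names(binarized)[binarized]
  excl_tissue <- if (length(expr_cells) >= 3 &&
                     length(unique(lab[expr_cells])) == 1L)
    unique(lab[expr_cells]) else NA_character_
  rows <- list()
  for (ti in tissues) {
    crit <- character()
    if (!is.na(q_q[ti]) && q_q[ti] < q_max && fq[ti] > fold_quant)
      crit <- c(crit, "quantitative")
    if (!is.na(q_f[ti]) && q_f[ti] < q_max && !is.na(ff[ti]) &&
        ff[ti] > fold_frac)
      crit <- c(crit, "fraction")
    if (!is.na(excl_tissue) && excl_tissue == ti)
      crit <- c(crit, "exclusive")
    if (!length(crit)) next
    rows[[ti]] <- data.frame(
      tissue = ti, criteria = paste(crit, collapse = ","),
      pan_or_sub = if (cov[ti] > pan_threshold) "pan" else "sub",
      fold_quant = fq[ti], q_quant = q_q[ti],
      fold_frac = ff[ti], q_frac = q_f[ti], coverage = cov[ti])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tissue = character(), criteria = character(),
               pan_or_sub = character(), fold_quant = numeric(),
               q_quant = numeric(), fold_frac = numeric(),
               q_frac = numeric(), coverage = numeric())
  rownames(out) <- NULL
  out
}

#' Tissue-specificity calls for a whole feature matrix
#'
#' @param mat Matrix cells x features (e.g. the integrated atlas).
#' @param tt A `tissue_table`.
#' @param ... Passed to [call_tissue_specific()].
#' @return Data.frame with a `feature` column prepended.
#' @export
call_tissue_specific_all <- function(mat, tt, ...) {
  rows <- lapply(colnames(mat), function(f) {
    calls <- call_tissue_specific(mat[, f], tt = tt, ...)
    if (nrow(calls)) cbind(feature = f, calls) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(), tissue = character(),
                      criteria = character(), pan_or_sub = character(),
                      fold_quant = numeric(), q_quant = numeric(),
                      fold_frac = numeric(), q_frac = numeric(),
                      coverage = numeric())
  rownames(out) <- NULL
  out
}

#' Late-embryo expression proxy per terminal cell
#'
#' The late-embryo expression of a gene for a terminal cell is the maximum
#' of the terminal cell's and its mother's value; if the terminal cell is
#' not covered by the transcriptome, the latest covered ancestor is used
#' as a proxy.
#'
#' @param tpm Named numeric vector of one gene's expression over covered
#'   cells (terminal and/or internal).
#' @param tree A `lineage_tree`.
#' @return Named numeric vector over the tree's surviving terminal cells
#'   (`NA` where no covered ancestor exists).
#' @export
late_embryo_expression <- function(tpm, tree) {
  parent <- stats::setNames(tree$parent, tree$name)
  terms <- terminal_cells(tree, surviving = TRUE)
  out <- stats::setNames(rep(NA_real_, length(terms)), terms)
  for (tc in terms) {
    mo <- parent[[tc]]
    vals <- tpm[c(tc, mo)]
    if (all(is.na(vals))) {
      cur <- mo
      while (!is.na(cur) && (!cur %in% names(tpm) || is.na(tpm[cur]))) {
        cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
      }
      if (!is.na(cur)) out[tc] <- tpm[[cur]]
    } else {
      out[tc] <- max(vals, na.rm = TRUE)
    }
  }
  out
}

#' Identify tissue-specific genes (TSGs) in a transcriptome
#'
#' Applies the same three-criteria caller used for reporters to
#' late-embryo expression values of each gene; columns named by terminal
#' cells (track-level matrices) are used directly.
#'
#' @param transcriptome Matrix genes x cells (TPM-like). Columns must be
#'   terminal-cell / track names.
#' @param tt A `tissue_table`.
#' @param detect Detection threshold for binarized expression (default 0,
#'   i.e. TPM > 0; a stringent profile uses 5).
#' @param ... Passed to [call_tissue_specific()].
#' @return Data.frame of calls (`gene`, `tissue`, `pan_or_sub`, ...).
#' @export
call_tsg <- function(transcriptome, tt, detect = 0, ...) {
  rows <- lapply(rownames(transcriptome), function(g) {
    v <- transcriptome[g, ]
    calls <- call_tissue_specific(v, binarized = v > detect, tt = tt, ...)
    if (nrow(calls)) cbind(gene = g, calls) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), tissue = character(),
                      criteria = character(), pan_or_sub = character(),
                      fold_quant = numeric(), q_quant = numeric(),
                      fold_frac = numeric(), q_frac = numeric(),
                      coverage = numeric())
  rownames(out) <- NULL
  out
}

#' Bin expression breadth into high / medium / low
#'
#' Cell counts: high `N > 200`, medium `10 < N <= 200`, low `N <= 10`.
#' Tissue fractions: high `F > 0.7`, medium `0.3 < F <= 0.7`,
#' low `F <= 0.3`.
#'
#' @param n_exp Number of expressing cells, or `NULL`.
#' @param f_exp Expressing fraction within a tissue, or `NULL`.
#' @return `"high"`, `"medium"` or `"low"`.
#' @export
categorize_expression <- function(n_exp = NULL, f_exp = NULL) {
  if (!is.null(n_exp)) {
    return(if (n_exp > 200) "high" else if (n_exp > 10) "medium" else "low")
  }
  if (!is.null(f_exp)) {
    return(if (f_exp > 0.7) "high" else if (f_exp > 0.3) "medium"
           else "low")
  }
  stop("supply n_exp or f_exp")
}

#' Compare sequencing expression between breadth categories
#'
#' @param categories Named character vector miRNA -> category
#'   (high/medium/low).
#' @param cpm Named numeric vector of sequencing expression (CPM).
#' @return List `medians` (per category) and `pairwise` (data.frame of
#'   two-sided Mann-Whitney p-values between category pairs; empty
#'   categories are skipped with a warning).
#' @export
compare_seq_categories <- function(categories, cpm) {
  common <- intersect(names(categories), names(cpm))
  categories <- categories[common]; cpm <- cpm[common]
  lev <- c("high", "medium", "low")
  groups <- lapply(lev, function(l) cpm[categories == l])
  names(groups) <- lev
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning("empty category skipped: ", paste(lev[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  meds <- vapply(groups, stats::median, numeric(1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    p <- suppressWarnings(stats::wilcox.test(groups[[pr[1]]],
                                             groups[[pr[2]]])$p.value)
    data.frame(group1 = pr[1], group2 = pr[2], p = p)
  }))
  list(medians = meds, pairwise = pw)
}

#' Intra-family expression divergence
#'
#' For each within-family miRNA pair, similarity (Kendall tau over cells
#' by default) is ranked against the pair's inter-family comparisons (the
#' union of each member's similarities to all out-of-family miRNAs); the
#' pair is flagged high-similarity if it reaches the top `top_fraction`
#' of that comparison set.
#'
#' @param mat Matrix miRNAs x cells of atlas expression.
#' @param family Named character vector miRNA -> family id.
#' @param top_fraction Top quantile defining high similarity (default 0.2).
#' @param similarity Function(matrix-row, matrix-row) -> scalar; default
#'   Kendall tau.
#' @return List `pairs` (data.frame mirna1, mirna2, family, similarity,
#'   cutoff, high_similarity) and `fraction_high`.
#' @export
intra_family_divergence <- function(mat, family, top_fraction = 0.2,
                                    similarity = NULL) {
  if (is.null(similarity))
    similarity <- function(a, b) suppressWarnings(
      stats::cor(a, b, method = "kendall"))
  mirnas <- intersect(rownames(mat), names(family))
  fam <- family[mirnas]
  rows <- list()
  for (f in unique(fam)) {
    mem <- mirnas[fam == f]
    if (length(mem) < 2) next
    outside <- mirnas[fam != f]
    prs <- utils::combn(mem, 2, simplify = FALSE)
    for (pr in prs) {
      s <- similarity(mat[pr[1], ], mat[pr[2], ])
      comp <- c(vapply(outside, function(o) similarity(mat[pr[1], ],
                                                       mat[o, ]),
                       numeric(1)),
                vapply(outside, function(o) similarity(mat[pr[2], ],
                                                       mat[o, ]),
                       numeric(1)))
      comp <- comp[!is.na(comp)]
      cutoff <- if (length(comp)) stats::quantile(comp, 1 - top_fraction,
                                                  names = FALSE) else -Inf
      rows[[length(rows) + 1L]] <- data.frame(
        mirna1 = pr[1], mirna2 = pr[2], family = f, similarity = s,
        cutoff = cutoff,
        high_similarity = !is.na(s) && s >= cutoff)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna1 = character(), mirna2 = character(),
               family = character(), similarity = numeric(),
               cutoff = numeric(), high_similarity = logical())
  list(pairs = pairs,
       fraction_high = if (nrow(pairs)) mean(pairs$high_similarity)
                       else NA_real_)
}

#' Categorize consistency with a literature expression description
#'
#' Literature descriptions are standardized to tissue-level, cell-level or
#' ubiquitous; each is compared to this atlas's pattern: for tissue-level,
#' consistent if pan-tissue enrichment was detected, partially consistent
#' if sub-tissue enrichment or any expression in the tissue was detected,
#' not consistent otherwise; for cell-level, consistent if pan-tissue
#' enrichment, partially consistent if at least one documented cell
#' expresses, not consistent if none does; for ubiquitous, consistent if
#' ubiquitous expression (90 percent of tracks or cells) was also seen.
#' Per study, all-consistent gives consistent, all-not gives not
#' consistent, anything else partial; across studies the best category is
#' kept.
#'
#' @param ours List describing this atlas's pattern: `pan_tissues`,
#'   `sub_tissues`, `tissues_with_expression`, `expressed_cells`,
#'   `ubiquitous` (logical).
#' @param literature Data.frame with columns `study`, `type`
#'   (tissue/cell/ubiquitous), `tissue` (for tissue-level), `cells`
#'   (comma-separated, for cell-level); the literature entries are curated
#'   input with this controlled vocabulary.
#' @return `"consistent"`, `"partially consistent"` or
#'   `"not consistent"`.
#' @export
categorize_literature_consistency <- function(ours, literature) {
  stopifnot(nrow(literature) >= 1)
  entry_cat <- function(row) {
    ti <- row$tissue
    switch(row$type,
      tissue = {
        if (ti %in% ours$pan_tissues) "consistent"
        else if (ti %in% ours$sub_tissues ||
                 ti %in% ours$tissues_with_expression)
          "partially consistent"
        else "not consistent"
      },
      cell = {
        cells <- trimws(strsplit(row$cells, ",")[[1]])
        related_pan <- length(ours$pan_tissues) > 0 &&
          !is.na(ti) && ti %in% ours$pan_tissues
        if (related_pan) "consistent"
        else if (any(cells %in% ours$expressed_cells))
          "partially consistent"
        else "not consistent"
      },
      ubiquitous = {
        if (isTRUE(ours$ubiquitous)) "consistent" else "not consistent"
      },
      stop("unknown literature entry type: ", row$type))
  }
  rank <- c("not consistent" = 1, "partially consistent" = 2,
            consistent = 3)
  per_study <- vapply(split(seq_len(nrow(literature)), literature$study),
                      function(ix) {
    cats <- vapply(ix, function(i) entry_cat(literature[i, ]),
                   character(1))
    if (all(cats == "consistent")) "consistent"
    else if (all(cats == "not consistent")) "not consistent"
    else "partially consistent"
  }, character(1))
  names(rank)[max(rank[per_study])]
}
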