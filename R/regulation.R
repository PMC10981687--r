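# TF ChIP-peak to promoter assignment and binding-frequency analyses.

#' Strand-aware promoter windows around TSS coordinates
#'
#' The promoter window covers TSS-2000 to TSS+100 in transcription
#' orientation (2100 bp): for minus-strand genes the window is mirrored
#' around the TSS. Coordinates are 0-based half-open.
#'
#' @param tss_table Data.frame with columns `gene`, `chrom`, `tss`,
#'   `strand` (`+`/`-`); optionally `class`. `tss` is the 0-based TSS
#'   coordinate (set `one_based = TRUE` for 1-based input tables).
#' @param upstream,downstream Window extent in bp (defaults 2000 and 100).
#' @param one_based Convert 1-based TSS input to 0-based first.
#' @return Data.frame `gene`, `chrom`, `start`, `end`, `strand` (0-based
#'   half-open windows, clipped at 0).
#' @export
promoter_windows <- function(tss_table, upstream = 2000L,
                             downstream = 100L, one_based = FALSE) {
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(tss_table)))
  t0 <- as.integer(tss_table$tss) - if (one_based) 1L else 0L
  plus <- tss_table$strand == "+"
  start <- ifelse(plus, t0 - upstream, t0 - downstream + 1L)
  end <- ifelse(plus, t0 + downstream, t0 + upstream + 1L)
  data.frame(gene = tss_table$gene, chrom = tss_table$chrom,
             start = pmax(0L, as.integer(start)), end = as.integer(end),
             strand = tss_table$strand)
}

#' Read a BED file of ChIP peaks
#'
#' Minimal BED (chrom, start, end, optional name = TF id); 0-based
#' half-open convention.
#' @param path BED path.
#' @return Data.frame `chrom`, `start`, `end`, `tf`.
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  st <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  en <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
  if (anyNA(st) || anyNA(en))
    stop("malformed BED line ", which(is.na(st) | is.na(en))[1],
         ": non-integer coordinates")
  data.frame(chrom = vapply(parts, `[`, "", 1), start = st, end = en,
             tf = ifelse(nf >= 4, vapply(parts, function(p)
               if (length(p) >= 4) p[4] else NA_character_, ""), "peak"))
}

#' Assign ChIP peaks to promoter windows
#'
#' A TF is bound to a gene when any of its peaks overlaps the gene's
#' promoter window by at least 1 bp (any-overlap rule, half-open
#' intervals; `rule = "midpoint"` instead requires the peak midpoint to
#' fall inside the window). TF datasets with fewer than `min_peaks` peaks
#' are excluded from the matrix.
#'
#' @param peaks Data.frame `chrom`, `start`, `end`, `tf` (BED 0-based
#'   half-open), as from [read_peaks_bed()] or [simulate_tf_peaks()].
#' @param windows A [promoter_windows()] result.
#' @param rule `"any"` (default) or `"midpoint"`.
#' @param min_peaks Minimum peak count per TF dataset (default 100; use 0
#'   to keep all).
#' @return Logical matrix TFs x genes with attribute `peak_counts`.
#' @export
assign_peaks_to_promoters <- function(peaks, windows,
                                      rule = c("any", "midpoint"),
                                      min_peaks = 100L) {
  rule <- match.arg(rule)
  counts <- table(peaks$tf)
  keep_tf <- names(counts)[counts >= min_peaks]
  tfs <- sort(keep_tf)
  genes <- windows$gene
  mat <- matrix(FALSE, length(tfs), length(genes),
                dimnames = list(tfs, genes))
  chroms_w <- unique(windows$chrom)
  skipped <- setdiff(unique(peaks$chrom), chroms_w)
  if (length(skipped))
    warning("peak chromosome(s) absent from TSS table skipped: ",
            paste(skipped, collapse = ", "))
  for (ch in chroms_w) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    pk <- peaks[peaks$chrom == ch & peaks$tf %in% tfs, , drop = FALSE]
    if (!nrow(pk) || !nrow(w)) next
    if (rule == "midpoint") {
      mid <- (pk$start + pk$end) %/% 2L
      qr <- IRanges::IRanges(start = mid, width = 1L)
    } else {
      qr <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    }
    sr <- IRanges::IRanges(start = w$start + 1L, end = w$end)
    ov <- IRanges::findOverlaps(qr, sr)
    if (length(ov))
      mat[cbind(pk$tf[S4Vectors::queryHits(ov)],
                w$gene[S4Vectors::subjectHits(ov)])] <- TRUE
  }
  attr(mat, "peak_counts") <- as.integer(counts[tfs])
  mat
}

#' Compare TF binding frequencies between gene classes
#'
#' Per TF, the fraction of genes bound within each class; classes are
#' compared pairwise to the reference class by a two-sided Wilcoxon
#' signed-rank test across TFs.
#'
#' @param bmat Logical binding matrix TFs x genes.
#' @param gene_classes Named character vector gene -> class.
#' @param reference Reference class (default `"protein_coding"`).
#' @return List `frequencies` (TF x class matrix) and `tests`
#'   (data.frame class, p; test skipped with a single TF).
#' @export
compare_binding_frequencies <- function(bmat, gene_classes,
                                        reference = "protein_coding") {
  classes <- unique(gene_classes[colnames(bmat)])
  classes <- classes[!is.na(classes)]
  freq <- sapply(classes, function(cl) {
    gs <- colnames(bmat)[gene_classes[colnames(bmat)] %in% cl]
    rowMeans(bmat[, gs, drop = FALSE])
  })
  if (is.null(dim(freq)))
    freq <- matrix(freq, nrow = nrow(bmat),
                   dimnames = list(rownames(bmat), classes))
  others <- setdiff(classes, reference)
  tests <- do.call(rbind, lapply(others, function(cl) {
    d <- freq[, cl] - freq[, reference]
    p <- if (nrow(bmat) < 2) NA_real_
         else if (all(d == 0)) 1   # identical classes: no signed ranks
         else suppressWarnings(
           stats::wilcox.test(freq[, cl], freq[, reference],
                              paired = TRUE)$p.value)
    data.frame(class = cl, p = p)
  }))
  list(frequencies = freq, tests = tests)
}

#' Same-tissue TF to miRNA-promoter binding enrichment
#'
#' Tests whether miRNA promoters are more frequently bound by TFs of the
#' same tissue specificity than by other tissue-specific TFs: one-sided
#' Fisher exact test on the 2x2 of same-tissue vs other (TF, miRNA)
#' pairs by bound vs unbound.
#'
#' @param bmat Logical binding matrix TFs x miRNA genes.
#' @param tf_tissue Named character vector TF -> tissue.
#' @param mirna_tissue Named character vector miRNA gene -> tissue.
#' @return List `odds_ratio`, `p`, `rate_same`, `rate_other`, `table`.
#' @export
same_tissue_binding_enrichment <- function(bmat, tf_tissue,
                                           mirna_tissue) {
  tfs <- intersect(rownames(bmat), names(tf_tissue)[!is.na(tf_tissue)])
  mis <- intersect(colnames(bmat),
                   names(mirna_tissue)[!is.na(mirna_tissue)])
  if (!length(tfs) || !length(mis))
    stop("no tissue-specific TFs or miRNAs to compare")
  sub <- bmat[tfs, mis, drop = FALSE]
  same <- outer(tf_tissue[tfs], mirna_tissue[mis], "==")
  tab <- matrix(c(sum(sub[same]), sum(!sub[same]),
                  sum(sub[!same]), sum(!sub[!same])), 2)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value,
       rate_same = mean(sub[same]), rate_other = mean(sub[!same]),
       table = tab)
}
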