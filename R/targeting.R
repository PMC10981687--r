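# miRNA seed-site scanning (8mer / 7mer-m8 / 7mer-A1), the
# observed/expected preferential-targeting statistic, leaky-transcription
# metrics, binding-site density and target-level comparisons.

.revcomp_dna <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

.norm_nt <- function(x, what = "sequence") {
  y <- chartr("u", "t", tolower(x))
  if (grepl("[^acgt]", y))
    stop("non-ACGTU character in ", what)
  toupper(y)
}

#' Canonical seed-site patterns for a miRNA
#'
#' From the miRNA 5' region (positions 1-8): the 7mer-m8 site is the
#' reverse complement of positions 2-8; the 7mer-A1 site is the reverse
#' complement of positions 2-7 followed by an A; the 8mer site is the
#' reverse complement of positions 2-8 followed by an A. U and T are
#' treated as equivalent on input; patterns are DNA, sense strand.
#'
#' @param mirna_5p miRNA sequence, at least the first 8 nucleotides.
#' @return Named character vector of site patterns
#'   (`8mer`, `7mer-m8`, `7mer-A1`).
#' @export
seed_site_patterns <- function(mirna_5p) {
  s <- .norm_nt(mirna_5p, "miRNA sequence")
  if (nchar(s) < 8) stop("miRNA sequence must provide positions 1-8")
  p2_8 <- substr(s, 2, 8)
  p2_7 <- substr(s, 2, 7)
  c(`8mer` = paste0(.revcomp_dna(p2_8), "A"),
    `7mer-m8` = .revcomp_dna(p2_8),
    `7mer-A1` = paste0(.revcomp_dna(p2_7), "A"))
}

.find_fixed <- function(utr, pat) {
  hits <- gregexpr(pat, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L  # 0-based
}

#' Scan a 3'UTR for seed-match sites of one miRNA
#'
#' Overlapping matches are reported; each locus is classified by its most
#' specific type (an 8mer subsumes the 7mer-m8 at the same start and the
#' 7mer-A1 one base downstream). Coordinates are 0-based half-open on the
#' sense strand.
#'
#' @param utr 3'UTR sequence (DNA or RNA alphabet).
#' @param mirna_5p miRNA 5' region (positions 1-8).
#' @return Data.frame `site_type`, `start`, `end`.
#' @export
scan_seed_sites <- function(utr, mirna_5p) {
  u <- .norm_nt(utr, "UTR")
  pats <- seed_site_patterns(mirna_5p)
  p8 <- .find_fixed(u, pats[["8mer"]])
  pm8 <- setdiff(.find_fixed(u, pats[["7mer-m8"]]), p8)
  pa1 <- .find_fixed(u, pats[["7mer-A1"]])
  pa1 <- pa1[!(pa1 - 1L) %in% p8]
  if (pats[["7mer-m8"]] == pats[["7mer-A1"]]) pa1 <- setdiff(pa1, pm8)
  out <- rbind(
    if (length(p8)) data.frame(site_type = "8mer", start = p8,
                               end = p8 + 8L),
    if (length(pm8)) data.frame(site_type = "7mer-m8", start = pm8,
                                end = pm8 + 7L),
    if (length(pa1)) data.frame(site_type = "7mer-A1", start = pa1,
                                end = pa1 + 7L))
  if (is.null(out))
    out <- data.frame(site_type = character(), start = integer(),
                      end = integer())
  out[order(out$start), , drop = FALSE]
}

#' Scan a set of UTRs against a panel of miRNAs
#'
#' @param utrs Named character vector of 3'UTR sequences.
#' @param mirna_seeds Named character vector of miRNA 5' regions.
#' @return Data.frame `gene`, `mirna`, `site_type`, `start`, `end`.
#' @export
scan_all_targets <- function(utrs, mirna_seeds) {
  rows <- list()
  for (g in names(utrs)) {
    for (mi in names(mirna_seeds)) {
      st <- scan_seed_sites(utrs[[g]], mirna_seeds[[mi]])
      if (nrow(st))
        rows[[length(rows) + 1L]] <- cbind(gene = g, mirna = mi, st)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), mirna = character(),
                      site_type = character(), start = integer(),
                      end = integer())
  rownames(out) <- NULL
  out
}

#' Build the target-prediction gene universe from 3'UTR sequences
#'
#' Keeps one UTR per gene (the longest, when several isoform UTRs exist)
#' and drops genes whose longest UTR is shorter than `min_len` (50 nt).
#'
#' @param utrs Either a named character vector of UTR sequences (names may
#'   repeat per gene) or the path to an (uncompressed) FASTA file.
#' @param min_len Minimum UTR length (default 50).
#' @return Named character vector, one UTR per retained gene.
#' @export
build_gene_universe <- function(utrs, min_len = 50L) {
  if (length(utrs) == 1L && is.character(utrs) &&
      is.null(names(utrs)) && file.exists(utrs)) {
    ss <- Biostrings::readDNAStringSet(utrs)
    utrs <- stats::setNames(as.character(ss),
                            sub("\\s.*$", "", names(ss)))
  }
  if (length(utrs) == 0) return(stats::setNames(character(), character()))
  if (is.null(names(utrs)))
    stop("UTRs must be a named vector (gene ids) or a FASTA path")
  len <- nchar(utrs)
  keep <- unlist(lapply(split(seq_along(utrs), names(utrs)),
                        function(ix) ix[which.max(len[ix])]),
                 use.names = FALSE)
  out <- utrs[keep]
  out[nchar(out) >= min_len]
}

#' Write UTRs as FASTA
#' @param utrs Named character vector.
#' @param path Output path.
#' @export
write_utr_fasta <- function(utrs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(utrs), path)
  invisible(path)
}

#' Observed/expected TSG-targeting profile per miRNA and cell track
#'
#' Within each cell track where the miRNA is expressed, the expected
#' frequency of a TSG type is its share among the track-transcribed genes
#' of the 3'UTR universe, the observed frequency is the same share among
#' the miRNA's predicted targets transcribed in the track, and O/E is
#' their ratio. To absorb type-specific differences in UTR length and
#' composition, O/E is normalized by its median across tracks per
#' (miRNA, TSG type), so the normalized medians equal 1 by construction.
#'
#' @param targets Target table (`gene`, `mirna`, ...) as from
#'   [scan_all_targets()].
#' @param tsg_map Named character vector gene -> focus tissue for pan-TSGs.
#' @param transcriptome Matrix genes x tracks (TPM-like).
#' @param universe Character vector of universe genes (see
#'   [build_gene_universe()]).
#' @param detect Transcription detection threshold (default TPM > 0).
#' @param mirna_tracks Optional named list miRNA -> tracks where the miRNA
#'   is expressed (embryonic and L1 combined); default: all tracks.
#' @return Data.frame `mirna`, `track`, `tsg_type`, `observed`,
#'   `expected`, `oe`, `oe_norm`, `undefined` (expected 0 flag).
#' @export
compute_oe <- function(targets, tsg_map, transcriptome, universe,
                       detect = 0, mirna_tracks = NULL) {
  universe <- intersect(universe, rownames(transcriptome))
  types <- sort(unique(stats::na.omit(tsg_map)))
  tracks <- colnames(transcriptome)
  tgt_by_mirna <- split(targets$gene, targets$mirna)
  rows <- list()
  for (mi in names(tgt_by_mirna)) {
    tg <- unique(tgt_by_mirna[[mi]])
    trs <- if (is.null(mirna_tracks)) tracks else
      intersect(mirna_tracks[[mi]], tracks)
    for (tr in trs) {
      on <- universe[transcriptome[universe, tr] > detect]
      tgt_on <- intersect(tg, on)
      for (ty in types) {
        is_ty <- !is.na(tsg_map[on]) & tsg_map[on] == ty
        expected <- mean(is_ty)
        observed <- if (length(tgt_on))
          mean(!is.na(tsg_map[tgt_on]) & tsg_map[tgt_on] == ty) else 0
        undef <- !is.finite(expected) || expected == 0
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mi, track = tr, tsg_type = ty,
          observed = observed, expected = expected,
          oe = if (undef) NA_real_ else observed / expected,
          undefined = undef)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(mirna = character(), track = character(),
                      tsg_type = character(), observed = numeric(),
                      expected = numeric(), oe = numeric(),
                      oe_norm = numeric(), undefined = logical()))
  out$oe_norm <- NA_real_
  for (key in unique(paste(out$mirna, out$tsg_type))) {
    ix <- paste(out$mirna, out$tsg_type) == key
    med <- stats::median(out$oe[ix], na.rm = TRUE)
    if (is.finite(med) && med > 0) out$oe_norm[ix] <- out$oe[ix] / med
  }
  rownames(out) <- NULL
  out
}

#' Call preferential targeting from normalized O/E profiles
#'
#' For each (miRNA, TSG type), the normalized O/E values of the cell
#' tracks differentiating into the miRNA's specific tissue are compared to
#' those of the other tracks in the profile; preferential targeting is
#' called when the group median exceeds 1, the fold change of medians
#' exceeds `fold`, and the two-sided Mann-Whitney p-value is below
#' `p_max`. With `grouping = "tissue"` the group is instead formed per
#' candidate tissue irrespective of the miRNA's own specificity.
#'
#' @param oe A [compute_oe()] result (tracks restricted to where the
#'   miRNA is expressed, if that restriction is wanted).
#' @param track_tissues Named character vector track -> tissue.
#' @param mirna_tissue Named character vector miRNA -> its specific
#'   tissue.
#' @param fold Median fold-change gate (default 1.25).
#' @param p_max P-value gate (default 0.01).
#' @param min_group Minimum group size to test (default 3).
#' @return Data.frame `mirna`, `tsg_type`, `mirna_tissue`,
#'   `median_group`, `median_other`, `fold`, `p`, `tested`, `called`.
#' @export
call_preferential_targeting <- function(oe, track_tissues, mirna_tissue,
                                        fold = 1.25, p_max = 0.01,
                                        min_group = 3L) {
  rows <- list()
  for (mi in unique(oe$mirna)) {
    ti <- mirna_tissue[[mi]]
    if (is.null(ti) || is.na(ti)) next
    sub <- oe[oe$mirna == mi & !is.na(oe$oe_norm), , drop = FALSE]
    for (ty in unique(sub$tsg_type)) {
      ss <- sub[sub$tsg_type == ty, ]
      grp <- ss$oe_norm[track_tissues[ss$track] == ti]
      oth <- ss$oe_norm[track_tissues[ss$track] != ti]
      tested <- length(grp) >= min_group && length(oth) >= min_group
      mg <- stats::median(grp); mo <- stats::median(oth)
      fc <- if (is.na(mo) || mo == 0) Inf else mg / mo
      p <- if (tested) suppressWarnings(
        stats::wilcox.test(grp, oth)$p.value) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mi, tsg_type = ty, mirna_tissue = ti,
        median_group = mg, median_other = mo, fold = fc, p = p,
        tested = tested,
        called = tested && !is.na(p) && mg > 1 && fc > fold && p < p_max)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna = character(), tsg_type = character(),
                      mirna_tissue = character(), median_group = numeric(),
                      median_other = numeric(), fold = numeric(),
                      p = numeric(), tested = logical(), called = logical())
  rownames(out) <- NULL
  out
}

#' Same-tissue preferential-targeting rate
#'
#' A call is same-tissue when the TSG type equals the miRNA's own tissue.
#' The expected same-tissue call frequency applies the overall (marginal)
#' call rate to the same-tissue pairs (independence model); observed and
#' expected are compared by a two-sided Fisher exact test on the 2x2 of
#' same/cross pairs by called/not.
#'
#' @param calls A [call_preferential_targeting()] result.
#' @return List `observed_freq`, `expected_freq`, `ratio`
#'   (observed/expected), `n_same`, `fisher_p` (`NA` when no calls).
#' @export
same_tissue_targeting_rate <- function(calls) {
  calls <- calls[calls$tested, , drop = FALSE]
  if (!nrow(calls))
    return(list(observed_freq = NA_real_, expected_freq = NA_real_,
                ratio = NA_real_, n_same = 0L, fisher_p = NA_real_))
  same <- calls$tsg_type == calls$mirna_tissue
  n_same <- sum(same)
  overall <- mean(calls$called)
  observed <- if (n_same) mean(calls$called[same]) else NA_real_
  tab <- matrix(c(sum(calls$called[same]), sum(!calls$called[same]),
                  sum(calls$called[!same]), sum(!calls$called[!same])), 2)
  p <- if (sum(calls$called) == 0 || n_same == 0) NA_real_ else
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(observed_freq = observed, expected_freq = overall,
       ratio = if (is.finite(overall) && overall > 0 &&
                   is.finite(observed)) observed / overall else NA_real_,
       n_same = n_same, fisher_p = p)
}

#' Quantify leaky transcription of tissue-specific genes
#'
#' For each (pan-)TSG: `freq_other` is its detection frequency in cell
#' tracks differentiating into tissues other than its focus tissue
#' (CT_other), and `rel_level` is its mean level in CT_other divided by
#' its mean level in focus-tissue tracks (CT_focus). Track-level leakiness
#' is, per track, the fraction of TSGs of each non-own tissue type
#' detected in the track, averaged over tissue types.
#'
#' @param tsg_map Named character vector gene -> focus tissue (pan-TSGs).
#' @param transcriptome Matrix genes x tracks.
#' @param track_tissues Named character vector track -> tissue.
#' @param detect Detection threshold (default TPM > 0).
#' @return List `profiles` (gene, focus, freq_other, rel_level) and
#'   `track_leakiness` (named numeric per track).
#' @export
quantify_leakiness <- function(tsg_map, transcriptome, track_tissues,
                               detect = 0) {
  genes <- intersect(names(tsg_map), rownames(transcriptome))
  tracks <- intersect(colnames(transcriptome), names(track_tissues))
  tt <- track_tissues[tracks]
  prof <- do.call(rbind, lapply(genes, function(g) {
    foc <- tsg_map[[g]]
    oth <- tracks[!is.na(tt) & tt != foc]
    fct <- tracks[!is.na(tt) & tt == foc]
    lev <- transcriptome[g, ]
    data.frame(gene = g, focus = foc,
               freq_other = mean(lev[oth] > detect),
               rel_level = if (length(fct) && mean(lev[fct]) > 0)
                 mean(lev[oth]) / mean(lev[fct]) else NA_real_)
  }))
  types <- unique(stats::na.omit(tsg_map))
  leak <- vapply(tracks, function(tr) {
    own <- tt[[tr]]
    fr <- vapply(setdiff(types, own), function(ty) {
      gs <- genes[tsg_map[genes] == ty]
      if (!length(gs)) return(NA_real_)
      mean(transcriptome[gs, tr] > detect)
    }, numeric(1))
    mean(fr, na.rm = TRUE)
  }, numeric(1))
  list(profiles = prof, track_leakiness = leak)
}

#' miRNA binding-site density of a gene's 3'UTR
#'
#' The number of distinct miRNAs with at least one seed site in the UTR
#' (multiple sites of one miRNA count once), per kilobase of UTR.
#'
#' @param targets Target table (`gene`, `mirna`, ...).
#' @param utr_lengths Named integer vector of UTR lengths per gene.
#' @return Named numeric vector of densities (sites per kb) over all
#'   genes in `utr_lengths`.
#' @export
site_density <- function(targets, utr_lengths) {
  counts <- vapply(names(utr_lengths), function(g)
    length(unique(targets$mirna[targets$gene == g])), numeric(1))
  1000 * counts / utr_lengths
}

#' Correlate TSG leakiness with binding-site density
#'
#' Spearman rank correlation across TSGs, plus a two-sided Mann-Whitney
#' comparison of densities between high- and low-leakiness strata
#' (median split).
#'
#' @param freq_other Named numeric leakiness per gene.
#' @param density Named numeric site density per gene.
#' @return List `rho`, `p`, `strata_p`, `n`.
#' @export
correlate_leakiness_density <- function(freq_other, density) {
  genes <- intersect(names(freq_other), names(density))
  if (length(genes) < 5)
    stop("need at least 5 genes to correlate leakiness with density")
  x <- freq_other[genes]; y <- density[genes]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  med <- stats::median(x)
  hi <- y[x > med]; lo <- y[x <= med]
  sp <- if (length(hi) >= 2 && length(lo) >= 2) suppressWarnings(
    stats::wilcox.test(hi, lo)$p.value) else NA_real_
  list(rho = unname(ct$estimate), p = ct$p.value, strata_p = sp,
       n = length(genes))
}

#' Compare target transcription between miRNA-expressing and other tracks
#'
#' Per-track mean expression over the miRNA's predicted targets, compared
#' between the tracks where the miRNA is expressed and the rest
#' (two-sided Mann-Whitney). Under the coherent model the targets are
#' transcribed but at lower levels in the miRNA-expressing tracks.
#'
#' @param target_genes Character vector of the miRNA's predicted targets.
#' @param transcriptome Matrix genes x tracks.
#' @param expressing_tracks Tracks where the miRNA is expressed.
#' @return List `p`, `median_expressing`, `median_other`, `n_targets`;
#'   `NULL` when the miRNA has no covered targets.
#' @export
compare_target_levels <- function(target_genes, transcriptome,
                                  expressing_tracks) {
  tg <- intersect(target_genes, rownames(transcriptome))
  if (!length(tg)) return(NULL)
  per_track <- colMeans(transcriptome[tg, , drop = FALSE])
  ex <- intersect(expressing_tracks, names(per_track))
  ot <- setdiff(names(per_track), ex)
  if (!length(ex) || !length(ot)) return(NULL)
  p <- suppressWarnings(stats::wilcox.test(per_track[ex],
                                           per_track[ot])$p.value)
  list(p = p, median_expressing = stats::median(per_track[ex]),
       median_other = stats::median(per_track[ot]), n_targets = length(tg))
}
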