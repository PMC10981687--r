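# Integrated terminal-cell x reporter atlas: percentile-rank
# normalization, cell-track averaging, embryonic/L1 integration.

#' Percentile-rank normalization within one reporter and stage
#'
#' Zeros stay zero; nonzero values are replaced by
#' `100 * rank / (number of nonzero values)` with average ranks for ties,
#' making expression comparable between the embryonic and L1 acquisitions
#' of a reporter and invariant to monotone rescaling.
#'
#' @param values Nonnegative numeric vector (one reporter, one stage).
#' @return Percentile ranks in [0, 100].
#' @export
percentile_normalize <- function(values) {
  if (any(values < 0)) stop("percentile normalization needs nonnegative values")
  out <- numeric(length(values))
  nz <- values > 0
  if (!any(nz)) {
    if (length(values)) warning("all-zero column: ranks all zero")
    names(out) <- names(values)
    return(out)
  }
  out[nz] <- 100 * rank(values[nz], ties.method = "average") / sum(nz)
  names(out) <- names(values)
  out
}

#' Average reporter expression along a cell track
#'
#' Only reporters continuously expressed in at least `min_consecutive`
#' consecutive cell generations within the track count as expressed; when
#' such a run exists the value is the mean over all expressing cells of
#' the track, otherwise 0 (isolated single-generation signals are treated
#' as noise).
#'
#' @param track_values Ordered per-generation expression values along one
#'   track (origin to terminal).
#' @param min_consecutive Minimum run length of expressing generations.
#' @return A single track-level expression value.
#' @export
average_track_expression <- function(track_values, min_consecutive = 2L) {
  if (length(track_values) == 0) stop("empty cell track")
  on <- track_values > 0
  r <- rle(on)
  if (!any(r$values & r$lengths >= min_consecutive)) return(0)
  mean(track_values[on])
}

#' Integrate embryonic-track and L1 percentile ranks
#'
#' The integrated value of a terminal cell is the maximum of its
#' embryonic cell-track percentile rank and its L1-stage percentile rank:
#' a cell counts as expressing if it expressed at either stage.
#'
#' @param embryonic,l1 Percentile ranks on the same [0, 100] scale.
#' @return Pairwise maxima.
#' @export
integrate_terminal_expression <- function(embryonic, l1) {
  pmax(embryonic, l1)
}

#' Build the integrated terminal-cell x reporter atlas
#'
#' For each reporter: per-cell embryonic expression is averaged along the
#' cell tracks ending in each terminal cell, track values and L1 cellular
#' values are independently percentile-rank normalized, and the two stages
#' are integrated per terminal cell by their maximum.
#'
#' @param embryonic_expr Matrix cells x reporters of per-cell embryonic
#'   expression (all traced cells; post-cutoff values).
#' @param l1_expr Matrix terminal cells x reporters of L1 expression
#'   (post-cutoff values).
#' @param tree A `lineage_tree` used to construct cell tracks.
#' @param min_consecutive Passed to [average_track_expression()].
#' @return List of matrices (`integrated`, `embryonic_rank`, `l1_rank`),
#'   rows = surviving terminal cells, plus `tracks`.
#' @export
build_atlas <- function(embryonic_expr, l1_expr, tree,
                        min_consecutive = 2L) {
  tracks <- build_tracks(tree)
  terms <- terminal_cells(tree, surviving = TRUE)
  tracks <- tracks[terms]
  reporters <- colnames(embryonic_expr)
  track_val <- matrix(0, length(terms), length(reporters),
                      dimnames = list(terms, reporters))
  for (r in reporters) {
    v <- embryonic_expr[, r]
    for (tc in terms) {
      cells <- tracks[[tc]]
      tv <- v[cells]
      tv[is.na(tv)] <- 0
      track_val[tc, r] <- average_track_expression(tv, min_consecutive)
    }
  }
  emb_rank <- apply(track_val, 2, percentile_normalize)
  l1 <- matrix(0, length(terms), length(reporters),
               dimnames = list(terms, reporters))
  common <- intersect(rownames(l1_expr), terms)
  l1[common, colnames(l1_expr)] <- l1_expr[common, , drop = FALSE]
  l1_rank <- apply(l1, 2, percentile_normalize)
  integrated <- integrate_terminal_expression(emb_rank, l1_rank)
  dimnames(integrated) <- dimnames(emb_rank) <- dimnames(l1_rank) <-
    list(terms, reporters)
  list(integrated = integrated, embryonic_rank = emb_rank,
       l1_rank = l1_rank, tracks = tracks)
}
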