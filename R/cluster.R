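# Hierarchical clustering of cells on reporter profiles with multiscale
# bootstrap (approximately-unbiased) cluster confidence.

#' Kendall-tau distance matrix between atlas rows
#'
#' Distance between two cells is `1 - tau_b` over their reporter profiles;
#' tau-b (tie-corrected) is used because atlas columns are tie-rich
#' (zeros). A constant row, for which tau is undefined, is placed at
#' distance 1 from every other row with a warning.
#'
#' @param mat Numeric matrix, cells x reporters.
#' @return A `dist` object.
#' @export
kendall_distance <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 rows to compute distances")
  tau <- suppressWarnings(stats::cor(t(mat), method = "kendall"))
  const <- apply(mat, 1, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning(sum(const), " constant row(s): tau undefined, distance set to 1")
    tau[const, ] <- 0
    tau[, const] <- 0
  }
  tau[is.na(tau)] <- 0
  d <- 1 - tau
  diag(d) <- 0
  stats::as.dist(d)
}

#' Average-linkage clustering of cells on Kendall-tau distance
#'
#' @param mat Numeric matrix, cells x reporters (percentile-rank atlas).
#' @return An `hclust` object (agglomeration is deterministic given the
#'   input; equal-height merges follow the stable lowest-index order of
#'   the agglomeration backend).
#' @export
hierarchical_cluster <- function(mat) {
  stats::hclust(kendall_distance(mat), method = "average")
}

# member sets (row names) for every internal node of an hclust tree
.node_members <- function(hc, labels = hc$labels) {
  n <- nrow(hc$merge)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- hc$merge[i, ]
    pick <- function(j) if (j < 0) labels[-j] else out[[j]]
    out[[i]] <- c(pick(m[1]), pick(m[2]))
  }
  lapply(out, sort)
}

# weighted least-squares fit of the multiscale-bootstrap model
# qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r); AU = 1 - pnorm(v - c)
.fit_au <- function(bp, scales, n_boot) {
  if (all(bp <= 1e-12)) return(list(au = 0, v = Inf, c = 0, flagged = TRUE))
  use <- bp > 0 & bp < 1   # degenerate scales carry no curvature signal
  if (sum(use) < 3) {
    # (nearly) always or never recovered across scales: AU equals the
    # degenerate bootstrap answer
    return(list(au = if (mean(bp) >= 0.5) 100 else 0, v = 0, c = 0))
  }
  z <- stats::qnorm(1 - bp[use])
  r <- scales[use]
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- n_boot * stats::dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients[1]); cc <- unname(fit$coefficients[2])
  list(au = 100 * (1 - stats::pnorm(v - cc)), v = v, c = cc)
}

#' Approximately-unbiased cluster p-values by multiscale bootstrap
#'
#' Columns (reporters) are resampled with replacement at several scales
#' `r`; per scale, `ceiling(r * n_columns)` columns are drawn, the rows are
#' reclustered, and the recovery frequency `BP_r` of each original node's
#' member set is recorded. The signed-distance / curvature model
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` is fitted by weighted
#' least squares and the AU value is `100 * (1 - pnorm(v - c))`. A node
#' never recovered at any scale gets AU 0 and is flagged.
#'
#' @param mat Atlas matrix, cells x reporters.
#' @param hc Optional precomputed [hierarchical_cluster()] result.
#' @param n_boot Bootstrap replicates per scale (>= 100; default 1000).
#' @param scales Resampling scales (default 10 steps over 0.5 to 1.4).
#' @param seed Required RNG seed.
#' @return Data.frame per internal node: `node`, `au`, `bp` (percent,
#'   at the scale nearest 1), `v`, `c`, `flagged`, plus the member list in
#'   attribute `members` and the tree in attribute `hclust`.
#' @export
au_pvalues <- function(mat, hc = NULL, n_boot = 1000L,
                       scales = seq(0.5, 1.4, length.out = 10), seed) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  if (n_boot < 100L) stop("n_boot must be at least 100")
  if (is.null(hc)) hc <- hierarchical_cluster(mat)
  members <- .node_members(hc, rownames(mat))
  keys <- vapply(members, paste, character(1), collapse = "\r")
  p <- ncol(mat)
  counts <- matrix(0L, length(keys), length(scales))
  .with_seed(seed, {
    for (si in seq_along(scales)) {
      m <- max(2L, ceiling(scales[si] * p))
      for (b in seq_len(n_boot)) {
        cols <- sample.int(p, m, replace = TRUE)
        bhc <- tryCatch(
          suppressWarnings(hierarchical_cluster(mat[, cols, drop = FALSE])),
          error = function(e) NULL)
        if (is.null(bhc)) next
        bkeys <- vapply(.node_members(bhc, rownames(mat)), paste,
                        character(1), collapse = "\r")
        counts[, si] <- counts[, si] + as.integer(keys %in% bkeys)
      }
    }
  })
  bp <- counts / n_boot
  near1 <- which.min(abs(scales - 1))
  fits <- lapply(seq_along(keys), function(i)
    .fit_au(bp[i, ], scales, n_boot))
  res <- data.frame(
    node = seq_along(keys),
    au = vapply(fits, `[[`, numeric(1), "au"),
    bp = 100 * bp[, near1],
    v = vapply(fits, `[[`, numeric(1), "v"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    flagged = vapply(fits, function(f) isTRUE(f$flagged), logical(1)))
  # root: always recovered by construction
  res$au[length(keys)] <- 100
  attr(res, "members") <- members
  attr(res, "hclust") <- hc
  res
}

#' Extract disjoint supported clusters from an AU-annotated dendrogram
#'
#' Scans the dendrogram top-down and keeps the maximal nodes whose AU
#' value reaches the threshold, so selected clusters are disjoint; cells
#' under no supported node are reported as singletons. The root node
#' (whose recovery is certain by construction, AU 100) is not itself a
#' candidate unless `include_root = TRUE`: the all-cells "cluster" carries
#' no grouping information.
#'
#' @param au An [au_pvalues()] result.
#' @param threshold Minimum AU (default 90).
#' @param include_root Allow the root to be selected as one cluster.
#' @return Data.frame `cell`, `cluster` (`C<k>` for supported clusters,
#'   `S<k>` for singletons) with per-cluster AU in attribute `cluster_au`.
#' @export
extract_clusters <- function(au, threshold = 90, include_root = FALSE) {
  hc <- attr(au, "hclust")
  members <- attr(au, "members")
  labels <- hc$labels
  root <- nrow(hc$merge)
  picked <- integer()
  walk <- function(node) {
    if (node > 0) {
      ok <- au$au[node] >= threshold && (include_root || node != root)
      if (ok) { picked <<- c(picked, node); return(invisible()) }
      walk(hc$merge[node, 1]); walk(hc$merge[node, 2])
    }
    # negative node = leaf; left unassigned here, becomes a singleton
  }
  walk(root)
  cell <- character(); cluster <- character(); cau <- numeric()
  for (k in seq_along(picked)) {
    mem <- members[[picked[k]]]
    cell <- c(cell, mem)
    cluster <- c(cluster, rep(sprintf("C%d", k), length(mem)))
    cau <- c(cau, au$au[picked[k]])
  }
  left <- setdiff(labels, cell)
  if (length(left)) {
    cell <- c(cell, left)
    cluster <- c(cluster, sprintf("S%d", seq_along(left)))
  }
  out <- data.frame(cell = cell, cluster = cluster)
  attr(out, "cluster_au") <- stats::setNames(cau,
                                             sprintf("C%d", seq_along(picked)))
  out
}

#' Tissue purity of extracted cell clusters
#'
#' For each cluster, the majority tissue and its fraction among cells with
#' a tissue label; the summary counts the fraction of clusters with more
#' than one cell whose majority fraction reaches the threshold.
#'
#' @param clusters An [extract_clusters()] result.
#' @param tt A `tissue_table`.
#' @param majority Purity threshold (default 0.75).
#' @return List `per_cluster` (cluster, size, majority_tissue, purity,
#'   passes) and `fraction_pure` over multi-cell clusters.
#' @export
cluster_tissue_purity <- function(clusters, tt, majority = 0.75) {
  lab <- tissue_of(tt)
  sp <- split(clusters$cell, clusters$cluster)
  rows <- lapply(names(sp), function(cl) {
    cells <- sp[[cl]]
    tis <- lab[cells]
    tis <- tis[!is.na(tis)]
    if (!length(tis))
      return(data.frame(cluster = cl, size = length(cells),
                        majority_tissue = NA_character_, purity = NA_real_,
                        passes = NA))
    tb <- table(tis)
    data.frame(cluster = cl, size = length(cells),
               majority_tissue = names(tb)[which.max(tb)],
               purity = max(tb) / sum(tb),
               passes = max(tb) / sum(tb) >= majority)
  })
  per <- do.call(rbind, rows)
  multi <- per[per$size > 1L & !is.na(per$passes), , drop = FALSE]
  list(per_cluster = per,
       fraction_pure = if (nrow(multi)) mean(multi$passes) else NA_real_)
}
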