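# Canonical full-size lineage model and synthetic small lineages.
#
# The full-size model reproduces the printed census of the invariant
# embryonic lineage -- 671 traced terminal cells of which 113 undergo
# programmed cell death, leaving 558 annotated L1 cells, classified into
# 11 tissues (neuron 202, glia 40, hypodermis 48, seam 20, P cell 12,
# pharynx 95, intestine 20, rectum-anus 15, body wall muscle 87,
# coelomocyte 4, excretory 6; germline and a few other cells unassigned).
# Topology below each founder and all division timings are synthetic: the
# census constrains counts, not branch shapes or clock times.

.axis_pair <- function(depth) {
  switch((depth %% 3L) + 1L, c("a", "p"), c("l", "r"), c("d", "v"))
}

# grow a balanced binary subtree below `root` with `n` leaves; returns
# data.frame(name, parent) excluding the root row, plus leaf order (DFS)
.grow_subtree <- function(root, n, depth = 0L) {
  if (n <= 1L)
    return(list(rows = data.frame(name = character(),
                                  parent = character()),
                leaves = root))
  ax <- .axis_pair(depth)
  nl <- ceiling(n / 2)
  kidL <- paste0(root, ax[1])
  kidR <- paste0(root, ax[2])
  L <- .grow_subtree(kidL, nl, depth + 1L)
  R <- .grow_subtree(kidR, n - nl, depth + 1L)
  list(rows = rbind(data.frame(name = c(kidL, kidR),
                               parent = c(root, root)),
                    L$rows, R$rows),
       leaves = c(L$leaves, R$leaves))
}

.scaffold <- data.frame(
  name   = c("P0", "AB", "P1", "ABa", "ABp", "EMS", "P2", "MS", "E",
             "C", "P3", "D", "P4", "Z2", "Z3"),
  parent = c(NA, "P0", "P0", "AB", "AB", "P1", "P1", "EMS", "EMS",
             "P2", "P2", "P3", "P3", "P4", "P4"))

.assemble_tree <- function(rows, leaves, deaths, tissue_map,
                           gen_len = 18, term_len = 30,
                           stage = "embryonic_traced") {
  df <- rows
  df$terminal <- df$name %in% leaves
  df$death <- df$name %in% deaths
  # depth from root for synthetic timings
  parent <- stats::setNames(df$parent, df$name)
  depth <- stats::setNames(integer(nrow(df)), df$name)
  for (nm in df$name) {
    d <- 0L; cur <- nm
    while (!is.na(parent[[cur]]) && parent[[cur]] %in% df$name) {
      cur <- parent[[cur]]; d <- d + 1L
    }
    depth[[nm]] <- d
  }
  df$birth <- depth[df$name] * gen_len
  df$end <- df$birth + ifelse(df$terminal, term_len, gen_len)
  df$tissue <- unname(tissue_map[df$name])
  lineage_tree(df, stage = stage)
}

# evenly spaced death-leaf positions within a founder's leaf list
.death_positions <- function(n_leaves, n_deaths) {
  if (n_deaths == 0L) return(integer())
  unique(round(seq(2, n_leaves - 1, length.out = n_deaths)))
}

#' Canonical full-size embryonic lineage model
#'
#' Deterministically builds the packaged full-size lineage: 671 traced
#' terminal cells (113 death-flagged, counted among the terminals), 558
#' surviving L1 cells, and the 11-tissue classification with the canonical
#' per-tissue census. Subtree topology and division timings are synthetic;
#' terminal counts, death counts and tissue counts are the modeled
#' quantities.
#'
#' @return A `lineage_tree` with tissue labels on surviving terminal cells.
#' @export
celegans_lineage <- function() {
  alloc <- list(
    ABa = c(n = 240L, deaths = 50L),
    ABp = c(n = 247L, deaths = 48L),
    MS  = c(n = 88L,  deaths = 9L),
    E   = c(n = 20L,  deaths = 0L),
    C   = c(n = 54L,  deaths = 6L),
    D   = c(n = 20L,  deaths = 0L))
  rows <- .scaffold
  leaves <- character(); deaths <- character()
  surv <- list()
  for (f in names(alloc)) {
    g <- .grow_subtree(f, alloc[[f]][["n"]])
    rows <- rbind(rows, g$rows)
    leaves <- c(leaves, g$leaves)
    dp <- .death_positions(length(g$leaves), alloc[[f]][["deaths"]])
    deaths <- c(deaths, g$leaves[dp])
    surv[[f]] <- setdiff(g$leaves, g$leaves[dp])
  }
  leaves <- c(leaves, "Z2", "Z3")
  # tissue schedule over surviving terminals, founder by founder
  sched <- list(
    E   = c(intestine = 20L),
    D   = c(`body wall muscle` = 20L),
    C   = c(`body wall muscle` = 35L, hypodermis = 13L),
    MS  = c(`body wall muscle` = 32L, pharynx = 30L, neuron = 17L),
    ABa = c(pharynx = 65L, neuron = 90L, glia = 15L, hypodermis = 12L,
            seam = 8L),
    ABp = c(neuron = 95L, glia = 25L, hypodermis = 23L, seam = 12L,
            `P cell` = 12L, `rectum-anus` = 15L, coelomocyte = 4L,
            excretory = 6L))
  tissue_map <- stats::setNames(rep(NA_character_, length(leaves)), leaves)
  for (f in names(sched)) {
    labs <- rep(names(sched[[f]]), times = sched[[f]])
    cells <- surv[[f]]
    tissue_map[cells[seq_along(labs)]] <- labs
  }
  .assemble_tree(rows, leaves, deaths, tissue_map)
}

#' Canonical tissue table for the 558 L1 cells
#'
#' @param tree Optionally a precomputed [celegans_lineage()] tree.
#' @return A `tissue_table` over the surviving terminal cells (cells
#'   without one of the 11 labels, e.g. germline, carry `NA`).
#' @export
celegans_tissue_table <- function(tree = celegans_lineage()) {
  cells <- terminal_cells(tree, surviving = TRUE)
  tissue_table(data.frame(cell = cells,
                          tissue = tree$tissue[match(cells, tree$name)]))
}

#' Small synthetic lineage for simulations
#'
#' A reduced invariant lineage with the same structure as the full model:
#' binary divisions from the four 4-cell-stage origins, Sulston names,
#' contiguous tissue blocks over the terminal cells.
#'
#' @param n_terminals Number of terminal cells (default 64).
#' @param n_tissues Number of tissue labels used, taken from
#'   [tissue_labels()] (default 4).
#' @param tissue_weights Relative tissue sizes; by default proportional to
#'   the canonical census of the chosen labels (real tissues are strongly
#'   unequal: e.g. neuron 202 cells vs seam 20), so scaled-down lineages
#'   keep that skew.
#' @param gen_len,term_len Cell lifespans in frames (1 frame = 75 s).
#' @return A `lineage_tree`.
#' @export
synthetic_lineage <- function(n_terminals = 64L, n_tissues = 4L,
                              tissue_weights = NULL,
                              gen_len = 18, term_len = 30) {
  stopifnot(n_terminals >= 4L, n_tissues >= 1L,
            n_tissues <= length(tissue_labels()))
  census <- c(neuron = 202, glia = 40, hypodermis = 48, seam = 20,
              `P cell` = 12, pharynx = 95, intestine = 20,
              `rectum-anus` = 15, `body wall muscle` = 87,
              coelomocyte = 4, excretory = 6)
  if (is.null(tissue_weights))
    tissue_weights <- unname(census[tissue_labels()[seq_len(n_tissues)]])
  stopifnot(length(tissue_weights) == n_tissues, all(tissue_weights > 0))
  origins <- c("ABa", "ABp", "EMS", "P2")
  cuts <- round(seq(0, n_terminals, length.out = 5L))
  per <- diff(cuts)
  rows <- .scaffold[.scaffold$name %in%
                      c("P0", "AB", "P1", "ABa", "ABp", "EMS", "P2"), ]
  leaves <- character()
  for (i in seq_along(origins)) {
    g <- .grow_subtree(origins[i], per[i])
    rows <- rbind(rows, g$rows)
    leaves <- c(leaves, g$leaves)
  }
  bcuts <- round(cumsum(c(0, tissue_weights)) / sum(tissue_weights) *
                   length(leaves))
  labs <- rep(tissue_labels()[seq_len(n_tissues)], times = diff(bcuts))
  tissue_map <- stats::setNames(labs, leaves)
  .assemble_tree(rows, leaves, character(), tissue_map,
                 gen_len = gen_len, term_len = term_len)
}

#' Load the packaged miRNA annotation fixture
#'
#' A synthetic annotation of the 61 conserved miRNAs expressed during
#' embryogenesis or at L1, with intronic-location and prior-study flags
#' used for reporter-panel selection.
#' @return A data.frame with columns `mirna`, `conserved`,
#'   `expressed_embryo_or_l1`, `intronic_same_strand`, `previously_studied`,
#'   `family`.
#' @export
mirna_annotation <- function() {
  path <- system.file("extdata", "mirna_panel_synthetic.tsv",
                      package = "miratlas")
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "logical", "logical",
                                   "logical", "logical", "character"))
}

#' Select the reporter panel from a miRNA annotation
#'
#' Keeps conserved miRNAs expressed during embryogenesis or at the L1
#' stage, excluding those located within an intron and transcribed in the
#' same direction as the host gene unless previously studied.
#'
#' @param annot An annotation data.frame as from [mirna_annotation()].
#' @return The filtered annotation (the reporter panel).
#' @export
select_reporter_panel <- function(annot) {
  keep <- annot$conserved & annot$expressed_embryo_or_l1 &
    !(annot$intronic_same_strand & !annot$previously_studied)
  out <- annot[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
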