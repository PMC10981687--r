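# Lineage-tree data model: Sulston nomenclature, tree validation, cell tracks,
# tissue assignment tables, TSV/Newick serialization.

#' @keywords internal
.founders <- c("P0", "P1", "P2", "P3", "P4",
               "AB", "EMS", "MS", "E", "C", "D", "Z2", "Z3")

#' @keywords internal
.founder_parent <- c(
  P0 = NA_character_, AB = "P0", P1 = "P0", EMS = "P1", P2 = "P1",
  MS = "EMS", E = "EMS", C = "P2", P3 = "P2", D = "P3", P4 = "P3",
  Z2 = "P4", Z3 = "P4"
)

#' @keywords internal
.axis_letters <- c("a", "p", "l", "r", "d", "v")

#' The eleven terminal-cell tissue classes
#'
#' Controlled vocabulary of the tissue/cell-type labels used for terminal
#' cells: neuron, glia, hypodermis, seam, P cell, pharynx, intestine,
#' rectum-anus, body wall muscle, coelomocyte, excretory.
#' @return Character vector of the 11 labels.
#' @export
tissue_labels <- function() {
  c("neuron", "glia", "hypodermis", "seam", "P cell", "pharynx",
    "intestine", "rectum-anus", "body wall muscle", "coelomocyte",
    "excretory")
}

#' Parse a Sulston cell name
#'
#' Daughters carry the mother's full name plus one axis letter (a/p for
#' anterior-posterior, l/r for left-right, d/v for dorsal-ventral
#' divisions). Founder cells (P0-P4, AB, EMS, MS, E, C, D, Z2, Z3) are
#' exceptions resolved by lookup.
#'
#' @param name A single cell name.
#' @return A list with elements `valid` (logical), `parent` (parent name or
#'   `NA` for P0 / invalid names) and `reason` (why invalid, or `NA`).
#' @examples
#' parse_cell_name("ABpr")  # parent "ABp"
#' parse_cell_name("EMS")   # founder, parent "P1"
#' @export
parse_cell_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name)) {
    return(list(valid = FALSE, parent = NA_character_,
                reason = "empty or non-scalar name"))
  }
  if (name %in% .founders) {
    return(list(valid = TRUE, parent = unname(.founder_parent[name]),
                reason = NA_character_))
  }
  last <- substr(name, nchar(name), nchar(name))
  if (!last %in% .axis_letters) {
    return(list(valid = FALSE, parent = NA_character_,
                reason = sprintf("final character '%s' is not an axis letter",
                                 last)))
  }
  list(valid = TRUE, parent = substr(name, 1L, nchar(name) - 1L),
       reason = NA_character_)
}

#' Vectorized parent lookup for Sulston names
#' @param names Character vector of cell names.
#' @return Character vector of parent names (`NA` where invalid or root).
#' @export
sulston_parent <- function(names) {
  vapply(names, function(n) parse_cell_name(n)$parent, character(1),
         USE.NAMES = FALSE)
}

#' Construct a validated lineage tree
#'
#' @param nodes A data.frame with columns `name`, `parent`, `birth`, `end`,
#'   `terminal` (logical), `death` (logical), `tissue` (label or `NA`).
#'   An `axis` column (final division axis letter, or "none") is derived
#'   if absent.
#' @param stage Either `"embryonic_traced"` or `"L1"`.
#' @return A `lineage_tree` object (a validated data.frame).
#' @export
lineage_tree <- function(nodes, stage = c("embryonic_traced", "L1")) {
  stage <- match.arg(stage)
  req <- c("name", "parent", "birth", "end", "terminal", "death", "tissue")
  miss <- setdiff(req, names(nodes))
  if (length(miss))
    stop("lineage table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(nodes$name))
    stop("duplicate cell names in lineage table")
  if (!"axis" %in% names(nodes)) {
    last <- substr(nodes$name, nchar(nodes$name), nchar(nodes$name))
    nodes$axis <- ifelse(nodes$name %in% .founders, "none",
                         ifelse(last %in% c("a", "p"), "a/p",
                                ifelse(last %in% c("l", "r"), "l/r", "d/v")))
  }
  # name consistency: non-founder name must be parent + one axis letter
  for (i in seq_len(nrow(nodes))) {
    p <- parse_cell_name(nodes$name[i])
    if (!p$valid)
      stop("malformed cell name '", nodes$name[i], "': ", p$reason)
    if (!is.na(p$parent) && !is.na(nodes$parent[i]) &&
        p$parent != nodes$parent[i])
      stop("cell '", nodes$name[i], "' stored parent '", nodes$parent[i],
           "' disagrees with nomenclature parent '", p$parent, "'")
  }
  if (any(nodes$birth >= nodes$end))
    stop("birth_time must precede end_time for every cell")
  # each node has 0 or 2 daughters
  kids <- table(nodes$parent[!is.na(nodes$parent) &
                               nodes$parent %in% nodes$name])
  bad <- names(kids)[kids != 2L]
  if (length(bad))
    stop("cells with a number of daughters other than 0 or 2: ",
         paste(utils::head(bad, 5), collapse = ", "))
  rownames(nodes) <- NULL
  structure(nodes, class = c("lineage_tree", "data.frame"),
            stage_tag = stage)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %d cells (%d terminal, %d deaths), stage %s\n",
              nrow(x), sum(x$terminal), sum(x$death),
              attr(x, "stage_tag")))
  invisible(x)
}

#' Terminal cells of a lineage tree
#' @param tree A `lineage_tree`.
#' @param surviving Drop death-flagged terminals if `TRUE`.
#' @return Character vector of terminal-cell names.
#' @export
terminal_cells <- function(tree, surviving = FALSE) {
  keep <- tree$terminal
  if (surviving) keep <- keep & !tree$death
  tree$name[keep]
}

#' Cells present at the 4-cell stage
#'
#' ABa, ABp, EMS and P2 are the canonical origins of cell tracks; for trees
#' that do not contain all of them the earliest recorded ancestors are used.
#' @param tree A `lineage_tree`.
#' @return Character vector of origin cell names.
#' @export
four_cell_origins <- function(tree) {
  canon <- c("ABa", "ABp", "EMS", "P2")
  present <- canon[canon %in% tree$name]
  if (length(present)) return(present)
  tree$name[is.na(tree$parent) | !(tree$parent %in% tree$name)]
}

#' Build cell tracks from a lineage tree
#'
#' A cell track is the temporally ordered mother-daughter chain from a
#' 4-cell-stage origin to one terminal cell; embryonic expression is
#' averaged along these chains.
#'
#' @param tree A `lineage_tree` (stage `embryonic_traced`).
#' @return A named list, one character vector (origin ... terminal) per
#'   terminal cell.
#' @export
build_tracks <- function(tree) {
  origins <- four_cell_origins(tree)
  parent <- stats::setNames(tree$parent, tree$name)
  terms <- terminal_cells(tree)
  tracks <- vector("list", length(terms))
  names(tracks) <- terms
  for (tc in terms) {
    chain <- tc
    cur <- tc
    while (!cur %in% origins) {
      nxt <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
      if (is.na(nxt) || !(nxt %in% tree$name))
        stop("terminal cell '", tc,
             "' is not reachable from a 4-cell-stage origin")
      cur <- nxt
      chain <- c(cur, chain)
      if (length(chain) > nrow(tree)) stop("cycle detected in lineage tree")
    }
    tracks[[tc]] <- chain
  }
  tracks
}

#' Construct a validated tissue-assignment table
#'
#' @param df A data.frame with columns `cell` and `tissue`; tissues must be
#'   in [tissue_labels()] or `NA` (unassigned cells, e.g. germline, carry
#'   `NA` and are excluded from tissue statistics).
#' @return A `tissue_table` object.
#' @export
tissue_table <- function(df) {
  if (!all(c("cell", "tissue") %in% names(df)))
    stop("tissue table needs columns 'cell' and 'tissue'")
  if (anyDuplicated(df$cell))
    stop("duplicate cell rows in tissue table")
  bad <- setdiff(stats::na.omit(unique(df$tissue)), tissue_labels())
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  rownames(df) <- NULL
  structure(df[, c("cell", "tissue")],
            class = c("tissue_table", "data.frame"))
}

#' Load a tissue table from TSV
#' @param path TSV with header columns `cell`, `tissue`.
#' @return A `tissue_table`.
#' @export
load_tissue_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (nrow(df) == 0)
    return(tissue_table(data.frame(cell = character(),
                                   tissue = character())))
  tissue_table(df)
}

#' Tissue lookup vector from a tissue table
#' @param tt A `tissue_table`.
#' @return Named character vector `cell -> tissue` (`NA` for unassigned).
#' @export
tissue_of <- function(tt) stats::setNames(tt$tissue, tt$cell)

#' Write / read a lineage tree as flat TSV
#'
#' Columns: name, parent, axis, birth, end, terminal, death, tissue.
#' @param tree A `lineage_tree`.
#' @param path Output path.
#' @export
write_lineage_tsv <- function(tree, path) {
  df <- as.data.frame(tree)[, c("name", "parent", "axis", "birth", "end",
                                "terminal", "death", "tissue")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_lineage_tsv
#' @param stage Stage tag for the reconstructed tree.
#' @export
read_lineage_tsv <- function(path, stage = "embryonic_traced") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = "NA",
                          colClasses = c(name = "character",
                                         parent = "character",
                                         axis = "character",
                                         birth = "numeric", end = "numeric",
                                         terminal = "logical",
                                         death = "logical",
                                         tissue = "character"))
  lineage_tree(df, stage = stage)
}

#' Newick export of a lineage tree
#'
#' Branch lengths are cell lifespans in frame units (1 frame = 75 s).
#' @param tree A `lineage_tree`.
#' @return A single Newick string.
#' @export
as_newick <- function(tree) {
  children <- split(tree$name[!is.na(tree$parent)],
                    tree$parent[!is.na(tree$parent)])
  span <- stats::setNames(tree$end - tree$birth, tree$name)
  roots <- tree$name[is.na(tree$parent) | !(tree$parent %in% tree$name)]
  rec <- function(n) {
    kids <- children[[n]]
    bl <- format(span[[n]], trim = TRUE)
    if (is.null(kids)) return(sprintf("%s:%s", n, bl))
    sprintf("(%s)%s:%s", paste(vapply(kids, rec, character(1)),
                               collapse = ","), n, bl)
  }
  if (length(roots) == 1L) paste0(rec(roots), ";")
  else paste0("(", paste(vapply(roots, rec, character(1)), collapse = ","),
              ");")
}
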