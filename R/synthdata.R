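# Seeded generators for every pipeline input, with known ground truth.
# Every generator is a pure function of (configuration, seed).

.with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is required (reproducibility contract)")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Imaging model for reporter quantification
#'
#' Describes confocal acquisition of the nuclear reporter: Gaussian
#' background and measurement noise, exponential depth attenuation across
#' the 30 z-planes partially compensated by a multiplicative laser ramp
#' (laser power raised by 3\% per deeper plane), and the 75 s frame
#' interval.
#'
#' @param background_mean,background_sd Background fluorescence (AU).
#' @param measurement_sd Per-measurement noise sd (AU).
#' @param attenuation_length Depth attenuation length, in z-planes.
#' @param laser_ramp Multiplicative laser gain per plane (default 1.03).
#' @param planes Number of z-planes (default 30).
#' @param frame_interval Seconds per frame (default 75; presentation only).
#' @return An `imaging_model` list.
#' @export
imaging_model <- function(background_mean = 30, background_sd = 2,
                          measurement_sd = 1, attenuation_length = 20,
                          laser_ramp = 1.03, planes = 30L,
                          frame_interval = 75) {
  stopifnot(background_sd >= 0, measurement_sd >= 0,
            attenuation_length > 0, laser_ramp > 0, planes >= 1)
  structure(list(background_mean = background_mean,
                 background_sd = background_sd,
                 measurement_sd = measurement_sd,
                 attenuation_length = attenuation_length,
                 laser_ramp = laser_ramp, planes = as.integer(planes),
                 frame_interval = frame_interval),
            class = "imaging_model")
}

#' Net depth attenuation factor at z-plane `z`
#'
#' `attenuation(z) = exp(-z / lambda) * ramp^z`: exponential signal decay
#' with depth, partially compensated by the laser ramp.
#' @param model An [imaging_model()].
#' @param z Integer z-plane(s), 0-based.
#' @return Numeric attenuation factor(s) in (0, Inf).
#' @export
attenuation <- function(model, z) {
  if (any(z < 0 | z >= model$planes))
    stop("z-plane outside [0, planes)")
  exp(-z / model$attenuation_length) * model$laser_ramp^z
}

#' Ground-truth reporter program
#'
#' Cells in `active_cells` transcribe the reporter; the histone-fusion
#' fluorophore accumulates at `rate` per frame from each cell's onset frame
#' (default: the cell's birth) and never decays within a run.
#'
#' @param reporter_id Reporter name.
#' @param active_cells Character vector of transcribing cells.
#' @param rate Fluorophore accumulation per frame in active cells (AU).
#' @param onset_times Optional named vector of activation frames per cell.
#' @return A `reporter_program` list.
#' @export
reporter_program <- function(reporter_id, active_cells = character(),
                             rate = 5, onset_times = NULL) {
  stopifnot(rate > 0)
  structure(list(reporter_id = reporter_id,
                 active_cells = unique(active_cells),
                 rate = rate, onset_times = onset_times),
            class = "reporter_program")
}

#' Planted pan-tissue reporter program
#'
#' Transcription is on in every cell of the focus tissue's tracks from
#' the grandmother generation onward, plus sporadic ectopic activity in a
#' fraction of off-tissue terminal cells (real promoter reporters are
#' statistically, not absolutely, tissue-restricted; scattered off-tissue
#' signal is the norm and keeps cross-tissue expression profiles from
#' being degenerately tied).
#'
#' @param id Reporter id.
#' @param tree A `lineage_tree` with tissue labels.
#' @param tissue Focus tissue label.
#' @param rate Accumulation rate per frame.
#' @param off_fraction Fraction of off-tissue surviving terminals with
#'   ectopic activity (default 0.1).
#' @param seed Required seed for the ectopic-cell draw.
#' @return A [reporter_program()].
#' @export
pan_tissue_program <- function(id, tree, tissue, rate = 5,
                               off_fraction = 0.1, seed) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  parent <- stats::setNames(tree$parent, tree$name)
  terms <- tree$name[tree$terminal & !tree$death &
                       !is.na(tree$tissue) & tree$tissue == tissue]
  cells <- unique(c(terms, parent[terms],
                    parent[stats::na.omit(parent[terms])]))
  others <- setdiff(terminal_cells(tree, surviving = TRUE), terms)
  off <- .with_seed(seed,
                    sample(others, round(off_fraction * length(others))))
  reporter_program(id,
                   active_cells = as.character(
                     stats::na.omit(c(cells, off))),
                   rate = rate)
}

#' Simulate nuclear-reporter intensity traces
#'
#' Emulates per-nucleus quantification of a cumulative histone-fusion
#' reporter: in active cells the signal concentration grows by
#' `rate` per frame since onset; daughters inherit the mother's signal
#' concentration unchanged at division; the measured nucleus mean is the
#' depth-attenuated signal plus shared background plus noise, and the
#' annulus mean is the same background plus independent noise.
#'
#' @param tree A `lineage_tree`.
#' @param program A [reporter_program()]; cells must exist in the tree.
#' @param model An [imaging_model()].
#' @param seed Required RNG seed.
#' @param n_embryos Number of replicate embryos to stack.
#' @return A data.frame with columns `embryo`, `cell`, `frame`,
#'   `nucleus_mean`, `annulus_mean`, `z`.
#' @export
simulate_reporter_imaging <- function(tree, program, model, seed,
                                      n_embryos = 1L) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  unknown <- setdiff(program$active_cells, tree$name)
  if (length(unknown))
    stop("program cells absent from tree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  ord <- order(tree$birth)   # parents precede daughters
  cells <- tree$name[ord]
  birth <- stats::setNames(tree$birth, tree$name)
  endt <- stats::setNames(tree$end, tree$name)
  parent <- stats::setNames(tree$parent, tree$name)
  active <- cells %in% program$active_cells
  names(active) <- cells
  onset <- stats::setNames(birth[cells], cells)
  if (!is.null(program$onset_times)) {
    ii <- intersect(names(program$onset_times), cells)
    onset[ii] <- program$onset_times[ii]
  }
  # inherited signal concentration at each cell's birth
  inherit <- stats::setNames(numeric(length(cells)), cells)
  ends <- stats::setNames(numeric(length(cells)), cells)
  for (cl in cells) {
    p <- parent[[cl]]
    s0 <- if (!is.na(p) && p %in% cells) ends[[p]] else 0
    inherit[[cl]] <- s0
    gain <- if (active[[cl]]) program$rate * max(0, endt[[cl]] - onset[[cl]])
            else 0
    ends[[cl]] <- s0 + gain
  }
  nfr <- as.integer(endt[cells] - birth[cells])
  cell_col <- rep(cells, times = nfr)
  frame_col <- unlist(lapply(seq_along(cells), function(i)
    seq.int(birth[[cells[i]]], endt[[cells[i]]] - 1L)), use.names = FALSE)
  sig <- inherit[cell_col] +
    ifelse(active[cell_col],
           program$rate * pmax(0, frame_col - onset[cell_col]), 0)
  m <- length(cell_col)
  .with_seed(seed, {
    out <- vector("list", n_embryos)
    for (e in seq_len(n_embryos)) {
      z <- sample.int(model$planes, m, replace = TRUE) - 1L
      bg <- stats::rnorm(m, model$background_mean, model$background_sd)
      nuc <- sig * attenuation(model, z) + bg +
        stats::rnorm(m, 0, model$measurement_sd)
      ann <- bg + stats::rnorm(m, 0, model$measurement_sd)
      out[[e]] <- data.frame(embryo = e, cell = cell_col,
                             frame = frame_col, nucleus_mean = nuc,
                             annulus_mean = ann, z = z)
    }
    do.call(rbind, out)
  })
}

#' Simulate a negative-control strain (no reporter transgene)
#'
#' Identical acquisition model with an empty reporter program; the
#' background-subtracted values are centered on zero with variance
#' `2 * measurement_sd^2`.
#' @inheritParams simulate_reporter_imaging
#' @return As [simulate_reporter_imaging()].
#' @export
simulate_negative_control <- function(tree, model, seed, n_embryos = 1L) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  simulate_reporter_imaging(tree,
                            reporter_program("negative_control"),
                            model, seed, n_embryos = n_embryos)
}

#' Simulate L1-stage cellular expression of a reporter
#'
#' One value per surviving terminal cell: active cells carry the
#' accumulated signal for `l1_frames` frames of transcription plus
#' measurement noise; inactive cells carry background-subtracted noise
#' only.
#' @inheritParams simulate_reporter_imaging
#' @param l1_frames Effective accumulation frames at L1 (default 20).
#' @return Named numeric vector over surviving terminal cells.
#' @export
simulate_l1_expression <- function(tree, program, model, seed,
                                   l1_frames = 20) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  cells <- terminal_cells(tree, surviving = TRUE)
  act <- cells %in% program$active_cells
  .with_seed(seed, {
    noise <- stats::rnorm(length(cells), 0,
                          sqrt(2) * model$measurement_sd)
    stats::setNames(ifelse(act, program$rate * l1_frames, 0) + noise,
                    cells)
  })
}

#' Ground truth for a synthetic track-level transcriptome
#'
#' @param tsg_labels Named character vector `gene -> focus tissue`
#'   (`NA` for genes expressed everywhere).
#' @param focus_level Median TPM-like level in focus-tissue tracks.
#' @param leak_level Median level of leaky expression outside the focus
#'   tissue; must be below `focus_level`.
#' @param leak_fraction Probability that a non-focus track expresses the
#'   gene at all (default 0.3).
#' @param noise_sdlog Log-normal sd of expression noise.
#' @return A `transcriptome_truth` list.
#' @export
transcriptome_truth <- function(tsg_labels, focus_level = 100,
                                leak_level = 10, leak_fraction = 0.3,
                                noise_sdlog = 0.5) {
  stopifnot(focus_level > leak_level, leak_level >= 0,
            leak_fraction >= 0, leak_fraction <= 1)
  structure(list(tsg_labels = tsg_labels, focus_level = focus_level,
                 leak_level = leak_level, leak_fraction = leak_fraction,
                 noise_sdlog = noise_sdlog),
            class = "transcriptome_truth")
}

#' Simulate a track-level transcriptome with planted TSGs
#'
#' @param track_tissues Named character vector `track -> tissue`.
#' @param truth A [transcriptome_truth()].
#' @param seed Required RNG seed.
#' @return Numeric matrix, genes x tracks (TPM-like).
#' @export
simulate_track_transcriptome <- function(track_tissues, truth, seed) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  genes <- names(truth$tsg_labels)
  tracks <- names(track_tissues)
  .with_seed(seed, {
    mat <- matrix(0, length(genes), length(tracks),
                  dimnames = list(genes, tracks))
    for (g in genes) {
      foc <- truth$tsg_labels[[g]]
      lev <- stats::rlnorm(length(tracks), log(truth$focus_level),
                           truth$noise_sdlog)
      if (is.na(foc)) {
        mat[g, ] <- lev
      } else {
        infoc <- track_tissues == foc
        mat[g, infoc] <- lev[infoc]
        leaks <- !infoc &
          stats::runif(length(tracks)) < truth$leak_fraction
        mat[g, leaks] <- stats::rlnorm(sum(leaks),
                                       log(max(truth$leak_level, 1e-8)),
                                       truth$noise_sdlog)
      }
    }
    mat
  })
}

#' Generate synthetic 3'UTRs with planted miRNA seed sites
#'
#' Random-background DNA UTRs with 8mer / 7mer-m8 / 7mer-A1 sites planted
#' at a controlled per-gene, per-miRNA rate on the sense strand. The
#' returned target table is the [scan_seed_sites()] output on the emitted
#' sequences, so the two are self-consistent by construction.
#'
#' @param genes Character vector of gene ids.
#' @param mirna_seeds Named character vector of miRNA 5' regions
#'   (positions 1-8, RNA or DNA alphabet).
#' @param density Expected planted site count per gene per miRNA
#'   (Poisson mean); 0 leaves chance background matches only.
#' @param utr_length Length range (min, max), minimum at least 50 nt.
#' @param site_type_probs Sampling weights for types 8mer, 7mer-m8,
#'   7mer-A1 when planting.
#' @param seed Required RNG seed.
#' @return List with `utrs` (named character vector) and `targets`
#'   (data.frame gene, mirna, site_type, start, end; 0-based half-open).
#' @export
generate_utrs_and_targets <- function(genes, mirna_seeds, density = 1,
                                      utr_length = c(200L, 800L),
                                      site_type_probs = c(0.5, 0.25, 0.25),
                                      seed) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  stopifnot(utr_length[1] >= 50L, density >= 0)
  .with_seed(seed, {
    utrs <- stats::setNames(vapply(genes, function(g) {
      len <- sample(seq.int(utr_length[1], utr_length[2]), 1L)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1)), genes)
    for (g in genes) {
      for (mi in names(mirna_seeds)) {
        k <- stats::rpois(1, density)
        if (k == 0) next
        site_by_type <- seed_site_patterns(mirna_seeds[[mi]])
        for (j in seq_len(k)) {
          type <- sample(names(site_by_type), 1L, prob = site_type_probs)
          pat <- site_by_type[[type]]
          len <- nchar(utrs[[g]])
          if (len < nchar(pat) + 2L) next
          pos <- sample.int(len - nchar(pat) + 1L, 1L)
          substr(utrs[[g]], pos, pos + nchar(pat) - 1L) <- pat
        }
      }
    }
    list(utrs = utrs,
         targets = scan_all_targets(utrs, mirna_seeds))
  })
}

#' Simulate TF ChIP peaks around promoter windows
#'
#' Places one peak per bound (TF, gene) pair with its midpoint uniformly
#' inside the gene's promoter window (TSS-2000 to TSS+100 in transcription
#' orientation) and, optionally, decoy peaks well outside the window for
#' unbound pairs.
#'
#' @param tss_table Data.frame with columns `gene`, `chrom`, `tss`,
#'   `strand` (TSS coordinates 0-based).
#' @param binding Logical matrix TFs x genes: ground-truth binding.
#' @param peak_width Peak width in bp (default 200).
#' @param decoy_offset Distance beyond the window for unbound-pair decoy
#'   peaks (default 5000); set `NA` to emit no decoys.
#' @param seed Required RNG seed.
#' @return Data.frame `chrom`, `start`, `end`, `tf` (BED-like 0-based
#'   half-open intervals).
#' @export
simulate_tf_peaks <- function(tss_table, binding, peak_width = 200L,
                              decoy_offset = 5000L, seed) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  win <- promoter_windows(tss_table)
  half <- peak_width %/% 2L
  .with_seed(seed, {
    rows <- list()
    for (tf in rownames(binding)) {
      for (g in colnames(binding)) {
        w <- win[win$gene == g, ]
        if (nrow(w) == 0) next
        if (isTRUE(binding[tf, g])) {
          mid <- sample(seq.int(w$start + half, w$end - half - 1L), 1L)
        } else if (!is.na(decoy_offset)) {
          side <- sample(c(-1L, 1L), 1L)
          mid <- if (side < 0) w$start - decoy_offset - half
                 else w$end + decoy_offset + half
          mid <- max(mid, half)
        } else next
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = w$chrom, start = max(0L, mid - half),
                     end = mid + half, tf = tf)
      }
    }
    do.call(rbind, rows)
  })
}
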