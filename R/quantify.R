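# Per-cell reporter-expression quantification: background subtraction,
# depth correction, quantile cutoff calibration, increased-expression
# inference, representative-strain selection.

#' Background-subtract an intensity trace
#'
#' Net value per frame = nucleus mean minus the local-background annulus
#' mean. Negative values are permitted at this stage (they are only zeroed
#' by the expression cutoff later, which keeps the averaging unbiased).
#'
#' @param trace Data.frame with columns `cell`, `frame`, `nucleus_mean`,
#'   `annulus_mean`, `z` (one cell or many).
#' @return The input with a `net` column; frames with a missing annulus
#'   value are dropped with a warning.
#' @export
subtract_background <- function(trace) {
  if (nrow(trace) == 0) stop("empty intensity trace")
  bad <- is.na(trace$annulus_mean) | is.na(trace$nucleus_mean)
  if (any(bad)) {
    warning(sum(bad), " frame(s) dropped: missing nucleus/annulus value")
    trace <- trace[!bad, , drop = FALSE]
  }
  trace$net <- trace$nucleus_mean - trace$annulus_mean
  trace
}

#' Correct depth attenuation of net intensities
#'
#' Divides each net value by the imaging model's attenuation factor at its
#' z-plane, so the same true signal measured at different depths agrees in
#' expectation.
#'
#' @param net Numeric net values.
#' @param z Integer z-plane per value (0-based).
#' @param model An [imaging_model()].
#' @return Corrected numeric values.
#' @export
correct_depth_attenuation <- function(net, z, model) {
  net / attenuation(model, z)
}

#' Calibrate the expression cutoff on negative-control values
#'
#' The cutoff is the (1 - target_fdr) empirical quantile (inverse-ECDF
#' definition) of control cell-timepoint values, floored at zero, so that
#' the fraction of control values exceeding it is at most `target_fdr`.
#' The conventional fixed cutoff of 3.2 intensity units can be imposed via
#' `override`.
#'
#' @param control_values Background-subtracted, depth-corrected values from
#'   a negative-control strain.
#' @param target_fdr Target false-discovery rate of expression calls per
#'   cell-timepoint (default 1e-4, i.e. 0.01\%).
#' @param override Optional fixed cutoff replacing the calibrated one.
#' @return A `cutoff_calibration` list: `cutoff`, `target_fdr`,
#'   `n_control`, `empirical_fdr`.
#' @export
calibrate_cutoff <- function(control_values, target_fdr = 1e-4,
                             override = NULL) {
  if (length(control_values) == 0) stop("no control values supplied")
  if (length(control_values) < 10 / target_fdr)
    warning("fewer than 10/target_fdr control values; ",
            "the calibrated quantile is unstable")
  cutoff <- if (!is.null(override)) override else
    max(0, stats::quantile(control_values, 1 - target_fdr, type = 1,
                           names = FALSE))
  structure(list(cutoff = cutoff, target_fdr = target_fdr,
                 n_control = length(control_values),
                 empirical_fdr = mean(control_values > cutoff)),
            class = "cutoff_calibration")
}

#' Per-cell expression summary with cutoff thresholding
#'
#' The corrected net intensity is averaged across all traced time points
#' of the cell; a mean below the cutoff is set to zero.
#'
#' @param corrected Corrected net values of one cell.
#' @param calib A [calibrate_cutoff()] result (or a bare cutoff number).
#' @return List `value` (thresholded mean, >= 0) and `n_frames`.
#' @export
summarize_cell_expression <- function(corrected, calib) {
  if (length(corrected) == 0) stop("no corrected values for cell")
  cutoff <- if (inherits(calib, "cutoff_calibration")) calib$cutoff
            else calib
  m <- mean(corrected)
  list(value = if (m < cutoff) 0 else m, n_frames = length(corrected))
}

#' Quantify all cells of a traced embryo
#'
#' Convenience wrapper: background subtraction, depth correction and
#' per-cell cutoff thresholding over a whole traces table.
#'
#' @param traces Traces data.frame (`cell`, `frame`, `nucleus_mean`,
#'   `annulus_mean`, `z`).
#' @param model An [imaging_model()].
#' @param calib A [calibrate_cutoff()] result.
#' @return Data.frame `cell`, `value`, `n_frames`.
#' @export
quantify_embryo <- function(traces, model, calib) {
  tr <- subtract_background(traces)
  tr$corrected <- correct_depth_attenuation(tr$net, tr$z, model)
  vals <- split(tr$corrected, tr$cell)
  out <- data.frame(cell = names(vals),
                    value = NA_real_, n_frames = NA_integer_)
  for (i in seq_len(nrow(out))) {
    s <- summarize_cell_expression(vals[[i]], calib)
    out$value[i] <- s$value
    out$n_frames[i] <- s$n_frames
  }
  out
}

# early/late split: first 10 frames if more than 20 traced, else first half
.early_window <- function(n) if (n > 20L) 10L else n %/% 2L

#' Infer increased expression from cumulative reporter traces
#'
#' Because the histone-fusion signal is cumulative, promoter activity in a
#' cell is inferred from a rise of intensity within the cell's own traced
#' time points: the late window is compared to the early window
#' (Mann-Whitney, two-sided), q-values are Benjamini-Hochberg corrected
#' across all tested cells, and a call requires Q < alpha together with a
#' higher late-window median. Cells with fewer than 12 traced time points
#' are not tested. The onset cell of an expressing cell track is
#' classified as increased by rule.
#'
#' @param values_by_cell Named list of per-cell ordered frame values.
#' @param alpha BH-corrected significance level (default 0.05).
#' @param onset_cells Cells forced to `increased` by the onset rule.
#' @return Data.frame `cell`, `increased`, `p`, `q`, `reason`
#'   (`window_test`, `onset_rule` or `insufficient_frames`).
#' @export
infer_increased_expression <- function(values_by_cell, alpha = 0.05,
                                       onset_cells = character()) {
  cells <- names(values_by_cell)
  n <- lengths(values_by_cell)
  testable <- n >= 12L
  p <- rep(NA_real_, length(cells))
  dir_up <- rep(FALSE, length(cells))
  for (i in which(testable)) {
    v <- values_by_cell[[i]]
    k <- .early_window(length(v))
    early <- v[seq_len(k)]
    late <- v[-seq_len(k)]
    if (length(unique(v)) == 1L) {
      p[i] <- 1
    } else {
      p[i] <- suppressWarnings(
        stats::wilcox.test(late, early, alternative = "two.sided")$p.value)
    }
    dir_up[i] <- stats::median(late) > stats::median(early)
  }
  q <- rep(NA_real_, length(cells))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  increased <- !is.na(q) & q < alpha & dir_up
  reason <- ifelse(testable, "window_test", "insufficient_frames")
  onset <- cells %in% onset_cells
  increased[onset] <- TRUE
  reason[onset] <- "onset_rule"
  data.frame(cell = cells, increased = increased, p = p, q = q,
             reason = reason, row.names = NULL)
}

#' Select the representative reporter strain for a miRNA
#'
#' When several independent integration strains exist for one miRNA, the
#' most representative, informative pattern is kept:
#' type 1 - all strains express: the highest-expressing strain of the
#' predominant pattern; type 2 - mixed, non-expression predominant: the
#' literature decides between an expressing strain and a silent one;
#' type 3 - all silent within the tracing window: the strain with the
#' highest late-window (post-tracing) expression; type 4 - all silent
#' always: a seeded random choice. Ties on representativeness may return
#' several strains.
#'
#' @param strains Data.frame with columns `strain`, `expressed` (logical),
#'   `pattern` (pattern id), `max_level`, `late_window_level`.
#' @param literature_expressed Was embryonic expression reported before?
#' @param seed Seed for the type-4 random choice.
#' @return List `strains` (selected ids) and `type` (1-4).
#' @export
select_representative_strain <- function(strains,
                                         literature_expressed = FALSE,
                                         seed = 1L) {
  stopifnot(nrow(strains) >= 1L)
  bad <- strains$expressed & strains$max_level <= 0
  if (any(bad))
    stop("strain(s) flagged as expressing but with level 0: ",
         paste(strains$strain[bad], collapse = ", "))
  if (all(strains$expressed)) {
    tab <- table(strains$pattern)
    predom <- names(tab)[tab == max(tab)]
    cand <- strains[strains$pattern %in% predom, , drop = FALSE]
    best <- cand[cand$max_level == max(cand$max_level), , drop = FALSE]
    return(list(strains = best$strain, type = 1L))
  }
  if (any(strains$expressed)) {
    expr_n <- sum(strains$expressed)
    if (expr_n >= nrow(strains) - expr_n) {
      cand <- strains[strains$expressed, , drop = FALSE]
      best <- cand[cand$max_level == max(cand$max_level), , drop = FALSE]
      return(list(strains = best$strain, type = 1L))
    }
    pick <- if (literature_expressed) strains[strains$expressed, ]
            else strains[!strains$expressed, ]
    best <- if (literature_expressed)
      pick[pick$max_level == max(pick$max_level), , drop = FALSE]
    else pick[1L, , drop = FALSE]
    return(list(strains = best$strain, type = 2L))
  }
  if (any(strains$late_window_level > 0)) {
    best <- strains[strains$late_window_level ==
                      max(strains$late_window_level), , drop = FALSE]
    return(list(strains = best$strain, type = 3L))
  }
  pick <- .with_seed(seed, sample(strains$strain, 1L))
  list(strains = pick, type = 4L)
}
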