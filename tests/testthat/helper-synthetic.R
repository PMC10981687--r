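# Shared synthetic study setup: a small lineage with planted pan-tissue
# reporter programs plus silent null reporters, run through the full
# quantification chain to an integrated atlas.

make_reporter_atlas <- function(seed, n_act = 6L, n_null = 6L,
                                n_terminals = 64L, n_tissues = 4L,
                                n_ctrl_embryos = 2L) {
  model <- imaging_model()
  tree <- synthetic_lineage(n_terminals, n_tissues)
  terms <- terminal_cells(tree, surviving = TRUE)
  tt <- tissue_table(data.frame(
    cell = terms, tissue = tree$tissue[match(terms, tree$name)]))
  tissues <- tissue_labels()[seq_len(n_tissues)]
  ctrl <- subtract_background(
    simulate_negative_control(tree, model, seed * 1000L + 1L,
                              n_embryos = n_ctrl_embryos))
  calib <- suppressWarnings(calibrate_cutoff(
    correct_depth_attenuation(ctrl$net, ctrl$z, model)))
  n_rep <- n_act + n_null
  reporters <- sprintf("rep%02d", seq_len(n_rep))
  emb <- matrix(0, nrow(tree), n_rep,
                dimnames = list(tree$name, reporters))
  l1 <- matrix(0, length(terms), n_rep,
               dimnames = list(terms, reporters))
  truth <- stats::setNames(rep(NA_character_, n_rep), reporters)
  for (i in seq_len(n_rep)) {
    if (i <= n_act) truth[i] <- tissues[((i - 1L) %% n_tissues) + 1L]
    prog <- if (i <= n_act)
      pan_tissue_program(reporters[i], tree, truth[i],
                         seed = seed * 1000L + 500L + i)
    else reporter_program(reporters[i])
    tr <- simulate_reporter_imaging(tree, prog, model,
                                    seed * 1000L + 10L + i)
    q <- quantify_embryo(tr, model, calib)
    emb[q$cell, i] <- q$value
    lv <- simulate_l1_expression(tree, prog, model,
                                 seed * 1000L + 200L + i)
    lv[lv < calib$cutoff] <- 0
    l1[names(lv), i] <- lv
  }
  atlas <- suppressWarnings(build_atlas(emb, l1, tree))
  list(atlas = atlas, tree = tree, tissue_table = tt, truth = truth,
       calib = calib, model = model, reporters = reporters,
       n_act = n_act)
}

# census-weighted track tissue assignment for targeting/leakiness tests
make_track_tissues <- function(n_tracks = 64L, n_tissues = 4L) {
  tree <- synthetic_lineage(n_tracks, n_tissues)
  terms <- terminal_cells(tree, surviving = TRUE)
  stats::setNames(tree$tissue[match(terms, tree$name)], terms)
}
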