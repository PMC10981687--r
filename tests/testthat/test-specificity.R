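# a small two-tissue cell population reused across cases
.mk_tt <- function(n_neuron = 202, n_other = 356) {
  tissue_table(data.frame(
    cell = c(sprintf("n%03d", seq_len(n_neuron)),
             sprintf("o%03d", seq_len(n_other))),
    tissue = c(rep("neuron", n_neuron),
               rep("body wall muscle", n_other))))
}

test_that("exclusive expression in >= 3 cells of one tissue is a call", {
  tt <- tissue_table(data.frame(
    cell = sprintf("c%02d", 1:40),
    tissue = rep(c("intestine", "neuron"), c(20, 20))))
  expr <- setNames(rep(0, 40), sprintf("c%02d", 1:40))
  expr[c("c01", "c02", "c03", "c04")] <- c(5, 6, 7, 8)
  calls <- call_tissue_specific(expr, tt = tt)
  expect_true("intestine" %in% calls$tissue)
  expect_match(calls$criteria[calls$tissue == "intestine"], "exclusive")
})

test_that("two expressing cells are not enough, matching the exact test", {
  tt <- .mk_tt()
  expr <- setNames(rep(0, 558), tt$cell)
  expr[c("n001", "n002")] <- 10
  calls <- call_tissue_specific(expr, tt = tt)
  expect_equal(nrow(calls), 0)
  # independent hypergeometric check of the Fisher branch: 2 expressing
  # cells among 202 of 558 is unremarkable
  p <- bf_fisher(matrix(c(2, 200, 0, 356), 2))
  expect_equal(p, 0.13, tolerance = 0.02)
  expect_gt(p, 0.01)
})

test_that("a planted quantitative program is called pan-tissue", {
  tt <- tissue_table(data.frame(
    cell = sprintf("c%03d", 1:150),
    tissue = rep(c("pharynx", "neuron", "glia"), each = 50)))
  set.seed(3)
  expr <- setNames(c(rnorm(50, 10, 1), abs(rnorm(100, 1, 1))), tt$cell)
  calls <- call_tissue_specific(expr, tt = tt)
  ph <- calls[calls$tissue == "pharynx", ]
  expect_equal(nrow(ph), 1)
  expect_match(ph$criteria, "quantitative")
  expect_equal(ph$pan_or_sub, "pan")
  # criterion 3 survives any monotone rescaling of expression
  calls2 <- call_tissue_specific(expr^2, tt = tt)
  expect_equal(calls2$tissue, calls$tissue)
})

test_that("late-embryo proxy takes max of terminal and mother, or ancestor", {
  tree <- synthetic_lineage(8, 2)
  terms <- terminal_cells(tree, surviving = TRUE)
  parent <- setNames(tree$parent, tree$name)
  tc <- terms[1]; mo <- parent[[tc]]
  tpm <- setNames(c(5, 3), c(tc, mo))
  expect_equal(unname(late_embryo_expression(tpm, tree)[tc]), 5)
  tpm2 <- setNames(c(0, 4), c(tc, mo))
  expect_equal(unname(late_embryo_expression(tpm2, tree)[tc]), 4)
  # terminal not covered: the latest covered ancestor stands in
  tpm3 <- setNames(2, mo)
  expect_equal(unname(late_embryo_expression(tpm3, tree)[tc]), 2)
  gm <- parent[[mo]]
  tpm4 <- setNames(9, gm)
  expect_equal(unname(late_embryo_expression(tpm4, tree)[tc]), 9)
})

test_that("TSG calling recovers planted focus tissues", {
  tk <- make_track_tissues(64, 4)
  tt <- tissue_table(data.frame(cell = names(tk), tissue = unname(tk)))
  tsg <- setNames(c(rep(tissue_labels()[1], 5), rep(tissue_labels()[2], 5),
                    rep(NA, 5)), sprintf("g%02d", 1:15))
  truth <- transcriptome_truth(tsg, leak_fraction = 0.2)
  txn <- simulate_track_transcriptome(tk, truth, seed = 8)
  calls <- call_tsg(txn, tt)
  for (g in names(tsg)[!is.na(tsg)])
    expect_true(any(calls$gene == g & calls$tissue == tsg[[g]]),
                label = paste("planted TSG", g))
  # housekeeping-profile genes are not called
  expect_false(any(calls$gene %in% names(tsg)[is.na(tsg)]))
})

test_that("expression-breadth categories pin their printed boundaries", {
  expect_equal(categorize_expression(n_exp = 250), "high")
  expect_equal(categorize_expression(n_exp = 201), "high")
  expect_equal(categorize_expression(n_exp = 200), "medium")
  expect_equal(categorize_expression(n_exp = 11), "medium")
  expect_equal(categorize_expression(n_exp = 10), "low")
  expect_equal(categorize_expression(f_exp = 0.71), "high")
  expect_equal(categorize_expression(f_exp = 0.7), "medium")
  expect_equal(categorize_expression(f_exp = 0.3), "low")
  expect_error(categorize_expression(), "supply")
})

test_that("category comparison reports medians and rank-test p-values", {
  cats <- setNames(rep(c("high", "medium", "low"), each = 6),
                   sprintf("m%02d", 1:18))
  cpm_same <- setNames(rep(c(5, 7, 9, 11, 13, 15), 3), names(cats))
  same <- compare_seq_categories(cats, cpm_same)
  expect_true(all(same$pairwise$p == 1))
  set.seed(2)
  cpm_ord <- setNames(c(rnorm(6, 100, 5), rnorm(6, 30, 5),
                        rnorm(6, 5, 2)), names(cats))
  ord <- compare_seq_categories(cats, cpm_ord)
  expect_true(ord$medians["high"] > ord$medians["medium"])
  expect_true(ord$medians["medium"] > ord$medians["low"])
  expect_true(all(ord$pairwise$p < 0.05))
  cats2 <- cats; cats2[cats2 == "low"] <- "medium"
  expect_warning(compare_seq_categories(cats2, cpm_same), "empty")
})

test_that("intra-family similarity is ranked against inter-family pairs", {
  set.seed(5)
  base <- matrix(runif(8 * 30, 0, 100), 8,
                 dimnames = list(sprintf("m%d", 1:8), NULL))
  base["m2", ] <- base["m1", ]  # duplicated pattern inside the family
  fam <- setNames(c("famA", "famA", "famB", "famB", letters[1:4]),
                  rownames(base))
  res <- intra_family_divergence(base, fam)
  pr <- res$pairs
  expect_true(pr$high_similarity[pr$family == "famA"])
  # famB members are unrelated: not expected to reach the top 20%
  expect_false(pr$high_similarity[pr$family == "famB"])
  # families of one contribute no pairs
  expect_equal(nrow(pr), 2)
})

test_that("literature consistency combines entry categories", {
  ours <- list(pan_tissues = "pharynx", sub_tissues = "neuron",
               tissues_with_expression = c("pharynx", "neuron"),
               expressed_cells = c("ABala", "ABalp"),
               ubiquitous = FALSE)
  lit1 <- data.frame(study = "s1", type = "tissue", tissue = "pharynx",
                     cells = NA)
  expect_equal(categorize_literature_consistency(ours, lit1),
               "consistent")
  lit2 <- data.frame(study = "s1", type = "tissue", tissue = "neuron",
                     cells = NA)
  expect_equal(categorize_literature_consistency(ours, lit2),
               "partially consistent")
  lit3 <- data.frame(study = "s1", type = "cell", tissue = NA,
                     cells = "PVQL, PVQR")
  expect_equal(categorize_literature_consistency(ours, lit3),
               "not consistent")
  lit4 <- data.frame(study = "s1", type = "cell", tissue = NA,
                     cells = "ABala, PVQL")
  expect_equal(categorize_literature_consistency(ours, lit4),
               "partially consistent")
  # the best study wins
  lit5 <- rbind(cbind(lit3, stringsAsFactors = FALSE),
                data.frame(study = "s2", type = "tissue",
                           tissue = "pharynx", cells = NA))
  expect_equal(categorize_literature_consistency(ours, lit5),
               "consistent")
  litu <- data.frame(study = "s1", type = "ubiquitous", tissue = NA,
                     cells = NA)
  expect_equal(categorize_literature_consistency(ours, litu),
               "not consistent")
})
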