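let7 <- "UGAGGUAGUAGGUUGU"

test_that("seed-site scanning classifies canonical let-7-like sites", {
  hits <- scan_seed_sites("AACTACCTCAGG", let7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_type, "8mer")
  expect_equal(hits$start, 2L)  # 0-based
  expect_equal(substr("AACTACCTCAGG", hits$start + 1, hits$end),
               "CTACCTCA")
  m8 <- scan_seed_sites("CTACCTCG", let7)
  expect_equal(m8$site_type, "7mer-m8")
  a1 <- scan_seed_sites("GTACCTCA", let7)
  expect_equal(a1$site_type, "7mer-A1")
  expect_equal(nrow(scan_seed_sites("ACGTAC", let7)), 0)
  expect_error(scan_seed_sites("ACGTNNN", let7), "non-ACGTU")
})

test_that("every 8mer locus string-satisfies both 7mer conditions", {
  pats <- seed_site_patterns(let7)
  expect_equal(substr(pats[["8mer"]], 1, 7), pats[["7mer-m8"]])
  expect_equal(substr(pats[["8mer"]], 2, 8), pats[["7mer-A1"]])
  # and the scanner reports the most specific type only
  u <- paste0("GG", pats[["8mer"]], "GG")
  hits <- scan_seed_sites(u, let7)
  expect_equal(hits$site_type, "8mer")
})

test_that("scanning matches the brute-force per-position oracle", {
  set.seed(13)
  for (i in 1:25) {
    u <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    mi <- paste(sample(c("A", "C", "G", "U"), 10, replace = TRUE),
                collapse = "")
    got <- scan_seed_sites(u, mi)
    want <- bf_scan_sites(u, mi)
    got <- got[order(got$start, got$site_type), ]
    expect_equal(got$site_type, want$site_type)
    expect_equal(got$start, want$start)
  }
})

test_that("the gene universe keeps the longest UTR at >= 50 nt", {
  u <- c(gA = strrep("ACGT", 10), gA = strrep("ACGT", 30),
         gB = strrep("AC", 24), gC = strrep("ACGT", 15))
  uni <- build_gene_universe(u)
  expect_setequal(names(uni), c("gA", "gC"))
  expect_equal(nchar(uni[["gA"]]), 120)
  expect_length(build_gene_universe(setNames(character(), character())), 0)
  # FASTA round trip through the standard reader
  path <- withr::local_tempfile(fileext = ".fa")
  write_utr_fasta(c(gX = strrep("ACGT", 20)), path)
  expect_equal(names(build_gene_universe(path)), "gX")
})

test_that("O/E follows the hand-enumerated example and normalizes to 1", {
  genes <- sprintf("g%02d", 1:10)
  tsg <- setNames(c(rep("neuron", 4), rep(NA, 6)), genes)
  txn <- matrix(10, 10, 3, dimnames = list(genes, c("t1", "t2", "t3")))
  targets <- data.frame(gene = genes[1:5], mirna = "m1")
  oe <- compute_oe(targets, tsg, txn, genes)
  row <- oe[oe$track == "t1" & oe$tsg_type == "neuron", ]
  expect_equal(row$observed, 0.8)
  expect_equal(row$expected, 0.4)
  expect_equal(row$oe, 2.0)
  expect_equal(median(oe$oe_norm[oe$tsg_type == "neuron"]), 1)
})

test_that("uniform random targets give O/E near 1 and no calls", {
  tk <- make_track_tissues(64, 4)
  genes <- sprintf("g%03d", 1:120)
  tsg <- setNames(rep(c(tissue_labels()[1:4], NA, NA), each = 20), genes)
  truth <- transcriptome_truth(tsg, leak_fraction = 0.4)
  txn <- simulate_track_transcriptome(tk, truth, seed = 30)
  set.seed(31)
  targets <- data.frame(gene = sample(genes, 40), mirna = "m1")
  oe <- compute_oe(targets, tsg, txn, genes)
  expect_equal(mean(oe$oe, na.rm = TRUE), 1, tolerance = 0.25)
  calls <- call_preferential_targeting(
    oe, tk, c(m1 = tissue_labels()[1]))
  expect_true(all(!calls$called))
})

test_that("the call gates are median > 1, fold > 1.25 and p < 0.01", {
  tk <- setNames(rep(c("neuron", "glia"), c(30, 300)),
                 sprintf("t%03d", 1:330))
  mk_oe <- function(grp, oth) data.frame(
    mirna = "m1", track = names(tk), tsg_type = "neuron",
    observed = NA, expected = NA, oe = NA,
    oe_norm = c(grp, oth), undefined = FALSE)
  set.seed(40)
  strong <- mk_oe(rnorm(30, 1.8, 0.2), rnorm(300, 1.0, 0.2))
  c1 <- call_preferential_targeting(strong, tk, c(m1 = "neuron"))
  expect_true(c1$called)
  flat <- mk_oe(rnorm(30, 1.0, 0.2), rnorm(300, 1.0, 0.2))
  expect_false(call_preferential_targeting(flat, tk,
                                           c(m1 = "neuron"))$called)
  # significant shift but fold below the gate: not called
  weak <- mk_oe(rnorm(30, 1.5, 0.05), rnorm(300, 1.38, 0.05))
  cw <- call_preferential_targeting(weak, tk, c(m1 = "neuron"))
  expect_false(cw$called)
  expect_lt(cw$fold, 1.25)
  expect_gt(cw$median_group, 1)
  # groups below the minimum size are flagged untested
  tiny <- strong[c(1:2, 31:60), ]
  expect_false(call_preferential_targeting(tiny, tk,
                                           c(m1 = "neuron"))$tested)
})

test_that("same-tissue rate compares to the marginal expectation", {
  calls <- data.frame(
    mirna = rep(sprintf("m%d", 1:8), each = 2),
    tsg_type = rep(c("neuron", "glia"), 8),
    mirna_tissue = rep(c("neuron", "glia"), each = 8),
    tested = TRUE,
    called = FALSE)
  # planted avoidance: cross-tissue pairs called often, same-tissue never
  same <- calls$tsg_type == calls$mirna_tissue
  calls$called[!same] <- TRUE
  r <- same_tissue_targeting_rate(calls)
  expect_equal(r$observed_freq, 0)
  expect_gt(r$expected_freq, 0)
  expect_lt(r$fisher_p, 0.01)
  none <- calls; none$called <- FALSE
  expect_true(is.na(same_tissue_targeting_rate(none)$fisher_p))
})

test_that("leakiness profiles report frequency and relative level", {
  tk <- setNames(rep(c("neuron", "glia", "pharynx"), each = 4),
                 sprintf("t%02d", 1:12))
  txn <- matrix(0, 2, 12, dimnames = list(c("gF", "gL"), names(tk)))
  txn["gF", tk == "neuron"] <- 10         # focus only
  txn["gL", tk == "neuron"] <- 10
  txn["gL", c("t05", "t09")] <- 2          # leaks into one track each
  res <- quantify_leakiness(setNames(c("neuron", "neuron"),
                                     c("gF", "gL")), txn, tk)
  pf <- res$profiles
  expect_equal(pf$freq_other[pf$gene == "gF"], 0)
  expect_equal(pf$freq_other[pf$gene == "gL"], 2 / 8)
  expect_equal(pf$rel_level[pf$gene == "gL"], mean(txn["gL", tk != "neuron"]) / 10)
  # focus mean 10, other mean 2 everywhere: relative level 0.2
  txn2 <- rbind(gX = ifelse(tk == "neuron", 10, 2))
  r2 <- quantify_leakiness(c(gX = "neuron"), txn2, tk)
  expect_equal(r2$profiles$rel_level, 0.2)
})

test_that("site density counts each miRNA once per UTR, per kilobase", {
  lens <- c(gA = 1000L, gB = 1000L, gC = 500L)
  targets <- data.frame(
    gene = c("gA", "gA", "gB", "gB", "gB"),
    mirna = c("m1", "m2", "m1", "m1", "m1"))
  d <- site_density(targets, lens)
  expect_equal(unname(d["gA"]), 2)
  expect_equal(unname(d["gB"]), 1)   # three sites of one miRNA count once
  expect_equal(unname(d["gC"]), 0)
})

test_that("leakiness-density coupling is detected and nulls are flat", {
  set.seed(50)
  n <- 60
  leak <- runif(n, 0.05, 0.6)
  dens <- 5 * leak + rnorm(n, 0, 0.3)
  names(leak) <- names(dens) <- sprintf("g%02d", 1:n)
  res <- correlate_leakiness_density(leak, dens)
  expect_gt(res$rho, 0)
  expect_lt(res$p, 0.01)
  expect_lt(res$strata_p, 0.01)
  sh <- correlate_leakiness_density(
    leak, setNames(sample(unname(dens)), names(dens)))
  expect_lt(abs(sh$rho), 0.3)
  expect_error(correlate_leakiness_density(leak[1:4], dens[1:4]),
               "at least 5")
})

test_that("target-level comparison flags planted repression", {
  tk <- sprintf("t%03d", 1:100)
  genes <- sprintf("g%02d", 1:20)
  set.seed(60)
  txn <- matrix(rlnorm(2000, log(50), 0.3), 20,
                dimnames = list(genes, tk))
  expressing <- tk[1:50]
  expect_gt(compare_target_levels(genes, txn, expressing)$p, 0.001)
  txn2 <- txn
  txn2[, expressing] <- txn2[, expressing] * 0.7  # 30% repression
  res <- compare_target_levels(genes, txn2, expressing)
  expect_lt(res$p, 0.01)
  expect_lt(res$median_expressing, res$median_other)
  expect_null(compare_target_levels(character(), txn, expressing))
})
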