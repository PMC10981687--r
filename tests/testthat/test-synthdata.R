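tree8 <- synthetic_lineage(8, 2)

test_that("generators demand a seed and are deterministic given one", {
  model <- imaging_model()
  expect_error(simulate_negative_control(tree8, model), "seed")
  expect_error(simulate_reporter_imaging(tree8, reporter_program("r"),
                                         model), "seed")
  a <- simulate_negative_control(tree8, model, seed = 7)
  b <- simulate_negative_control(tree8, model, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_negative_control(tree8, model, seed = 8)))
})

test_that("an empty program yields background-subtracted values near 0", {
  model <- imaging_model()
  tr <- simulate_negative_control(synthetic_lineage(128, 4), model,
                                  seed = 3, n_embryos = 4)
  net <- tr$nucleus_mean - tr$annulus_mean
  n <- length(net)
  expect_gt(n, 1e4)
  se <- sqrt(2) * model$measurement_sd / sqrt(n)
  expect_lt(abs(mean(net)), 3 * se)
  # Var(nuc - ann) = 2 * measurement_sd^2 (shared background cancels)
  expect_equal(stats::var(net), 2 * model$measurement_sd^2,
               tolerance = 0.05)
  # definitional equality with the empty-program simulation
  expect_identical(tr, simulate_reporter_imaging(
    synthetic_lineage(128, 4), reporter_program("empty"), model,
    seed = 3, n_embryos = 4))
})

test_that("noise-free cumulative signal follows the closed form", {
  model <- imaging_model(background_sd = 0, measurement_sd = 0,
                         attenuation_length = Inf, laser_ramp = 1)
  cell <- terminal_cells(tree8)[1]
  prog <- reporter_program("r", active_cells = cell, rate = 2)
  tr <- simulate_reporter_imaging(tree8, prog, model, seed = 1)
  net <- tr$nucleus_mean - tr$annulus_mean
  sub <- tr$cell == cell
  birth <- tree8$birth[tree8$name == cell]
  expect_equal(net[sub], 2 * (tr$frame[sub] - birth))
  expect_true(all(abs(net[!sub]) < 1e-9))
})

test_that("daughters inherit the mother's accumulated signal", {
  model <- imaging_model(background_sd = 0, measurement_sd = 0,
                         attenuation_length = Inf, laser_ramp = 1)
  # activate an internal cell; its daughters inherit the end concentration
  tree16 <- synthetic_lineage(16, 2)
  internal <- setdiff(tree16$name[!tree16$terminal],
                      c("P0", "AB", "P1", four_cell_origins(tree16)))[1]
  prog <- reporter_program("r", active_cells = internal, rate = 3)
  tr <- simulate_reporter_imaging(tree16, prog, model, seed = 1)
  net <- tr$nucleus_mean - tr$annulus_mean
  span <- tree16$end[tree16$name == internal] -
    tree16$birth[tree16$name == internal]
  kids <- tree16$name[!is.na(tree16$parent) & tree16$parent == internal]
  for (k in kids)
    expect_true(all(abs(net[tr$cell == k] - 3 * span) < 1e-9))
})

test_that("track transcriptomes honor leak fraction and determinism", {
  tk <- make_track_tissues(64, 4)
  genes <- setNames(rep(tissue_labels()[1], 10), sprintf("g%d", 1:10))
  truth0 <- transcriptome_truth(genes, leak_fraction = 0)
  m0 <- simulate_track_transcriptome(tk, truth0, seed = 5)
  nonfocus <- names(tk)[tk != tissue_labels()[1]]
  expect_true(all(m0[, nonfocus] == 0))
  expect_true(all(m0[, setdiff(names(tk), nonfocus)] > 0))

  truth3 <- transcriptome_truth(genes, leak_fraction = 0.3)
  m3 <- simulate_track_transcriptome(tk, truth3, seed = 5)
  k <- sum(m3[, nonfocus] > 0)
  n <- length(genes) * length(nonfocus)
  ci <- qbinom(c(0.005, 0.995), n, 0.3)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
  expect_identical(m3, simulate_track_transcriptome(tk, truth3, seed = 5))
  expect_error(transcriptome_truth(genes, focus_level = 5,
                                   leak_level = 10))
})

test_that("UTR generator plants recoverable sites and is self-consistent", {
  genes <- sprintf("g%02d", 1:20)
  seeds <- c(m1 = "UGAGGUAGUA", m2 = "ACCCGUAAAU")
  out <- generate_utrs_and_targets(genes, seeds, density = 1.5, seed = 11)
  expect_identical(out$targets, scan_all_targets(out$utrs, seeds))
  # density 0: background 7mer hit rate near the 4^-7 chance expectation
  bg <- generate_utrs_and_targets(sprintf("h%03d", 1:300), seeds["m1"],
                                  density = 0,
                                  utr_length = c(500L, 500L), seed = 12)
  n_pos <- 300 * (500 - 6)
  # two 7mer patterns plus the 8mer refinement: ~2 matches per 4^7 positions
  expected <- 2 * n_pos / 4^7
  expect_lt(nrow(bg$targets), expected * 3 + 10)
  expect_gt(nrow(bg$targets), 0)  # chance hits do occur at this size
})

test_that("planting one 8mer per gene guarantees recovery", {
  genes <- sprintf("g%02d", 1:15)
  seeds <- c(m1 = "UGAGGUAGUA")
  out <- generate_utrs_and_targets(genes, seeds, density = 0,
                                   utr_length = c(100L, 200L), seed = 2)
  utrs <- out$utrs
  pat <- seed_site_patterns("UGAGGUAGUA")[["8mer"]]
  for (g in genes) substr(utrs[[g]], 10, 10 + nchar(pat) - 1) <- pat
  hits <- scan_all_targets(utrs, seeds)
  expect_true(all(genes %in% hits$gene[hits$site_type == "8mer"]))
})

test_that("simulated TF peaks land inside or outside promoter windows", {
  tss <- data.frame(gene = c("gA", "gB"), chrom = "chrI",
                    tss = c(10000L, 50000L), strand = c("+", "-"))
  binding <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                    dimnames = list(c("tf1", "tf2"), c("gA", "gB")))
  pk <- simulate_tf_peaks(tss, binding, seed = 4)
  win <- promoter_windows(tss)
  in_window <- function(tf, g) {
    w <- win[win$gene == g, ]
    rows <- pk[pk$tf == tf, , drop = FALSE]
    mids <- (rows$start + rows$end) %/% 2
    any(mids >= w$start & mids < w$end)
  }
  for (tf in rownames(binding)) for (g in colnames(binding))
    expect_equal(in_window(tf, g), unname(binding[tf, g]),
                 label = paste(tf, g))
  expect_identical(pk, simulate_tf_peaks(tss, binding, seed = 4))
})
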