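test_that("background subtraction is nucleus minus annulus, NA frames drop", {
  tr <- data.frame(cell = "c", frame = 1:3, nucleus_mean = c(10, 4, 7),
                   annulus_mean = c(4, 4, NA), z = 0L)
  expect_warning(out <- subtract_background(tr), "dropped")
  expect_equal(out$net, c(6, 0))
  expect_error(subtract_background(tr[0, ]), "empty")
})

test_that("depth correction inverts the attenuation model", {
  flat <- imaging_model(attenuation_length = Inf, laser_ramp = 1)
  expect_equal(correct_depth_attenuation(c(1, 2, 3), c(0, 5, 29), flat),
               c(1, 2, 3))
  m <- imaging_model(attenuation_length = 10, laser_ramp = 1.03)
  # same true signal observed at two depths corrects to the same value
  sig <- 7
  net <- sig * attenuation(m, c(0, 10))
  expect_equal(correct_depth_attenuation(net, c(0, 10), m), c(sig, sig))
  # attenuation 0.5 at some z: net 3 corrects to 6
  m2 <- imaging_model(attenuation_length = 1 / log(2), laser_ramp = 1)
  expect_equal(attenuation(m2, 1), 0.5)
  expect_equal(correct_depth_attenuation(3, 1, m2), 6)
  expect_error(attenuation(m, 30), "z-plane")
})

test_that("cutoff calibration hits the target quantile", {
  expect_error(calibrate_cutoff(numeric()), "no control values")
  expect_warning(cal0 <- calibrate_cutoff(c(-2, -1, 0), 1e-4))
  expect_equal(cal0$cutoff, 0)
  set.seed(42)
  x <- rnorm(1e6)
  cal <- calibrate_cutoff(x, target_fdr = 1e-4)
  # sort-and-index oracle for the inverse-ECDF quantile
  expect_equal(cal$cutoff, sort(x)[ceiling((1 - 1e-4) * 1e6)])
  expect_equal(cal$cutoff, qnorm(0.9999), tolerance = 0.05)
  expect_lte(cal$empirical_fdr, 1e-4)
  # the conventional fixed cutoff can be imposed
  expect_equal(calibrate_cutoff(x, override = 3.2)$cutoff, 3.2)
})

test_that("cell summaries average frames and zero below the cutoff", {
  cal <- suppressWarnings(calibrate_cutoff(rep(0, 10), override = 3.2))
  expect_equal(summarize_cell_expression(c(4, 6, 8), cal)$value, 6)
  expect_equal(summarize_cell_expression(c(1, 1, 1), cal)$value, 0)
  expect_equal(summarize_cell_expression(5, cal),
               list(value = 5, n_frames = 1L))
  expect_error(summarize_cell_expression(numeric(), cal), "no corrected")
})

test_that("increased-expression inference follows the window rules", {
  vals <- list(
    flat15 = rep(2, 15),
    rise24 = seq_len(24) + 0,
    short11 = seq_len(11) + 0)
  out <- infer_increased_expression(vals)
  expect_false(out$increased[out$cell == "flat15"])
  expect_equal(out$p[out$cell == "flat15"], 1)
  expect_true(out$increased[out$cell == "rise24"])
  # early window = first 10 of 24; strictly increasing trace gives the
  # extreme rank split: exact two-sided p is 2 / choose(24, 10)
  expect_equal(out$p[out$cell == "rise24"], 2 / choose(24, 10))
  expect_equal(out$reason[out$cell == "short11"], "insufficient_frames")
  expect_false(out$increased[out$cell == "short11"])
  # onset rule overrides the frame requirement
  out2 <- infer_increased_expression(vals, onset_cells = "short11")
  expect_true(out2$increased[out2$cell == "short11"])
  expect_equal(out2$reason[out2$cell == "short11"], "onset_rule")
})

test_that("q-values are BH-consistent: q >= p and monotone in p", {
  set.seed(9)
  vals <- lapply(1:30, function(i) rnorm(15))
  names(vals) <- paste0("c", 1:30)
  out <- infer_increased_expression(vals)
  ok <- !is.na(out$q)
  expect_true(all(out$q[ok] >= out$p[ok] - 1e-12))
  o <- order(out$p[ok])
  expect_true(all(diff(out$q[ok][o]) >= -1e-12))
  expect_equal(out$q[ok], bf_bh(out$p[ok]))
})

test_that("representative-strain selection implements the four types", {
  s3 <- data.frame(strain = c("a", "b", "c"), expressed = TRUE,
                   pattern = c("A", "A", "B"), max_level = c(5, 9, 20),
                   late_window_level = 0)
  r <- select_representative_strain(s3)
  expect_equal(r$type, 1L)
  expect_equal(r$strains, "b")  # highest level within predominant pattern

  s4 <- data.frame(strain = c("a", "b"), expressed = FALSE,
                   pattern = NA, max_level = 0, late_window_level = 0)
  r4a <- select_representative_strain(s4, seed = 3)
  expect_equal(r4a$type, 4L)
  expect_identical(r4a, select_representative_strain(s4, seed = 3))
  expect_true(r4a$strains %in% s4$strain)

  s2 <- data.frame(strain = c("a", "b", "c"),
                   expressed = c(TRUE, FALSE, FALSE),
                   pattern = c("A", NA, NA), max_level = c(4, 0, 0),
                   late_window_level = 0)
  r2 <- select_representative_strain(s2, literature_expressed = TRUE)
  expect_equal(r2$type, 2L)
  expect_equal(r2$strains, "a")

  s3b <- data.frame(strain = c("a", "b"), expressed = FALSE,
                    pattern = NA, max_level = 0,
                    late_window_level = c(0, 7))
  r3 <- select_representative_strain(s3b)
  expect_equal(r3$type, 3L)
  expect_equal(r3$strains, "b")

  bad <- data.frame(strain = "a", expressed = TRUE, pattern = "A",
                    max_level = 0, late_window_level = 0)
  expect_error(select_representative_strain(bad), "level 0")
})

test_that("noise-free end-to-end expression equals rate x mean elapsed", {
  model <- imaging_model(background_sd = 0, measurement_sd = 0,
                         attenuation_length = Inf, laser_ramp = 1)
  tree <- synthetic_lineage(8, 2)
  cell <- terminal_cells(tree)[2]
  prog <- reporter_program("r", active_cells = cell, rate = 4)
  tr <- simulate_reporter_imaging(tree, prog, model, seed = 1)
  q <- quantify_embryo(tr, model,
                       suppressWarnings(calibrate_cutoff(0, override = 0.5)))
  nfr <- sum(tr$cell == cell)
  expect_equal(q$value[q$cell == cell], 4 * mean(seq_len(nfr) - 1))
})
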