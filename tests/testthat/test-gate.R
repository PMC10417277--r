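fake_cells <- function(corr_g, corr_r, well = "A1") {
  tibble::tibble(well = well, corr_g = corr_g, corr_r = corr_r)
}

test_that("gates are mean + k sigma of negative-control intensities", {
  neg <- fake_cells(corr_g = rep(c(8, 12), 30), corr_r = rep(10, 60))
  g <- derive_gates(neg, k_sigma = 3)
  expect_equal(g$gate_g, mean(neg$corr_g) + 3 * sd(neg$corr_g))
  expect_equal(g$gate_r, 10)            # sd 0 -> gate = mean
  expect_equal(g$n_control, 60L)

  expect_error(derive_gates(neg[0, ]), "negative_control")
  expect_error(derive_gates(neg[1:10, ]), "unstable")
  td <- tidy(g)
  expect_equal(td$gate, c(g$gate_g, g$gate_r))
})

test_that("a cell is transfected when either reporter clears its gate", {
  g <- derive_gates(fake_cells(rep(10, 60), rep(10, 60)), k_sigma = 3)
  expect_equal(g$gate_g, 10)
  cells <- fake_cells(corr_g = c(50, 2, 50, 2), corr_r = c(2, 50, 50, 2))
  expect_equal(is_transfected(cells, g), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("the regularised ratio is finite, positive and symmetric", {
  expect_equal(g_over_r(30, 10, epsilon = 1e-9), 3, tolerance = 1e-6)
  expect_equal(g_over_r(25, 25), 1)
  expect_equal(g_over_r(40, 0, epsilon = 1), 41)
  expect_true(is.finite(g_over_r(0, 0)))
  expect_error(g_over_r(-1, 5), "non-negative")
})

test_that("ratio classification uses K/J with boundaries in the dual bucket", {
  p <- classifier_params(K = 2, J = 5)
  cls <- classify_ratio(c(6, 1, 3, 2, 5, 1.99, 5.01), p)
  expect_equal(as.character(cls),
               c("E10minus_GFP", "E10plus_RFP", "dual", "dual", "dual",
                 "E10plus_RFP", "E10minus_GFP"))
  expect_error(classifier_params(K = 5, J = 2), "smaller")
})

test_that("class assignments are scale invariant in both channels", {
  g <- derive_gates(fake_cells(rep(1, 60), rep(1, 60)), k_sigma = 0)
  p <- classifier_params(epsilon = 1e-6)
  cells <- fake_cells(corr_g = runif(200, 0, 400), corr_r = runif(200, 0, 400))
  c1 <- classify_cells(cells, g, p)
  c2 <- classify_cells(dplyr::mutate(cells, corr_g = corr_g * 7,
                                     corr_r = corr_r * 7), g, p)
  expect_identical(c1$splice_class, c2$splice_class)
})

test_that("well summaries report the declared denominators and partition", {
  g <- derive_gates(fake_cells(rep(5, 60), rep(5, 60)), k_sigma = 0)
  cells <- fake_cells(corr_g = c(rep(100, 30), rep(0, 90)),
                      corr_r = c(rep(10, 30), rep(0, 90)))
  cells <- classify_cells(cells, g, classifier_params())
  ws <- summarize_wells(cells)
  expect_equal(ws$total_cells, 120L)
  expect_equal(ws$pct_transfected, 25)          # 30 of 120
  expect_equal(ws$pct_gfp, 100)                 # ratio 101/11 > 5
  expect_equal(ws$pct_rfp + ws$pct_dual + ws$pct_gfp, 100, tolerance = 0.01)

  # zero transfected cells: flagged NA, not silent zeros
  none <- classify_cells(fake_cells(rep(0, 10), rep(0, 10), well = "Z9"),
                         derive_gates(fake_cells(rep(5, 60), rep(5, 60)),
                                      k_sigma = 3),
                         classifier_params())
  wz <- summarize_wells(none)
  expect_false(wz$ok)
  expect_true(is.na(wz$pct_rfp) && is.na(wz$median_g_over_r))
})

test_that("a clean all-inclusion well is recovered as 100% RFP", {
  op <- quiet_optics()
  lay <- plate_layout(
    wells = tibble::tibble(well = c("A1", "A2"),
                           condition = c("inc", "untransfected")),
    conditions = list(
      inc = condition_spec("inc", cells_per_field = 20,
                           inclusion_mean = 1, transfection_rate = 1),
      untransfected = condition_spec("untransfected", cells_per_field = 20,
                                     transfection_rate = 0,
                                     role = "negative_control")),
    min_fields = 2)
  res <- run_pipeline(generate_plate(lay, op, seed = 5),
                      min_control_cells = 30)
  w <- res$wells[res$wells$well == "A1", ]
  expect_equal(w$pct_rfp, 100)
  expect_equal(w$pct_transfected, 100)
})

test_that("truth-derived class fractions follow the same K/J rule", {
  truth <- tibble::tibble(transfected = rep(TRUE, 4),
                          psi = c(0.05, 0.5, 0.9, 0.1),
                          expression = 1)
  fr <- truth_class_fractions(truth, classifier_params())
  # ratios: 19, 1, 0.111, 9 -> gfp, rfp, rfp, gfp
  expect_equal(fr$pct_gfp, 50)
  expect_equal(fr$pct_rfp, 50)
  expect_equal(fr$pct_dual, 0)
})
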