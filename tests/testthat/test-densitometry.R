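test_that("ladder calibration is exact on a log-linear ladder", {
  lad <- demo_ladder()
  cal <- calibrate_ladder(lad$positions, lad$sizes)
  expect_equal(predict_size(cal, lad$positions), lad$sizes, tolerance = 1e-6)
  expect_equal(predict_position(cal, 650),
               400 - 120 * log10(650), tolerance = 1e-6)
  expect_lt(cal$slope, 0)  # larger fragments migrate less in this layout

  expect_error(calibrate_ladder(c(10, 5, 30), c(100, 200, 300)), "monotone")
  expect_error(calibrate_ladder(c(10, 20), c(100, 200)), "3 rungs")
})

test_that("held-out rung size is predicted within 5% on a noisy ladder", {
  lad <- demo_ladder(noise = 2)
  for (hold in seq_along(lad$sizes)) {
    cal <- calibrate_ladder(lad$positions[-hold], lad$sizes[-hold])
    pred <- predict_size(cal, lad$positions[hold])
    expect_lt(abs(pred - lad$sizes[hold]) / lad$sizes[hold], 0.05)
  }
})

test_that("band detection recovers analytic Gaussian areas", {
  pos <- seq(0, 400, by = 1)
  flat <- tibble::tibble(position = pos, intensity = rep(7, length(pos)))
  expect_equal(nrow(detect_bands(flat, baseline_window = 41)), 0L)
  expect_error(detect_bands(flat, baseline_window = 1000), "window")

  sigma <- 4; a1 <- 1500; a2 <- 600
  y <- 10 + a1 / (sigma * sqrt(2 * pi)) * exp(-(pos - 120)^2 / (2 * sigma^2)) +
    a2 / (sigma * sqrt(2 * pi)) * exp(-(pos - 260)^2 / (2 * sigma^2))
  bands <- detect_bands(tibble::tibble(position = pos, intensity = y),
                        baseline_window = 51)
  expect_equal(nrow(bands), 2L)
  expect_equal(bands$center, c(120, 260), tolerance = 1)
  expect_equal(bands$area, c(a1, a2), tolerance = 0.05)
})

test_that("bands are assigned to the nearest expected amplicon within tolerance", {
  lad <- demo_ladder()
  cal <- calibrate_ladder(lad$positions, lad$sizes)
  bands <- tibble::tibble(
    center = predict_position(cal, c(298, 209, 655)),
    height = 1, prominence = 1, area = c(5, 3, 8),
    left = 0, right = 0)
  asg <- assign_bands(bands, cal)
  expect_equal(asg$assignment, c("e10plus", "e10minus", "actin"))

  # a 500 bp band matches nothing but actin must still be present
  extra <- bands
  extra$center[1] <- predict_position(cal, 500)
  asg2 <- assign_bands(extra, cal)
  expect_equal(asg2$assignment[1], "unassigned")

  expect_error(assign_bands(bands[1:2, ], cal), "housekeeping")
  dup <- bands
  dup$center[2] <- predict_position(cal, 302)
  expect_error(assign_bands(dup, cal), "compete")
})

test_that("endogenous primer-set sizes are selectable", {
  exp_r <- expected_sizes("reporter")
  exp_e <- expected_sizes("endogenous")
  expect_equal(unname(exp_r[c("e10plus", "e10minus")]), c(300, 207))
  expect_equal(unname(exp_e[c("e10plus", "e10minus")]), c(368, 275))
  expect_equal(unname(exp_e["actin"]), 650)
})

test_that("isoform percentages and fold change follow the lane arithmetic", {
  mk <- function(ap, am, actin = 10) {
    tibble::tibble(center = 1:3, height = 1, prominence = 1,
                   area = c(ap, am, actin), left = 0, right = 0,
                   size = c(300, 207, 650),
                   assignment = c("e10plus", "e10minus", "actin"))
  }
  expect_equal(isoform_percent(mk(4, 4))$pct_e10plus, 50)
  expect_equal(isoform_percent(mk(0, 4))$pct_e10plus, 0)
  expect_equal(isoform_percent(mk(8.5, 1.5))$pct_e10plus, 85)
  expect_error(isoform_percent(mk(1, 1, actin = 0)), "zero")
  expect_error(isoform_percent(mk(1, 1)[-1, ]), "missing")

  q <- isoform_percent(mk(6, 2, actin = 12))
  expect_equal(fold_change(q, q), 1)
  # doubling every band in a lane leaves the normalised levels unchanged
  q2 <- isoform_percent(mk(12, 4, actin = 24))
  expect_equal(fold_change(q2, q), 1)
  qa <- isoform_percent(mk(8.5, 1.5, actin = 10))
  qb <- isoform_percent(mk(3.5, 6.5, actin = 10))
  expect_equal(fold_change(qa, qb), 0.85 / 0.35, tolerance = 1e-9)
  expect_equal(fold_change(qa, qb) * fold_change(qb, qa), 1)
  expect_error(fold_change(q, isoform_percent(mk(0, 4))), "zero")
})

test_that("lane synthesis is deterministic and within the calibrated range", {
  lad <- demo_ladder()
  cal <- calibrate_ladder(lad$positions, lad$sizes)
  spec <- tibble::tibble(size = c(300, 207, 650), area = c(900, 450, 1200))
  p1 <- synth_gel(spec, cal, noise_sd = 1, seed = 8)
  p2 <- synth_gel(spec, cal, noise_sd = 1, seed = 8)
  expect_identical(p1, p2)
  expect_true(all(p1$intensity >= 0))

  base <- synth_gel(spec[0, ], cal, noise_sd = 0, seed = 1)
  expect_lt(max(base$intensity) - min(base$intensity), 6)

  expect_error(synth_gel(tibble::tibble(size = 5000, area = 1), cal,
                         seed = 1), "calibration range")
})

test_that("synthesise-then-quantify round-trips areas and percentages", {
  lad <- demo_ladder()
  cal <- calibrate_ladder(lad$positions, lad$sizes)
  spec <- tibble::tibble(size = c(300, 207, 650), area = c(3400, 600, 4000))
  prof <- synth_gel(spec, cal, noise_sd = 1, seed = 4)
  bands <- assign_bands(detect_bands(prof, baseline_window = 41), cal)
  got <- bands$area[match(c("e10plus", "e10minus", "actin"),
                          bands$assignment)]
  expect_equal(got, spec$area, tolerance = 0.05)

  q <- quantify_lane(prof, cal, baseline_window = 41, lane = "mut")
  expect_equal(q$pct_e10plus, 85, tolerance = 2)      # percentage points
  expect_identical(q$lane, "mut")
})
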