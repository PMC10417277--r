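test_that("zprime reproduces the closed-form cases and bands", {
  noiseless <- zprime(control_stats(mu = 100, sigma = 0, role = "negative"),
                      control_stats(mu = 1000, sigma = 0, role = "positive"))
  expect_identical(noiseless$zprime, 1)
  expect_identical(noiseless$verdict, "robust")

  z0 <- zprime(control_stats(mu = 0, sigma = 1, role = "negative"),
               control_stats(mu = 9, sigma = 2, role = "positive"))
  expect_equal(z0$zprime, 0)
  expect_equal(z0$snr, 1 / 3)
  expect_identical(z0$verdict, "insufficient")

  mid <- zprime(control_stats(mu = 0, sigma = 0.5, role = "negative"),
                control_stats(mu = 10, sigma = 1, role = "positive"))
  expect_identical(mid$verdict, "sufficient")   # z = 0.55
  expect_error(zprime(control_stats(mu = 5, sigma = 1),
                      control_stats(mu = 5, sigma = 1, role = "positive")),
               "separation")
})

test_that("zprime is affine invariant and decreasing in noise", {
  z1 <- zprime(control_stats(mu = 2, sigma = 0.3, role = "negative"),
               control_stats(mu = 11, sigma = 0.7, role = "positive"))
  z10 <- zprime(control_stats(mu = 20, sigma = 3, role = "negative"),
                control_stats(mu = 110, sigma = 7, role = "positive"))
  expect_equal(z1$zprime, z10$zprime)
  zshift <- zprime(control_stats(mu = 2 + 50, sigma = 0.3, role = "negative"),
                   control_stats(mu = 11 + 50, sigma = 0.7, role = "positive"))
  expect_equal(z1$zprime, zshift$zprime)

  sig <- seq(0, 2, by = 0.25)
  zs <- vapply(sig, function(s)
    zprime(control_stats(mu = 0, sigma = s, role = "negative"),
           control_stats(mu = 10, sigma = 1, role = "positive"))$zprime,
    numeric(1))
  expect_true(all(diff(zs) < 0))
  expect_true(all(zs <= 1))
})

test_that("qc_result tidiers expose the control summaries", {
  z <- zprime(control_stats(c(1, 2, 3), "negative"),
              control_stats(c(10, 11, 12), "positive"))
  expect_equal(glance(z)$zprime, z$zprime)
  td <- tidy(z)
  expect_equal(td$mu, c(2, 11))
  expect_equal(td$n, c(3L, 3L))
})

test_that("welch_t behaves on identical, swapped and separated samples", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1.1, 2.3, 2.8); b <- c(5.2, 6.9, 6.1)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)

  far <- welch_t(rep(c(0, 0.01), 4), rep(c(10, 10.01), 4))
  expect_lt(far$p_value, 0.001)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("bonferroni caps and scales p-values", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 5), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("dose-response deltas compare treated wells to matched scramble", {
  ws <- tibble::tibble(
    well = c("T1", "T2", "S1", "S2"),
    condition = c("trt", "trt", "scr", "scr"),
    role = c("sample", "sample", "scramble_control", "scramble_control"),
    dose = c(10, 25, 10, 25), replicate = 1L,
    pct_rfp = c(35, 20, 60, 60), pct_gfp = c(40, 55, 20, 20),
    pct_dual = c(25, 25, 20, 20))
  dr <- dose_response(ws)
  expect_equal(dr$delta_rfp, c(-25, -40))
  expect_equal(dr$delta_gfp, c(20, 35))
  expect_equal(dr$delta_rfp + dr$delta_gfp + dr$delta_dual, c(0, 0),
               tolerance = 1e-9)

  # treated identical to control: all deltas zero
  same <- ws
  same$pct_rfp <- 50; same$pct_gfp <- 30; same$pct_dual <- 20
  dr0 <- dose_response(same)
  expect_true(all(abs(c(dr0$delta_rfp, dr0$delta_gfp, dr0$delta_dual)) < 1e-12))

  expect_error(dose_response(ws[ws$role == "sample", ]), "scramble_control")
})

test_that("plate_qc can compare control arms by condition", {
  ws <- tibble::tibble(
    well = sprintf("W%d", 1:6),
    condition = rep(c("wt", "mut"), each = 3),
    role = "sample", dose = NA_real_, replicate = rep(1:3, 2),
    mean_corr_r = c(10, 11, 12, 100, 105, 110))
  z <- plate_qc(ws, negative = "wt", positive = "mut")
  expect_gt(z$zprime, 0.5)
  expect_error(plate_qc(ws), "control arms")
  expect_error(plate_qc(ws, readout = "nope"), "not found")
})
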