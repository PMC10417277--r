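test_that("cell sampling honours degenerate parameters and determinism", {
  op <- small_optics()
  empty <- sample_condition_cells(
    condition_spec("none", cells_per_field = 0), 3, op, seed = 1)
  expect_equal(nrow(empty), 0L)

  untr <- sample_condition_cells(
    condition_spec("neg", cells_per_field = 15, transfection_rate = 0),
    2, op, seed = 2)
  expect_false(any(untr$transfected))
  expect_true(all(untr$expression == 0))

  a <- sample_condition_cells(condition_spec("wt"), 2, op, seed = 42)
  b <- sample_condition_cells(condition_spec("wt"), 2, op, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a, sample_condition_cells(condition_spec("wt"), 2, op, seed = 43)))
})

test_that("sampled cells satisfy the ground-truth invariants", {
  truth <- sample_condition_cells(condition_spec("wt", cells_per_field = 40),
                                  3, small_optics(), seed = 7)
  expect_equal(nrow(truth), 120L)
  expect_true(all(truth$psi >= 0 & truth$psi <= 1))
  expect_true(all(truth$cell_radius >= truth$nucleus_radius))
  expect_true(all(truth$nucleus_radius > 0))
  # nuclei of the same field never overlap
  for (f in unique(truth$field)) {
    tf <- truth[truth$field == f, ]
    d <- as.matrix(dist(cbind(tf$x, tf$y)))
    lim <- outer(tf$nucleus_radius, tf$nucleus_radius, "+")
    diag(d) <- Inf
    expect_true(all(d > lim))
  }
})

test_that("overcrowded fields fail with an explicit placement error", {
  expect_error(
    sample_condition_cells(
      condition_spec("jam", cells_per_field = 500), 1,
      small_optics(), seed = 1),
    "too crowded")
})

test_that("rendering a cell-free field gives the background level", {
  op <- optics_spec(field_shape = c(64, 64), background_gradient_amplitude = 0,
                    noise_sd = 4)
  empty <- sample_condition_cells(
    condition_spec("none", cells_per_field = 0), 1, op, seed = 1)
  img <- render_field(empty, op, seed = 5)
  tol <- 3 * op$noise_sd / sqrt(64 * 64)
  for (ch in c("hoechst", "gfp", "rfp")) {
    expect_lt(abs(mean(img[[ch]]) - op$background_level[[ch]]), tol + 0.5)
  }
})

test_that("a psi = 1 cell emits RFP but no GFP reporter signal", {
  op <- quiet_optics()
  cell <- tibble::tibble(field = 1L, cell_id = 1L, x = 48, y = 48,
                         nucleus_radius = 5, cell_radius = 9,
                         transfected = TRUE, psi = 1, expression = 400)
  img <- render_field(cell, op, seed = 3)
  inside <- img$gfp[44:52, 44:52]
  # GFP inside the cell stays at background + autofluorescence
  expect_lte(max(inside),
             op$background_level[["gfp"]] + op$autofluorescence[["gfp"]] + 1)
  expect_gt(max(img$rfp), op$background_level[["rfp"]] + 350)
})

test_that("rendered nucleus centroids match segmentation on a noise-free field", {
  op <- quiet_optics()
  truth <- sample_condition_cells(condition_spec("wt", cells_per_field = 10),
                                  1, op, seed = 9)
  img <- render_field(truth, op, seed = 9)
  nuc <- find_nuclei(img$hoechst)
  expect_equal(nrow(nuc$labels), nrow(truth))
  m <- match_centroids(truth, nuc$labels, max_dist = 1)
  expect_equal(m$n_matched, nrow(truth))
})

test_that("plate generation is deterministic and conserves cell counts", {
  lay <- tiny_layout(n_fields = 2, cells_per_field = 10)
  op <- small_optics()
  p1 <- generate_plate(lay, op, seed = 21)
  p2 <- generate_plate(lay, op, seed = 21)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$fields$image, p2$fields$image)
  expect_equal(nrow(p1$fields), 4L)         # 2 wells x 2 fields
  expect_equal(nrow(p1$truth), 2L * 2L * 10L)
  expect_setequal(names(p1$fields$image[[1]]), c("hoechst", "gfp", "rfp"))
})

test_that("a layout without negative controls warns at generation time", {
  lay <- plate_layout(
    wells = tibble::tibble(well = "A1", condition = "wt"),
    conditions = list(wt = condition_spec("wt", cells_per_field = 5)),
    min_fields = 1)
  expect_warning(generate_plate(lay, small_optics(), seed = 1),
                 "negative_control")
})

test_that("raising inclusion_mean shifts truth reporter signal from GFP to RFP", {
  op <- small_optics()
  means <- c(0.2, 0.5, 0.8)
  sig <- vapply(means, function(m) {
    tr <- sample_condition_cells(
      condition_spec("c", cells_per_field = 60, inclusion_mean = m),
      2, op, seed = 31)
    tr <- tr[tr$transfected, ]
    c(rfp = mean(tr$expression * tr$psi),
      gfp = mean(tr$expression * (1 - tr$psi)))
  }, numeric(2))
  expect_true(all(diff(sig["rfp", ]) > 0))
  expect_true(all(diff(sig["gfp", ]) < 0))
})

test_that("summed reporter amplitude per cell equals expression regardless of psi", {
  op <- quiet_optics(autofluorescence = c(hoechst = 0, gfp = 0, rfp = 0))
  for (psi in c(0.1, 0.5, 0.9)) {
    cell <- tibble::tibble(field = 1L, cell_id = 1L, x = 48, y = 48,
                           nucleus_radius = 5, cell_radius = 9,
                           transfected = TRUE, psi = psi, expression = 400)
    img <- render_field(cell, op, seed = 1)
    tot <- (img$gfp - op$background_level[["gfp"]]) +
      (img$rfp - op$background_level[["rfp"]])
    expect_equal(max(tot), 400, tolerance = 1e-2)
  }
})
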