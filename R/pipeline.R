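#' Write plate images and ground truth to disk
#'
#' One 16-bit (or 8-bit) grayscale TIFF per channel per field, named
#' `<well>_f<field>_<channel>.tiff`, plus `truth.csv` (one row per cell)
#' and `layout.yaml` alongside.
#'
#' @param plate A `plate_dataset` from [generate_plate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_images <- function(plate, dir) {
  if (!inherits(plate, "plate_dataset")) abort("`plate` must be a plate_dataset.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^plate$optics$bit_depth - 1
  bps <- plate$optics$bit_depth
  purrr::pwalk(plate$fields, function(well, field, image, ...) {
    for (ch in names(image)) {
      tiff::writeTIFF(image[[ch]] / maxval,
                      file.path(dir, sprintf("%s_f%02d_%s.tiff", well,
                                             field, ch)),
                      bits.per.sample = bps)
    }
  })
  readr::write_csv(plate$truth, file.path(dir, "truth.csv"))
  write_layout(plate$layout, file.path(dir, "layout.yaml"))
  invisible(dir)
}

#' Read plate images from disk
#'
#' Reads the `<well>_f<field>_<channel>.tiff` files declared by a layout
#' back into a `plate_dataset` (without ground truth). Wells with fewer
#' fields on disk than `min_fields` are kept with a warning.
#'
#' @param dir Directory written by [write_plate_images()] or by an export
#'   from an imaging platform following the same naming scheme.
#' @param layout A [plate_layout()]; defaults to `layout.yaml` in `dir`.
#' @param optics An [optics_spec()] describing bit depth and field shape;
#'   default taken from the first image read.
#' @return A `plate_dataset` with a `truth` of `NULL`.
#' @export
read_plate_images <- function(dir, layout = NULL, optics = NULL) {
  if (is.null(layout)) {
    lp <- file.path(dir, "layout.yaml")
    if (!file.exists(lp)) abort("no `layout` given and no layout.yaml in dir.")
    layout <- parse_layout(lp)
  }
  bit_depth <- if (is.null(optics)) 16L else optics$bit_depth
  maxval <- 2^bit_depth - 1
  rows <- list()
  for (i in seq_len(nrow(layout$wells))) {
    wl <- layout$wells[i, ]
    found <- 0L
    for (f in seq_len(layout$min_fields)) {
      paths <- file.path(dir, sprintf("%s_f%02d_%s.tiff", wl$well, f,
                                      layout$channels))
      if (!all(file.exists(paths))) next
      found <- found + 1L
      image <- lapply(setNames(paths, layout$channels), function(p) {
        m <- tiff::readTIFF(p)
        round(m * maxval)
      })
      rows[[length(rows) + 1L]] <-
        tibble(well = wl$well, condition = wl$condition, role = wl$role,
               dose = wl$dose, replicate = wl$replicate, field = f,
               image = list(image))
    }
    if (found < layout$min_fields) {
      warn(sprintf("well %s: %d of %d fields found on disk.",
                   wl$well, found, layout$min_fields))
    }
  }
  if (!length(rows)) abort("no field images found under the layout's naming scheme.")
  structure(list(fields = bind_rows(rows), truth = NULL, layout = layout,
                 optics = optics %||% optics_spec(bit_depth = bit_depth),
                 seed = NA_integer_),
            class = "plate_dataset")
}

#' Run the full imaging analysis pipeline on a plate
#'
#' End-to-end orchestration of the per-cell analysis: segment every field
#' ([measure_plate()]), derive transfection gates from the negative-control
#' wells ([derive_gates()]), gate and classify every cell
#' ([classify_cells()]), summarise wells ([summarize_wells()]) and, when
#' both negative and positive control wells are present, score the plate
#' with [plate_qc()]. Deterministic given the plate and parameters.
#'
#' @param plate A `plate_dataset`.
#' @param seg_params A [segmentation_params()].
#' @param class_params A [classifier_params()].
#' @param k_sigma Gate multiplier for [derive_gates()].
#' @param min_control_cells Minimum negative-control cells required for
#'   gating, see [derive_gates()].
#' @param bg_margin Cell-free margin (px) for background estimation.
#' @param qc_readout Well-summary column used for the Z' readout.
#' @param median_over Denominator for the well median G/R, see
#'   [summarize_wells()].
#' @return A `pipeline_result`: list with `cells` (classified per-cell
#'   tibble), `wells` (well summaries), `gates`, `qc` (a `qc_result` or
#'   `NULL`), and `params`.
#' @export
run_pipeline <- function(plate, seg_params = segmentation_params(),
                         class_params = classifier_params(),
                         k_sigma = 3, min_control_cells = 50L,
                         bg_margin = 5L,
                         qc_readout = "mean_corr_r",
                         median_over = "transfected") {
  cells <- measure_plate(plate, seg_params, bg_margin)
  neg <- filter(cells, .data$role == "negative_control")
  gates <- derive_gates(neg, k_sigma = k_sigma, min_cells = min_control_cells)
  cells <- classify_cells(cells, gates, class_params)
  wells <- summarize_wells(cells, median_over = median_over)
  qc <- if (any(wells$role == "negative_control") &&
            any(wells$role == "positive_control")) {
    plate_qc(wells, readout = qc_readout)
  } else NULL
  structure(list(cells = cells, wells = wells, gates = gates, qc = qc,
                 params = list(seg = seg_params, class = class_params,
                               k_sigma = k_sigma, bg_margin = bg_margin)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cells in %d wells\n",
              nrow(x$cells), nrow(x$wells)))
  if (!is.null(x$qc)) print(x$qc)
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(n_cells = nrow(x$cells), n_wells = nrow(x$wells),
         pct_transfected = 100 * mean(x$cells$transfected),
         zprime = if (is.null(x$qc)) NA_real_ else x$qc$zprime)
}

#' @export
tidy.pipeline_result <- function(x, ...) x$wells

#' Write pipeline outputs as CSV/JSON
#'
#' `cells.csv` (per-cell records with gate/ratio/class columns),
#' `wells.csv` (well summaries), `gates.csv`, and `qc.json` when QC was
#' computed. Stable column order, comma-separated, UTF-8.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  if (!inherits(result, "pipeline_result")) {
    abort("`result` must come from run_pipeline().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$cells, file.path(dir, "cells.csv"))
  readr::write_csv(result$wells, file.path(dir, "wells.csv"))
  readr::write_csv(tidy(result$gates), file.path(dir, "gates.csv"))
  if (!is.null(result$qc)) {
    jsonlite::write_json(
      list(zprime = result$qc$zprime, snr = result$qc$snr,
           verdict = result$qc$verdict,
           negative = result$qc$neg[c("mu", "sigma", "n")],
           positive = result$qc$pos[c("mu", "sigma", "n")]),
      file.path(dir, "qc.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
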