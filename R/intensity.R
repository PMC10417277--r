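#' Robust background level of a channel
#'
#' Median intensity over the cell-free pixels of one field. The median is
#' deliberately insensitive to debris, hot pixels and stray bright objects
#' that survive the cell-free masking.
#'
#' @param img Single-channel image matrix (counts).
#' @param mask Logical matrix of background pixels (e.g. from
#'   [cell_free_mask()]).
#' @return Background level in counts.
#' @export
background_level <- function(img, mask) {
  img <- as_image_matrix(img)
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  if (!is.logical(mask) || !identical(dim(mask), dim(img))) {
    abort("`mask` must be a logical matrix with the shape of `img`.")
  }
  if (!any(mask)) abort("background mask is empty; cannot estimate background.")
  median(img[mask])
}

#' Per-cell background-corrected reporter intensities
#'
#' Measures, for each ROI label, the raw mean GFP and RFP intensity and
#' subtracts the field background estimates; corrected means are floored at
#' zero because intensities are physical counts and the downstream G/R ratio
#' needs non-negative inputs.
#'
#' @param gfp,rfp Channel image matrices (counts), same shape as the ROI
#'   mask.
#' @param rois A `label_mask` of ROIs from [expand_rois()].
#' @param bg_g,bg_r Per-field background estimates (counts) from
#'   [background_level()].
#' @return A tibble with one row per cell: `label`, centroid `x`, `y`,
#'   `roi_area`, `raw_mean_g`, `raw_mean_r`, `bg_g`, `bg_r`, `corr_g`,
#'   `corr_r`.
#' @export
measure_cells <- function(gfp, rfp, rois, bg_g, bg_r) {
  gfp <- as_image_matrix(gfp, "gfp")
  rfp <- as_image_matrix(rfp, "rfp")
  if (!inherits(rois, "label_mask")) abort("`rois` must be a label_mask.")
  if (!identical(dim(gfp), dim(rois$mask)) ||
      !identical(dim(rfp), dim(rois$mask))) {
    abort("`gfp`, `rfp` and the ROI mask must share the same shape.")
  }
  stopifnot_scalar_number(bg_g, "bg_g")
  stopifnot_scalar_number(bg_r, "bg_r")
  if (nrow(rois$labels) == 0L) {
    return(tibble(label = integer(), x = numeric(), y = numeric(),
                  roi_area = numeric(), raw_mean_g = numeric(),
                  raw_mean_r = numeric(), bg_g = numeric(), bg_r = numeric(),
                  corr_g = numeric(), corr_r = numeric()))
  }
  idx <- which(rois$mask > 0)
  lab <- as.integer(rois$mask[idx])
  raw_g <- as.numeric(tapply(gfp[idx], lab, mean))
  raw_r <- as.numeric(tapply(rfp[idx], lab, mean))
  ord <- sort(unique(lab))
  meas <- tibble(label = ord, raw_mean_g = raw_g, raw_mean_r = raw_r)
  rois$labels |>
    select("label", "x", "y", roi_area = "area") |>
    left_join(meas, by = "label") |>
    mutate(bg_g = bg_g, bg_r = bg_r,
           corr_g = pmax(.data$raw_mean_g - bg_g, 0),
           corr_r = pmax(.data$raw_mean_r - bg_r, 0))
}

#' Segment and measure every field of a plate
#'
#' Runs the per-field chain nuclei -> ROIs -> cell-free background -> per-cell
#' corrected intensities over all fields of a `plate_dataset` (or any tibble
#' shaped like its `fields` component) and stacks the per-cell records.
#' Background is estimated per field and per channel, which tolerates
#' field-to-field illumination drift.
#'
#' @param plate A `plate_dataset` from [generate_plate()] or
#'   [read_plate_images()].
#' @param params A [segmentation_params()].
#' @param bg_margin Safety margin (px) for [cell_free_mask()].
#' @return Per-cell tibble: `well`, `condition`, `role`, `dose`,
#'   `replicate`, `field`, plus all [measure_cells()] columns.
#' @export
measure_plate <- function(plate, params = segmentation_params(),
                          bg_margin = 5L) {
  fields <- if (inherits(plate, "plate_dataset")) plate$fields else plate
  purrr::pmap(fields, function(well, condition, role, dose, replicate,
                               field, image) {
    nuc <- find_nuclei(image$hoechst, params)
    rois <- expand_rois(nuc, params$roi_expansion_radius)
    cf <- cell_free_mask(rois, margin = bg_margin)
    cells <- measure_cells(image$gfp, image$rfp, rois,
                           bg_g = background_level(image$gfp, cf$mask),
                           bg_r = background_level(image$rfp, cf$mask))
    mutate(cells, well = well, condition = condition, role = role,
           dose = dose, replicate = replicate, field = field, .before = 1)
  }) |> bind_rows()
}
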