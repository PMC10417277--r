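#' Nuclei segmentation parameters
#'
#' Controls for the Hoechst-channel nucleus detector: Gaussian smoothing, a
#' global threshold (Otsu on the observed intensity range, or fixed), hole
#' filling, an optional distance-transform watershed to split touching
#' nuclei, an area filter, optional removal of border-touching objects, and
#' the perinuclear ROI expansion radius used downstream.
#'
#' The area bounds and ROI radius are assay-tuning parameters with no
#' universal values; the defaults suit ~5-7 px nucleus radii at 20x-like
#' sampling and should be adapted to the magnification at hand.
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold in counts when `threshold_method="fixed"`.
#' @param min_nucleus_area,max_nucleus_area Area filter bounds in pixels^2.
#' @param split_touching Split touching nuclei by watershed on the distance
#'   transform.
#' @param watershed_tolerance Minimum height separating two watershed peaks.
#' @param border_exclusion Drop objects touching the image border.
#' @param roi_expansion_radius Dilation radius (px) for [expand_rois()].
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(smoothing_sigma = 1.5,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_nucleus_area = 20,
                                max_nucleus_area = 500,
                                split_touching = TRUE,
                                watershed_tolerance = 1,
                                border_exclusion = FALSE,
                                roi_expansion_radius = 4L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    abort("`fixed_threshold` is required when threshold_method = \"fixed\".")
  }
  if (min_nucleus_area >= max_nucleus_area) {
    abort("`min_nucleus_area` must be smaller than `max_nucleus_area`.")
  }
  stopifnot_scalar_number(roi_expansion_radius, "roi_expansion_radius", lower = 0)
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 split_touching = isTRUE(split_touching),
                 watershed_tolerance = watershed_tolerance,
                 border_exclusion = isTRUE(border_exclusion),
                 roi_expansion_radius = as.integer(round(roi_expansion_radius))),
            class = "segmentation_params")
}

label_table <- function(mask) {
  idx <- which(mask > 0)
  if (!length(idx)) {
    return(tibble(label = integer(), x = numeric(), y = numeric(),
                  area = numeric()))
  }
  h <- nrow(mask)
  lab <- as.integer(mask[idx])
  row0 <- (idx - 1L) %% h          # 0-based y
  col0 <- (idx - 1L) %/% h         # 0-based x
  tibble(label = sort(unique(lab)),
         x = as.numeric(tapply(col0, lab, mean)),
         y = as.numeric(tapply(row0, lab, mean)),
         area = as.numeric(tapply(lab, lab, length)))
}

relabel <- function(mask, keep) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(keep)) {
    lut <- integer(max(mask))
    lut[keep] <- seq_along(keep)
    nz <- mask > 0
    out[nz] <- lut[mask[nz]]
  }
  out
}

new_label_mask <- function(mask) {
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, labels = label_table(mask)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d objects on %dx%d px\n",
              nrow(x$labels), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Find nuclei in a Hoechst channel image
#'
#' Segments nuclei by Gaussian smoothing, a global threshold, hole filling,
#' an optional distance-transform watershed split of touching objects, an
#' area filter and optional border exclusion. The Otsu threshold is computed
#' on the observed intensity range, so segmentation is invariant to a global
#' additive offset of the channel.
#'
#' @param hoechst Single-channel 2-D image matrix (counts).
#' @param params A [segmentation_params()].
#' @return A `label_mask`: integer label image (0 = background, labels
#'   contiguous `1..N`) plus a `labels` tibble with 0-based centroid `x`,
#'   `y` and `area` (px^2) per object.
#' @export
find_nuclei <- function(hoechst, params = segmentation_params()) {
  img <- as_image_matrix(hoechst, "hoechst")
  rng <- range(img)
  if (diff(rng) == 0) {
    if (rng[1] >= 255) {
      abort("Hoechst image is uniformly saturated; nuclei cannot be segmented.")
    }
    return(new_label_mask(matrix(0L, nrow(img), ncol(img))))
  }
  sm <- if (params$smoothing_sigma > 0) {
    EBImage::gblur(img, sigma = params$smoothing_sigma)
  } else img
  thr <- if (params$threshold_method == "otsu") {
    r <- range(sm)
    EBImage::otsu((sm - r[1]) / diff(r), range = c(0, 1), levels = 256) *
      diff(r) + r[1]
  } else {
    params$fixed_threshold
  }
  bw <- EBImage::fillHull(sm > thr)
  lab <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(bw),
                       tolerance = params$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= params$min_nucleus_area &
                    areas <= params$max_nucleus_area)
    if (params$border_exclusion && length(keep)) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      keep <- setdiff(keep, border[border > 0])
    }
    lab <- relabel(lab, keep)
  }
  new_label_mask(lab)
}

#' Expand nuclei into perinuclear regions of interest
#'
#' Dilates every nucleus by `radius` pixels to obtain the region of interest
#' in which reporter intensity is measured. Contested pixels are assigned to
#' the nearest nucleus (Voronoi-style seeded propagation), so ROIs are
#' disjoint, jointly cover the union of the dilations, include the nucleus
#' interior, and keep the nucleus label identities.
#'
#' @param nuclei A `label_mask` from [find_nuclei()].
#' @param radius Dilation radius in pixels (0 returns the nuclei unchanged).
#' @return A `label_mask` of ROIs; the `labels` tibble keeps the nucleus
#'   centroid as the cell centroid, with ROI areas.
#' @export
expand_rois <- function(nuclei, radius) {
  if (!inherits(nuclei, "label_mask")) abort("`nuclei` must be a label_mask.")
  stopifnot_scalar_number(radius, "radius", lower = 0)
  radius <- as.integer(round(radius))
  if (radius == 0L || nrow(nuclei$labels) == 0L) {
    out <- new_label_mask(nuclei$mask)
    out$labels <- nuclei$labels
    return(out)
  }
  dil <- EBImage::dilate(nuclei$mask > 0,
                         EBImage::makeBrush(2L * radius + 1L, "disc"))
  vor <- EBImage::propagate(matrix(0, nrow(nuclei$mask), ncol(nuclei$mask)),
                            seeds = nuclei$mask, mask = dil, lambda = 1e10)
  mask <- matrix(as.integer(vor), nrow(nuclei$mask), ncol(nuclei$mask))
  out <- new_label_mask(mask)
  # report the nucleus centroid as the cell position, ROI area as the area
  out$labels <- left_join(select(nuclei$labels, "label", "x", "y"),
                          select(label_table(mask), "label", "area"),
                          by = "label")
  out
}

#' Mask of the cell-free background area
#'
#' The background region is the complement of all ROIs dilated by a safety
#' `margin`, so that dim cell edges cannot leak into the background
#' estimate. Fails when less than `min_fraction` of the field is cell-free,
#' in which case no reliable background can be estimated.
#'
#' @param rois A `label_mask` of ROIs.
#' @param margin Safety margin in pixels around every ROI.
#' @param min_fraction Minimal cell-free fraction of the field (default 1%).
#' @return A list with `mask` (logical matrix) and `fraction` (cell-free
#'   area fraction).
#' @export
cell_free_mask <- function(rois, margin = 5L, min_fraction = 0.01) {
  if (!inherits(rois, "label_mask")) abort("`rois` must be a label_mask.")
  stopifnot_scalar_number(margin, "margin", lower = 0)
  margin <- as.integer(round(margin))
  any_roi <- rois$mask > 0
  if (margin > 0L && any(any_roi)) {
    any_roi <- EBImage::dilate(any_roi,
                               EBImage::makeBrush(2L * margin + 1L, "disc"))
  }
  mask <- !any_roi
  fraction <- mean(mask)
  if (fraction < min_fraction) {
    abort(sprintf(
      "insufficient cell-free area (%.2f%% of pixels < %.2f%%): background not estimable",
      100 * fraction, 100 * min_fraction))
  }
  list(mask = mask, fraction = fraction)
}

#' Match detected centroids against ground-truth centroids
#'
#' Greedy nearest-pair matching within `max_dist` pixels, used to score a
#' segmentation against generator truth. Each truth cell and each detection
#' is used at most once.
#'
#' @param truth Data frame with truth centroids `x`, `y`.
#' @param detected Data frame with detected centroids `x`, `y`.
#' @param max_dist Maximal centroid distance (px) counting as a match.
#' @return A one-row tibble: `n_truth`, `n_detected`, `n_matched`,
#'   `precision`, `recall`, `f1`.
#' @export
match_centroids <- function(truth, detected, max_dist = 5) {
  nt <- nrow(truth); nd <- nrow(detected)
  n_matched <- 0L
  if (nt > 0 && nd > 0) {
    d2 <- outer(truth$x, detected$x, "-")^2 + outer(truth$y, detected$y, "-")^2
    cand <- which(d2 <= max_dist^2, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d2[cand])
      used_t <- logical(nt); used_d <- logical(nd)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_t[i] && !used_d[j]) {
          used_t[i] <- TRUE; used_d[j] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  precision <- if (nd > 0) n_matched / nd else NA_real_
  recall <- if (nt > 0) n_matched / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(n_truth = nt, n_detected = nd, n_matched = n_matched,
         precision = precision, recall = recall, f1 = f1)
}
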