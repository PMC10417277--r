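#' Classifier thresholds for the G/R ratio
#'
#' Cells are assigned to three subpopulations by their background-corrected
#' GFP/RFP intensity ratio: below the lower threshold `K` the cell
#' predominantly expresses RFP (exon included, E10+), above the upper
#' threshold `J` it predominantly expresses GFP (exon skipped, E10-), and in
#' between both reporters are present in comparable amounts ("dual" /
#' yellow). Boundary ratios equal to `K` or `J` fall in the dual bucket.
#'
#' @param K Lower ratio threshold (default 2).
#' @param J Upper ratio threshold (default 5).
#' @param epsilon Ratio regulariser in counts (default 1); added to both
#'   channels so the ratio stays finite when RFP is zero.
#' @return A `classifier_params` object.
#' @export
classifier_params <- function(K = 2, J = 5, epsilon = 1) {
  stopifnot_scalar_number(K, "K", lower = 1e-12)
  stopifnot_scalar_number(J, "J")
  stopifnot_scalar_number(epsilon, "epsilon", lower = 1e-12)
  if (K >= J) abort("`K` must be strictly smaller than `J`.")
  structure(list(K = K, J = J, epsilon = epsilon),
            class = "classifier_params")
}

SPLICE_CLASSES <- c("E10plus_RFP", "dual", "E10minus_GFP")

#' Derive transfection gates from negative-control cells
#'
#' The transfection gate for each reporter channel is
#' `mean + k_sigma * sd` of the background-corrected intensity over cells
#' from untransfected (negative control) wells, i.e. an upper envelope of
#' the autofluorescence distribution.
#'
#' @param neg_cells Per-cell tibble (with `corr_g`, `corr_r`) restricted to
#'   negative-control wells.
#' @param k_sigma Multiplier on the control SD (default 3).
#' @param min_cells Minimum control cells required (default 50).
#' @return A `gate_thresholds` object with `gate_g`, `gate_r`.
#' @export
derive_gates <- function(neg_cells, k_sigma = 3, min_cells = 50L) {
  if (is.null(neg_cells) || nrow(neg_cells) == 0L) {
    abort(paste("no negative_control cells available:",
                "the layout must declare at least one negative_control well."))
  }
  if (nrow(neg_cells) < min_cells) {
    abort(sprintf(
      "only %d negative_control cells (< %d): gates would be unstable.",
      nrow(neg_cells), min_cells))
  }
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  structure(list(
    gate_g = mean(neg_cells$corr_g) + k_sigma * sd0(neg_cells$corr_g),
    gate_r = mean(neg_cells$corr_r) + k_sigma * sd0(neg_cells$corr_r),
    k_sigma = k_sigma,
    n_control = nrow(neg_cells),
    source = unique(neg_cells$well %||% NA_character_)),
    class = "gate_thresholds")
}

#' @export
print.gate_thresholds <- function(x, ...) {
  cat(sprintf("<gate_thresholds> gate_g %.2f, gate_r %.2f (mean + %g sd of %d control cells)\n",
              x$gate_g, x$gate_r, x$k_sigma, x$n_control))
  invisible(x)
}

#' @export
tidy.gate_thresholds <- function(x, ...) {
  tibble(channel = c("gfp", "rfp"), gate = c(x$gate_g, x$gate_r),
         k_sigma = x$k_sigma, n_control = x$n_control)
}

#' Transfection gate: is a cell reporter-positive?
#'
#' A cell counts as transfected when it is positive for either reporter:
#' corrected GFP at or above the GFP gate, or corrected RFP at or above the
#' RFP gate.
#'
#' @param cells Per-cell tibble with `corr_g`, `corr_r`.
#' @param gates A [derive_gates()] result.
#' @return Logical vector, one entry per cell.
#' @export
is_transfected <- function(cells, gates) {
  if (!inherits(gates, "gate_thresholds")) {
    abort("`gates` must come from derive_gates().")
  }
  cells$corr_g >= gates$gate_g | cells$corr_r >= gates$gate_r
}

#' Regularised per-cell G/R ratio
#'
#' `(corr_g + epsilon) / (corr_r + epsilon)`: always finite and positive
#' even when a corrected channel is zero.
#'
#' @param corr_g,corr_r Background-corrected mean intensities (counts >= 0).
#' @param epsilon Regulariser in counts.
#' @return Numeric vector of ratios.
#' @export
g_over_r <- function(corr_g, corr_r, epsilon = 1) {
  stopifnot_scalar_number(epsilon, "epsilon", lower = 1e-12)
  if (any(corr_g < 0, na.rm = TRUE) || any(corr_r < 0, na.rm = TRUE)) {
    abort("corrected intensities must be non-negative.")
  }
  (corr_g + epsilon) / (corr_r + epsilon)
}

#' Classify a G/R ratio into the three splice subpopulations
#'
#' @param ratio Positive ratio vector.
#' @param params A [classifier_params()].
#' @return Factor with levels `E10plus_RFP` (ratio < K), `dual`
#'   (K <= ratio <= J) and `E10minus_GFP` (ratio > J).
#' @export
classify_ratio <- function(ratio, params = classifier_params()) {
  if (!inherits(params, "classifier_params")) {
    abort("`params` must come from classifier_params().")
  }
  out <- rep("dual", length(ratio))
  out[ratio > params$J] <- "E10minus_GFP"
  out[ratio < params$K] <- "E10plus_RFP"
  out[is.na(ratio)] <- NA
  factor(out, levels = SPLICE_CLASSES)
}

#' Gate and classify a per-cell table
#'
#' Adds the `transfected` flag, the regularised `g_over_r` ratio and the
#' `splice_class` assignment to a measured per-cell table.
#'
#' @param cells Per-cell tibble from [measure_plate()] / [measure_cells()].
#' @param gates A [derive_gates()] result.
#' @param params A [classifier_params()].
#' @return `cells` with `transfected`, `g_over_r`, `splice_class` appended.
#' @export
classify_cells <- function(cells, gates, params = classifier_params()) {
  ratio <- g_over_r(cells$corr_g, cells$corr_r, params$epsilon)
  mutate(cells,
         transfected = is_transfected(cells, gates),
         g_over_r = ratio,
         splice_class = classify_ratio(ratio, params))
}

#' Per-well feature summary
#'
#' The feature outputs of the imaging analysis: total cell count, percentage
#' of transfected cells over all cells, the median G/R ratio, and the
#' percentage of cells preferentially expressing RFP (E10+), GFP (E10-) or
#' both reporters. Class percentages (and, by default, the median G/R) are
#' computed over transfected cells only, so they are not diluted by
#' autofluorescent untransfected cells; `median_over = "all"` restores the
#' all-cells median. Wells with zero cells (or zero transfected cells) keep
#' `NA` percentages rather than silent zeros, flagged by `ok = FALSE`.
#'
#' @param cells Classified per-cell tibble from [classify_cells()]; may span
#'   several wells, grouping is by `well`.
#' @param median_over `"transfected"` (default) or `"all"`.
#' @return One row per well: `well`, `condition`, `role`, `dose`,
#'   `replicate`, `total_cells`, `n_transfected`, `pct_transfected`,
#'   `mean_corr_g`, `mean_corr_r` (per-cell means over all cells, the
#'   default Z' readouts), `median_g_over_r`, `pct_rfp`, `pct_dual`,
#'   `pct_gfp`, `ok`.
#' @export
summarize_wells <- function(cells, median_over = c("transfected", "all")) {
  median_over <- match.arg(median_over)
  if (!all(c("transfected", "g_over_r", "splice_class") %in% names(cells))) {
    abort("`cells` must be classified first; see classify_cells().")
  }
  for (col in c("condition", "role", "dose", "replicate")) {
    if (!col %in% names(cells)) cells[[col]] <- NA
  }
  cells |>
    group_by(.data$well, .data$condition, .data$role, .data$dose,
             .data$replicate) |>
    summarise(
      total_cells = dplyr::n(),
      n_transfected = sum(.data$transfected),
      pct_transfected = 100 * mean(.data$transfected),
      mean_corr_g = mean(.data$corr_g),
      mean_corr_r = mean(.data$corr_r),
      median_g_over_r = if (median_over == "all") median(.data$g_over_r)
        else if (any(.data$transfected))
          median(.data$g_over_r[.data$transfected]) else NA_real_,
      pct_rfp = if (any(.data$transfected))
        100 * mean(.data$splice_class[.data$transfected] == "E10plus_RFP")
        else NA_real_,
      pct_dual = if (any(.data$transfected))
        100 * mean(.data$splice_class[.data$transfected] == "dual")
        else NA_real_,
      pct_gfp = if (any(.data$transfected))
        100 * mean(.data$splice_class[.data$transfected] == "E10minus_GFP")
        else NA_real_,
      ok = dplyr::n() > 0 & any(.data$transfected),
      .groups = "drop")
}

#' Truth-derived class fractions for a synthetic condition
#'
#' Computes, from generator ground truth, the class percentages that an
#' ideal noise-free classifier would report: each transfected cell's
#' signal-model ratio `(1 - psi) / psi` is pushed through the same K/J rule
#' used for measured cells. This is the oracle against which recovered class
#' percentages are compared.
#'
#' @param truth Ground-truth tibble from [sample_condition_cells()] or a
#'   `plate_dataset$truth` (optionally filtered to one well).
#' @param params A [classifier_params()] (epsilon is not used: the truth
#'   ratio is formed directly from psi).
#' @return One-row tibble: `n_transfected`, `pct_rfp`, `pct_dual`,
#'   `pct_gfp`.
#' @export
truth_class_fractions <- function(truth, params = classifier_params()) {
  tr <- filter(truth, .data$transfected)
  ratio <- (1 - tr$psi) / pmax(tr$psi, .Machine$double.eps)
  cls <- classify_ratio(ratio, params)
  tibble(n_transfected = nrow(tr),
         pct_rfp = 100 * mean(cls == "E10plus_RFP"),
         pct_dual = 100 * mean(cls == "dual"),
         pct_gfp = 100 * mean(cls == "E10minus_GFP"))
}
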