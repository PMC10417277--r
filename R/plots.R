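#' Per-cell GFP vs RFP scatter plot
#'
#' The classic two-colour reporter scatter: each transfected cell plotted by
#' its background-corrected RFP (x) and GFP (y) intensity on log axes,
#' coloured by splice class, with the K and J ratio thresholds drawn as
#' diagonal guide lines.
#'
#' @param cells Classified per-cell tibble from [classify_cells()].
#' @param params The [classifier_params()] used (for the guide lines).
#' @param transfected_only Drop untransfected cells (default TRUE).
#' @return A ggplot object.
#' @export
plot_cell_scatter <- function(cells, params = classifier_params(),
                              transfected_only = TRUE) {
  df <- if (transfected_only) filter(cells, .data$transfected) else cells
  df <- mutate(df, r1 = .data$corr_r + params$epsilon,
               g1 = .data$corr_g + params$epsilon)
  rng <- range(c(df$r1, df$g1))
  guide <- tidyr::expand_grid(thr = c(K = params$K, J = params$J),
                              r1 = rng) |>
    mutate(g1 = .data$thr * .data$r1,
           thr = factor(.data$thr, labels = c(
             sprintf("K = %g", params$K), sprintf("J = %g", params$J))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r1, y = .data$g1)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$splice_class),
                        size = 0.6, alpha = 0.7) +
    ggplot2::geom_line(data = guide,
                       ggplot2::aes(group = .data$thr),
                       linetype = "dashed", colour = "grey30") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(E10plus_RFP = "#c0392b",
                                            dual = "#d4a017",
                                            E10minus_GFP = "#27ae60"),
                                 drop = FALSE) +
    ggplot2::labs(x = "corrected RFP (counts)", y = "corrected GFP (counts)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Well-summary class composition bar chart
#'
#' @param wells Well summaries from [summarize_wells()].
#' @return A ggplot object.
#' @export
plot_well_classes <- function(wells) {
  df <- wells |>
    tidyr::pivot_longer(c("pct_rfp", "pct_dual", "pct_gfp"),
                        names_to = "class", values_to = "pct") |>
    mutate(class = factor(.data$class,
                          levels = c("pct_rfp", "pct_dual", "pct_gfp"),
                          labels = c("RFP (E10+)", "dual", "GFP (E10-)")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$well, y = .data$pct,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c("#c0392b", "#d4a017", "#27ae60")) +
    ggplot2::labs(x = NULL, y = "% of transfected cells", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response delta plot
#'
#' Class-percentage deltas (treated minus matched scramble control) against
#' dose, one line per class.
#'
#' @param dr Output of [dose_response()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(dr) {
  df <- dr |>
    tidyr::pivot_longer(c("delta_rfp", "delta_gfp", "delta_dual"),
                        names_to = "class", values_to = "delta") |>
    mutate(class = factor(.data$class,
                          levels = c("delta_rfp", "delta_dual", "delta_gfp"),
                          labels = c("RFP (E10+)", "dual", "GFP (E10-)")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$delta,
                                   colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c("#c0392b", "#d4a017", "#27ae60")) +
    ggplot2::labs(x = "dose (nM)", y = "delta vs scramble (pct points)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Lane profile with detected bands
#'
#' @param profile Lane profile tibble (`position`, `intensity`).
#' @param bands Optional band tibble from [detect_bands()] or
#'   [assign_bands()]; band supports are shaded and centres marked.
#' @return A ggplot object.
#' @export
plot_lane <- function(profile, bands = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position,
                                             y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "migration position (px)", y = "intensity (counts)") +
    ggplot2::theme_minimal()
  if (!is.null(bands) && nrow(bands)) {
    lab <- if ("assignment" %in% names(bands)) bands$assignment else
      sprintf("band %d", seq_len(nrow(bands)))
    p <- p +
      ggplot2::geom_rect(data = mutate(bands, lab = lab),
                         ggplot2::aes(xmin = .data$left, xmax = .data$right,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, alpha = 0.12, fill = "steelblue") +
      ggplot2::geom_vline(xintercept = bands$center, linetype = "dotted")
  }
  p
}

#' @export
autoplot.pipeline_result <- function(object, ...) {
  plot_cell_scatter(object$cells, object$params$class, ...)
}
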