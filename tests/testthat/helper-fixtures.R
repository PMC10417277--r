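# Shared desk-scale fixtures, all generated in code.

small_optics <- function(...) {
  optics_spec(field_shape = c(192, 192), ...)
}

quiet_optics <- function(...) {
  # deterministic image formation: no gradient, no noise
  optics_spec(field_shape = c(96, 96), background_gradient_amplitude = 0,
              noise_sd = 0, ...)
}

# Flat image with bright discs at given 0-based centres.
disc_image <- function(h, w, centers, radius, fg = 500, bg = 100) {
  img <- matrix(bg, h, w)
  for (i in seq_len(nrow(centers))) {
    xy <- expand.grid(y = 0:(h - 1), x = 0:(w - 1))
    keep <- (xy$x - centers$x[i])^2 + (xy$y - centers$y[i])^2 <= radius^2
    img[cbind(xy$y[keep] + 1, xy$x[keep] + 1)] <- fg
  }
  img
}

tiny_layout <- function(n_fields = 2L, cells_per_field = 12L) {
  plate_layout(
    wells = tibble::tibble(well = c("A1", "A2"),
                           condition = c("wt", "untransfected")),
    conditions = list(
      wt = condition_spec("wt", cells_per_field = cells_per_field,
                          inclusion_mean = 0.35),
      untransfected = condition_spec("untransfected",
                                     cells_per_field = cells_per_field,
                                     transfection_rate = 0,
                                     role = "negative_control")),
    min_fields = n_fields)
}

# Synthetic five-rung ladder following the log-linear mobility law.
demo_ladder <- function(noise = 0) {
  sizes <- c(100, 200, 300, 500, 1000)
  pos <- 400 - 120 * log10(sizes) + noise * c(0.3, -0.5, 0.2, -0.1, 0.4)
  list(positions = rev(pos), sizes = rev(sizes))  # increasing positions
}
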