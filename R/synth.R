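#' Describe one experimental condition for the synthetic plate generator
#'
#' A condition bundles the biology the generator emulates for a set of wells:
#' how many adherent cells are plated per imaged field, which fraction of them
#' takes up the two-colour splicing reporter, and the distribution of the
#' per-cell exon-inclusion fraction psi. A cell with inclusion fraction psi
#' produces RFP reporter signal proportional to `expression * psi` (exon
#' included) and GFP signal proportional to `expression * (1 - psi)` (exon
#' skipped), so a high `inclusion_mean` emulates a splice-switching mutant and
#' a low one the wild-type reporter.
#'
#' `inclusion_mean` (with matching `inclusion_concentration` and optional
#' `inclusion_weights`) may be a vector, in which case each cell's psi is
#' drawn from the corresponding Beta mixture; this is how bimodal populations
#' with cleanly separated GFP- and RFP-dominant regimes are simulated.
#'
#' @param name Condition label used in plate layouts.
#' @param cells_per_field Number of cells placed in every imaged field.
#' @param transfection_rate Probability that a cell carries the reporter.
#' @param inclusion_mean Mean exon-inclusion fraction psi of transfected
#'   cells, in `[0, 1]`. May be a vector of mixture-component means.
#' @param inclusion_concentration Concentration (shape1 + shape2) of the Beta
#'   distribution of per-cell psi; larger values give a tighter spread.
#'   Recycled against `inclusion_mean`.
#' @param inclusion_weights Mixture weights, recycled and normalised to sum
#'   to one. Default: equal weights.
#' @param expression_log_mean,expression_log_sd Log-scale location and spread
#'   of the per-cell reporter expression level (counts), drawn log-normally.
#' @param role One of `"sample"`, `"negative_control"`,
#'   `"positive_control"`, `"scramble_control"`.
#' @return A `condition_spec` object.
#' @examples
#' wt <- condition_spec("wt", inclusion_mean = 0.35)
#' mut <- condition_spec("mut", inclusion_mean = 0.85, role = "positive_control")
#' @export
condition_spec <- function(name,
                           cells_per_field = 90L,
                           transfection_rate = 0.7,
                           inclusion_mean = 0.35,
                           inclusion_concentration = 8,
                           inclusion_weights = NULL,
                           expression_log_mean = log(350),
                           expression_log_sd = 0.5,
                           role = c("sample", "negative_control",
                                    "positive_control", "scramble_control")) {
  role <- role[1]
  if (!role %in% VALID_ROLES) {
    abort(sprintf("unknown role '%s' (valid: %s)", role,
                  paste(VALID_ROLES, collapse = ", ")))
  }
  stopifnot_scalar_number(cells_per_field, "cells_per_field", lower = 0)
  stopifnot_scalar_number(transfection_rate, "transfection_rate", 0, 1)
  if (!is.numeric(inclusion_mean) || any(inclusion_mean < 0) ||
      any(inclusion_mean > 1)) {
    abort("`inclusion_mean` must lie in [0, 1].")
  }
  if (any(inclusion_concentration <= 0)) {
    abort("`inclusion_concentration` must be positive.")
  }
  k <- length(inclusion_mean)
  conc <- rep_len(inclusion_concentration, k)
  w <- if (is.null(inclusion_weights)) rep(1, k) else
    rep_len(inclusion_weights, k)
  if (any(w < 0) || sum(w) <= 0) abort("`inclusion_weights` must be non-negative.")
  structure(
    list(name = as.character(name),
         cells_per_field = as.integer(cells_per_field),
         transfection_rate = transfection_rate,
         inclusion_mean = inclusion_mean,
         inclusion_concentration = conc,
         inclusion_weights = w / sum(w),
         expression_log_mean = expression_log_mean,
         expression_log_sd = expression_log_sd,
         role = role),
    class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> %s (%s)\n", x$name, x$role))
  cat(sprintf("  cells/field %d, transfection %.2f\n",
              x$cells_per_field, x$transfection_rate))
  cat(sprintf("  psi ~ Beta mixture: mean %s, concentration %s\n",
              paste(format(x$inclusion_mean), collapse = "/"),
              paste(format(x$inclusion_concentration), collapse = "/")))
  invisible(x)
}

#' Optical and camera model for synthetic field rendering
#'
#' Parameters of the simplified wide-field image formation model: a constant
#' per-channel background plus a smooth low-order polynomial illumination
#' gradient, cellular autofluorescence inside every cell (transfected or
#' not), homogeneous reporter fluorescence across the cell disc of
#' transfected cells, Hoechst signal confined to the nucleus, and additive
#' Gaussian detector noise, quantised to the camera bit depth.
#'
#' @param field_shape Image height and width in pixels, `c(h, w)`.
#' @param background_level Named per-channel baseline counts
#'   (`hoechst`, `gfp`, `rfp`).
#' @param background_gradient_amplitude Peak amplitude (counts) of the smooth
#'   illumination gradient added to every channel.
#' @param autofluorescence Named per-channel counts added inside all cells.
#' @param hoechst_intensity Mean nuclear Hoechst amplitude (counts).
#' @param noise_sd Standard deviation of the additive Gaussian noise (counts).
#' @param bit_depth Camera bit depth; 8 or 16.
#' @return An `optics_spec` object.
#' @export
optics_spec <- function(field_shape = c(256L, 256L),
                        background_level = c(hoechst = 100, gfp = 90, rfp = 90),
                        background_gradient_amplitude = 25,
                        autofluorescence = c(hoechst = 8, gfp = 12, rfp = 12),
                        hoechst_intensity = 500,
                        noise_sd = 6,
                        bit_depth = 16L) {
  if (length(field_shape) != 2L || any(field_shape < 32)) {
    abort("`field_shape` must be c(h, w) with both dimensions >= 32 px.")
  }
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  ch <- c("hoechst", "gfp", "rfp")
  bg <- background_level[ch]
  af <- autofluorescence[ch]
  if (anyNA(bg) || anyNA(af)) {
    abort("`background_level` and `autofluorescence` need hoechst/gfp/rfp entries.")
  }
  if (any(c(bg, af, background_gradient_amplitude, noise_sd,
            hoechst_intensity) < 0)) {
    abort("optical levels must be non-negative.")
  }
  structure(
    list(field_shape = as.integer(field_shape),
         background_level = bg,
         background_gradient_amplitude = background_gradient_amplitude,
         autofluorescence = af,
         hoechst_intensity = hoechst_intensity,
         noise_sd = noise_sd,
         bit_depth = as.integer(bit_depth)),
    class = "optics_spec")
}

beta_shapes <- function(mean, concentration) {
  list(shape1 = mean * concentration, shape2 = (1 - mean) * concentration)
}

sample_psi <- function(n, spec) {
  k <- length(spec$inclusion_mean)
  comp <- if (k == 1L) rep(1L, n) else
    sample.int(k, n, replace = TRUE, prob = spec$inclusion_weights)
  psi <- numeric(n)
  for (j in seq_len(k)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    m <- spec$inclusion_mean[j]
    if (m == 0 || m == 1) {
      psi[idx] <- m  # degenerate Beta limit
    } else {
      sh <- beta_shapes(m, spec$inclusion_concentration[j])
      psi[idx] <- rbeta(length(idx), sh$shape1, sh$shape2)
    }
  }
  psi
}

place_cells <- function(n, h, w, nucleus_radius, cell_radius,
                        max_retries = 500L) {
  x <- numeric(n); y <- numeric(n)
  if (n == 0L) return(list(x = x, y = y))
  for (i in seq_len(n)) {
    margin <- cell_radius[i] + 1
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      cx <- runif(1, margin, w - 1 - margin)
      cy <- runif(1, margin, h - 1 - margin)
      if (i == 1L) { ok <- TRUE } else {
        prev <- seq_len(i - 1L)
        # nuclei must not overlap and must keep a 2 px guard band
        mind <- nucleus_radius[i] + nucleus_radius[prev] + 2
        ok <- all((cx - x[prev])^2 + (cy - y[prev])^2 > mind^2)
      }
      if (ok) { x[i] <- cx; y[i] <- cy; placed <- TRUE; break }
    }
    if (!placed) {
      abort(sprintf(
        "could not place cell %d of %d after %d retries: field too crowded",
        i, n, max_retries))
    }
  }
  list(x = x, y = y)
}

#' Sample per-cell ground truth for one condition
#'
#' Draws the full per-cell ground-truth table for `n_fields` imaged fields of
#' one condition: cell positions (rejection-sampled so nuclei never overlap),
#' nucleus and cell radii, a Bernoulli transfection flag, the per-cell
#' exon-inclusion fraction psi from the condition's Beta (mixture)
#' distribution, and a log-normal reporter expression level. Untransfected
#' cells carry expression 0 and contribute no reporter signal.
#'
#' @param spec A [condition_spec()].
#' @param n_fields Number of fields to populate.
#' @param optics An [optics_spec()]; provides the field geometry.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with one row per cell: `field`, `cell_id`, `x`, `y`
#'   (0-based pixel-centre centroid), `nucleus_radius`, `cell_radius`,
#'   `transfected`, `psi`, `expression`.
#' @examples
#' truth <- sample_condition_cells(condition_spec("wt"), 2, optics_spec(), seed = 1)
#' @export
sample_condition_cells <- function(spec, n_fields, optics = optics_spec(),
                                   seed) {
  if (!inherits(spec, "condition_spec")) abort("`spec` must be a condition_spec.")
  stopifnot_scalar_number(n_fields, "n_fields", lower = 1)
  stopifnot_scalar_number(seed, "seed")
  h <- optics$field_shape[1]; w <- optics$field_shape[2]
  fields <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_fields), function(f) {
      n <- spec$cells_per_field
      if (n == 0L) {
        return(tibble(field = integer(), cell_id = integer(),
                      x = numeric(), y = numeric(),
                      nucleus_radius = numeric(), cell_radius = numeric(),
                      transfected = logical(), psi = numeric(),
                      expression = numeric()))
      }
      nucleus_radius <- pmin(pmax(rnorm(n, 5.5, 0.6), 4), 7.5)
      cell_radius <- nucleus_radius + runif(n, 2.5, 4.5)
      pos <- place_cells(n, h, w, nucleus_radius, cell_radius)
      transfected <- runif(n) < spec$transfection_rate
      psi <- sample_psi(n, spec)
      expression <- rlnorm(n, spec$expression_log_mean, spec$expression_log_sd)
      expression[!transfected] <- 0
      tibble(field = f, cell_id = seq_len(n), x = pos$x, y = pos$y,
             nucleus_radius = nucleus_radius, cell_radius = cell_radius,
             transfected = transfected, psi = psi, expression = expression)
    })
  })
  bind_rows(fields)
}

disc_indices <- function(h, w, cx, cy, r) {
  # pixel-centre convention, 0-based coordinates
  x0 <- max(0L, floor(cx - r)); x1 <- min(w - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(h - 1L, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  (g$x[keep]) * h + g$y[keep] + 1L  # linear index into h x w matrix
}

#' Render one multichannel field from ground truth
#'
#' Renders the Hoechst, GFP and RFP channels of one field under the image
#' formation model of [optics_spec()]: cells are concentric discs (nucleus
#' inside cytoplasm) with homogeneous reporter intensity, GFP amplitude
#' `expression * (1 - psi)` and RFP amplitude `expression * psi`, so the
#' summed reporter amplitude of a transfected cell is its expression level
#' regardless of psi.
#'
#' @param cells Ground-truth tibble for one field, as produced by
#'   [sample_condition_cells()] (rows of one `field`).
#' @param optics An [optics_spec()].
#' @param seed Integer seed driving the illumination gradient and noise.
#' @return A named list of three `h x w` count matrices:
#'   `hoechst`, `gfp`, `rfp`.
#' @export
render_field <- function(cells, optics = optics_spec(), seed) {
  stopifnot_scalar_number(seed, "seed")
  h <- optics$field_shape[1]; w <- optics$field_shape[2]
  if (nrow(cells) > 0 &&
      (any(cells$x < 0) || any(cells$x > w - 1) ||
       any(cells$y < 0) || any(cells$y > h - 1))) {
    abort("cell centroids must fall inside the field.")
  }
  maxval <- 2^optics$bit_depth - 1
  withr::with_seed(as.integer(seed), {
    u <- matrix(rep((0:(w - 1)) / max(1, w - 1), each = h), h, w)
    v <- matrix(rep((0:(h - 1)) / max(1, h - 1), times = w), h, w)
    cf <- runif(3)
    grad <- optics$background_gradient_amplitude *
      (cf[1] * u + cf[2] * v + cf[3] * u * v) / sum(cf)
    imgs <- lapply(c(hoechst = "hoechst", gfp = "gfp", rfp = "rfp"),
                   function(ch) matrix(optics$background_level[[ch]], h, w) + grad)
    if (nrow(cells) > 0) {
      hjit <- rlnorm(nrow(cells), 0, 0.15)
      for (i in seq_len(nrow(cells))) {
        nuc <- disc_indices(h, w, cells$x[i], cells$y[i], cells$nucleus_radius[i])
        cyt <- disc_indices(h, w, cells$x[i], cells$y[i], cells$cell_radius[i])
        imgs$hoechst[nuc] <- imgs$hoechst[nuc] + optics$hoechst_intensity * hjit[i]
        imgs$hoechst[cyt] <- imgs$hoechst[cyt] + optics$autofluorescence[["hoechst"]]
        imgs$gfp[cyt] <- imgs$gfp[cyt] + optics$autofluorescence[["gfp"]]
        imgs$rfp[cyt] <- imgs$rfp[cyt] + optics$autofluorescence[["rfp"]]
        if (isTRUE(cells$transfected[i]) && cells$expression[i] > 0) {
          imgs$gfp[cyt] <- imgs$gfp[cyt] + cells$expression[i] * (1 - cells$psi[i])
          imgs$rfp[cyt] <- imgs$rfp[cyt] + cells$expression[i] * cells$psi[i]
        }
      }
    }
    lapply(imgs, function(m) {
      if (optics$noise_sd > 0) m <- m + matrix(rnorm(h * w, 0, optics$noise_sd), h, w)
      matrix(pmin(pmax(round(m), 0), maxval), h, w)
    })
  })
}

#' Generate a full synthetic plate with ground truth
#'
#' Renders every field of every well declared in a [plate_layout()] and
#' returns the images together with the exact per-cell ground truth, so each
#' downstream stage (segmentation, intensity, gating, classification, QC) can
#' be validated against known answers. Generation is fully deterministic
#' given `(layout, optics, seed)`.
#'
#' @param layout A [plate_layout()]; its `conditions` list supplies the
#'   [condition_spec()] of each well and `min_fields` the fields per well.
#' @param optics An [optics_spec()].
#' @param seed Integer master seed.
#' @return A `plate_dataset`: list with `fields` (tibble, one row per
#'   well/field with an `image` list-column of 3-channel matrices), `truth`
#'   (per-cell tibble with `well` prepended), plus `layout`, `optics`,
#'   `seed`.
#' @examples
#' lay <- plate_layout(
#'   wells = tibble::tibble(well = c("A1", "A2"),
#'                          condition = c("wt", "untransfected")),
#'   conditions = list(
#'     wt = condition_spec("wt", cells_per_field = 12),
#'     untransfected = condition_spec("untransfected", cells_per_field = 12,
#'                                    transfection_rate = 0,
#'                                    role = "negative_control")),
#'   min_fields = 2)
#' plate <- generate_plate(lay, optics_spec(field_shape = c(96, 96)), seed = 7)
#' @export
generate_plate <- function(layout, optics = optics_spec(), seed) {
  if (!inherits(layout, "plate_layout")) abort("`layout` must be a plate_layout.")
  stopifnot_scalar_number(seed, "seed")
  if (!any(layout$wells$role == "negative_control")) {
    warn(paste("layout declares no negative_control well;",
               "transfection gating will not be derivable downstream."))
  }
  wells <- layout$wells
  fields_list <- vector("list", nrow(wells))
  truth_list <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    spec <- layout$conditions[[wells$condition[i]]]
    truth <- sample_condition_cells(spec, layout$min_fields, optics,
                                    seed = child_seed(seed, i))
    imgs <- purrr::map(seq_len(layout$min_fields), function(f) {
      render_field(dplyr::filter(truth, .data$field == f), optics,
                   seed = child_seed(seed, i, 1000L + f))
    })
    fields_list[[i]] <- tibble(
      well = wells$well[i], condition = wells$condition[i],
      role = wells$role[i], dose = wells$dose[i],
      replicate = wells$replicate[i],
      field = seq_len(layout$min_fields), image = imgs)
    truth_list[[i]] <- mutate(truth, well = wells$well[i], .before = 1)
  }
  structure(list(fields = bind_rows(fields_list),
                 truth = bind_rows(truth_list),
                 layout = layout, optics = optics,
                 seed = as.integer(seed)),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("<plate_dataset> %d wells x %d fields, %d cells (seed %d)\n",
              length(unique(x$fields$well)),
              max(x$fields$field), nrow(x$truth), x$seed))
  invisible(x)
}
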