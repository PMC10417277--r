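#' Expected amplicon sizes for band assignment
#'
#' Two primer sets are in play: the reporter-specific set (E10+ 300 bp,
#' E10- 207 bp) and the endogenous set (E10+ 368 bp, E10- 275 bp), each with
#' the 650 bp Beta-Actin housekeeping amplicon used for normalisation.
#'
#' @param set `"reporter"` (default) or `"endogenous"`.
#' @return Named vector (`e10plus`, `e10minus`, `actin`) of sizes in bp.
#' @export
expected_sizes <- function(set = c("reporter", "endogenous")) {
  switch(match.arg(set),
         reporter = c(e10plus = 300, e10minus = 207, actin = 650),
         endogenous = c(e10plus = 368, e10minus = 275, actin = 650))
}

#' Calibrate a gel lane from ladder rungs
#'
#' Least-squares fit of migration position against `log10(size in bp)`, the
#' standard electrophoretic mobility approximation. The fit exposes size
#' prediction for unknown bands via [predict_size()].
#'
#' @param rung_positions Rung centre positions (px) along the migration
#'   axis; must be strictly monotone.
#' @param rung_sizes Matching fragment sizes in bp.
#' @return A `ladder_calibration` object.
#' @export
calibrate_ladder <- function(rung_positions, rung_sizes) {
  if (length(rung_positions) != length(rung_sizes)) {
    abort("`rung_positions` and `rung_sizes` must have equal length.")
  }
  if (length(rung_positions) < 3L) {
    abort("ladder calibration needs at least 3 rungs.")
  }
  d <- diff(rung_positions)
  if (!(all(d > 0) || all(d < 0))) {
    abort("rung positions must be strictly monotone along the lane.")
  }
  if (any(rung_sizes <= 0)) abort("rung sizes must be positive (bp).")
  fit <- lm(pos ~ logsize,
            data = data.frame(pos = rung_positions,
                              logsize = log10(rung_sizes)))
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 rungs = tibble(position = rung_positions,
                                size = rung_sizes)),
            class = "ladder_calibration")
}

#' @export
print.ladder_calibration <- function(x, ...) {
  cat(sprintf("<ladder_calibration> position = %.2f %+.2f * log10(bp), %d rungs\n",
              x$intercept, x$slope, nrow(x$rungs)))
  invisible(x)
}

#' @export
tidy.ladder_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "log10_size"),
         estimate = s[, 1], std_error = s[, 2])
}

#' @export
glance.ladder_calibration <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, sigma = s$sigma, n_rungs = nrow(x$rungs))
}

#' @rdname calibrate_ladder
#' @param cal A `ladder_calibration`.
#' @param position Positions (px) to convert to fragment sizes.
#' @export
predict_size <- function(cal, position) {
  10^((position - cal$intercept) / cal$slope)
}

#' @rdname calibrate_ladder
#' @param size Fragment sizes (bp) to convert to positions.
#' @export
predict_position <- function(cal, size) {
  cal$intercept + cal$slope * log10(size)
}

roll_stat <- function(x, window, fun) {
  zoo::rollapply(x, width = window, FUN = fun, partial = TRUE,
                 align = "center")
}

#' Baseline of a 1-D lane profile by morphological opening
#'
#' Moving minimum followed by moving maximum with the same window: removes
#' every peak narrower than `window` while following the smooth lane
#' baseline. A short median prefilter (width `presmooth`) keeps the moving
#' minimum from latching onto downward noise excursions, which would bias
#' the baseline low and inflate integrated band areas.
#'
#' @param intensity Profile intensities.
#' @param window Structuring-element width in samples (odd recommended).
#' @param presmooth Median prefilter width (odd; 1 disables).
#' @return Baseline vector of the same length.
#' @export
profile_baseline <- function(intensity, window, presmooth = 5L) {
  if (window >= length(intensity)) {
    abort("`window` must be smaller than the profile length.")
  }
  sm <- if (presmooth > 1L && length(intensity) > presmooth) {
    stats::runmed(intensity, presmooth, endrule = "median")
  } else intensity
  roll_stat(roll_stat(sm, window, min), window, max)
}

peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- if (p > 1) y[seq_len(p - 1)] else numeric()
    right <- if (p < length(y)) y[(p + 1):length(y)] else numeric()
    lmin <- min_to_higher(rev(left), y[p])
    rmin <- min_to_higher(right, y[p])
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

# lowest point between the peak and the nearest equal-or-higher point
# (or the profile end) on one side
min_to_higher <- function(side, h) {
  if (!length(side)) return(min(h, 0))
  higher <- which(side >= h)
  seg <- if (length(higher)) side[seq_len(higher[1])] else side
  min(seg)
}

#' Detect bands on a 1-D lane profile
#'
#' Subtracts a morphological-opening baseline, finds local maxima, keeps
#' those whose topographic prominence exceeds `min_prominence`, and
#' integrates the baseline-subtracted signal over each band's support. The
#' support runs out to the flanking minima separating the band from its
#' neighbours, but is truncated where the median-smoothed signal returns to
#' the baseline, so the integral does not accumulate noise over band-free
#' stretches of the lane.
#'
#' @param profile Data frame with `position` (strictly increasing) and
#'   `intensity` columns.
#' @param baseline_window Opening window in samples (default 51).
#' @param min_prominence Minimal peak prominence in counts; default 5% of
#'   the baseline-subtracted maximum.
#' @return Tibble of bands: `center` (px), `height`, `prominence`, `area`
#'   (counts x px), `left`, `right` (support bounds, px).
#' @export
detect_bands <- function(profile, baseline_window = 51L,
                         min_prominence = NULL) {
  if (!all(c("position", "intensity") %in% names(profile))) {
    abort("`profile` needs `position` and `intensity` columns.")
  }
  pos <- profile$position; y0 <- profile$intensity
  if (any(diff(pos) <= 0)) abort("`position` must be strictly increasing.")
  if (any(y0 < 0)) abort("intensities must be non-negative.")
  base <- profile_baseline(y0, baseline_window)
  y <- y0 - base
  if (max(y) <= 0) return(empty_bands())
  if (is.null(min_prominence)) min_prominence <- 0.05 * max(y)
  n <- length(y)
  is_peak <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  if (!length(is_peak)) return(empty_bands())
  prom <- peak_prominence(y, is_peak)
  keep <- prom >= min_prominence & y[is_peak] > 0
  pk <- is_peak[keep]; prom <- prom[keep]
  if (!length(pk)) return(empty_bands())
  # outer support boundaries: minimum of y between consecutive kept peaks
  bounds <- integer(length(pk) + 1L)
  bounds[1] <- 1L; bounds[length(pk) + 1L] <- n
  if (length(pk) > 1L) {
    for (i in seq_len(length(pk) - 1L)) {
      seg <- pk[i]:pk[i + 1]
      bounds[i + 1L] <- seg[which.min(y[seg])]
    }
  }
  # smoothed residual used to decide where a band has rejoined the baseline
  y_sm <- if (n > 5L) stats::runmed(y0, 5, endrule = "median") - base else y
  purrr::map(seq_along(pk), function(i) {
    li <- bounds[i]; ri <- bounds[i + 1L]
    p <- pk[i]
    if (li < p) {
      z <- which(y_sm[li:(p - 1L)] <= 0)
      if (length(z)) li <- li + max(z) - 1L
    }
    if (ri > p) {
      z <- which(y_sm[(p + 1L):ri] <= 0)
      if (length(z)) ri <- p + min(z)
    }
    tibble(center = pos[pk[i]], height = y[pk[i]], prominence = prom[i],
           area = pracma::trapz(pos[li:ri], y[li:ri]),
           left = pos[li], right = pos[ri])
  }) |> bind_rows()
}

empty_bands <- function() {
  tibble(center = numeric(), height = numeric(), prominence = numeric(),
         area = numeric(), left = numeric(), right = numeric())
}

#' Assign detected bands to expected amplicons
#'
#' Converts band centres to fragment sizes through the ladder calibration
#' and assigns each band to the nearest expected amplicon within a relative
#' size tolerance; bands matching nothing stay `unassigned`. A missing
#' housekeeping (actin) band is an error, as is a pair of bands competing
#' for the same amplicon.
#'
#' @param bands Band tibble from [detect_bands()].
#' @param cal A [calibrate_ladder()] result.
#' @param expected Named expected sizes, see [expected_sizes()].
#' @param tolerance Relative size tolerance (default 0.10).
#' @return `bands` with `size` (bp) and `assignment` columns.
#' @export
assign_bands <- function(bands, cal, expected = expected_sizes("reporter"),
                         tolerance = 0.10) {
  if (!inherits(cal, "ladder_calibration")) {
    abort("`cal` must come from calibrate_ladder().")
  }
  if (!"actin" %in% names(expected)) {
    abort("`expected` must include an `actin` housekeeping size.")
  }
  bands <- mutate(bands, size = predict_size(cal, .data$center))
  assignment <- rep("unassigned", nrow(bands))
  for (i in seq_len(nrow(bands))) {
    rel <- abs(bands$size[i] - expected) / expected
    j <- which.min(rel)
    if (rel[j] <= tolerance) assignment[i] <- names(expected)[j]
  }
  for (nm in names(expected)) {
    hits <- which(assignment == nm)
    if (length(hits) > 1L) {
      abort(sprintf(
        "bands at %s bp all compete for the %s (%g bp) amplicon",
        paste(round(bands$size[hits]), collapse = ", "), nm, expected[nm]))
    }
  }
  if (!"actin" %in% assignment) {
    abort("missing housekeeping band: no band within tolerance of the actin amplicon.")
  }
  mutate(bands, assignment = assignment)
}

#' Actin-normalised isoform quantification for one lane
#'
#' Normalises the E10+ and E10- band areas by the in-lane Beta-Actin band
#' area and reports the percent exon inclusion
#' `pct_e10plus = E10+ / (E10+ + E10-) * 100`. The actin normalisation
#' cancels within the lane but the normalised levels are retained for
#' cross-lane comparisons such as [fold_change()].
#'
#' @param bands Assigned band tibble from [assign_bands()]; must contain
#'   `e10plus`, `e10minus` and `actin` assignments.
#' @param lane Optional lane identifier carried through.
#' @return One-row tibble: `lane`, `norm_e10plus`, `norm_e10minus`,
#'   `pct_e10plus`.
#' @export
isoform_percent <- function(bands, lane = NA_character_) {
  need <- c("e10plus", "e10minus", "actin")
  missing <- setdiff(need, bands$assignment)
  if (length(missing)) {
    abort(sprintf("lane is missing assigned band(s): %s",
                  paste(missing, collapse = ", ")))
  }
  a <- function(nm) bands$area[bands$assignment == nm]
  actin <- a("actin")
  if (actin <= 0) abort("actin band area is zero; cannot normalise.")
  np <- a("e10plus") / actin
  nm_ <- a("e10minus") / actin
  pct <- if (np + nm_ > 0) 100 * np / (np + nm_) else NA_real_
  tibble(lane = lane, norm_e10plus = np, norm_e10minus = nm_,
         pct_e10plus = pct)
}

#' Fold-change of exon inclusion between two lanes
#'
#' Ratio of actin-normalised E10+ levels, case over reference.
#'
#' @param q_case,q_ref [isoform_percent()] rows.
#' @return A single number.
#' @export
fold_change <- function(q_case, q_ref) {
  if (q_ref$norm_e10plus <= 0) {
    abort("reference lane has zero normalised E10+ level.")
  }
  q_case$norm_e10plus / q_ref$norm_e10plus
}

#' Detect, assign and quantify one lane in a single call
#'
#' @inheritParams detect_bands
#' @inheritParams assign_bands
#' @inheritParams isoform_percent
#' @return As [isoform_percent()].
#' @export
quantify_lane <- function(profile, cal, expected = expected_sizes("reporter"),
                          baseline_window = 51L, min_prominence = NULL,
                          tolerance = 0.10, lane = NA_character_) {
  detect_bands(profile, baseline_window, min_prominence) |>
    assign_bands(cal, expected, tolerance) |>
    isoform_percent(lane = lane)
}

#' Synthesise a gel lane profile with known band areas
#'
#' Places Gaussian bands of specified integrated area at the
#' ladder-calibrated positions of their fragment sizes, on a smooth
#' low-level baseline, with additive Gaussian noise. Used as the
#' desk-scale oracle for the densitometry chain: synthesising then
#' detecting must recover the specified areas.
#'
#' @param band_spec Data frame with `size` (bp, within the calibration
#'   range) and `area` (counts x px) columns.
#' @param cal A [calibrate_ladder()] result.
#' @param noise_sd Noise SD in counts (default 1).
#' @param seed Integer seed; same seed, same profile.
#' @param band_sigma Gaussian band width (px, default 3).
#' @param baseline_level Baseline plateau (counts, default 10).
#' @param step Sampling step along the axis (px, default 1).
#' @return Lane profile tibble (`position`, `intensity`), intensities
#'   floored at zero.
#' @export
synth_gel <- function(band_spec, cal, noise_sd = 1, seed = 1L,
                      band_sigma = 3, baseline_level = 10, step = 1) {
  rng_size <- range(cal$rungs$size)
  if (nrow(band_spec) > 0 &&
      (any(band_spec$size < rng_size[1]) || any(band_spec$size > rng_size[2]))) {
    abort(sprintf("band size outside the calibration range [%g, %g] bp.",
                  rng_size[1], rng_size[2]))
  }
  rng_pos <- range(cal$rungs$position)
  pad <- 6 * band_sigma + 10
  pos <- seq(min(rng_pos) - pad, max(rng_pos) + pad, by = step)
  withr::with_seed(as.integer(seed), {
    y <- baseline_level * (1 + 0.25 * sin(2 * pi * (pos - pos[1]) /
                                            (2 * diff(range(pos)))))
    for (i in seq_len(nrow(band_spec))) {
      mu <- predict_position(cal, band_spec$size[i])
      y <- y + band_spec$area[i] / (band_sigma * sqrt(2 * pi)) *
        exp(-(pos - mu)^2 / (2 * band_sigma^2))
    }
    if (noise_sd > 0) y <- y + rnorm(length(pos), 0, noise_sd)
    tibble(position = pos, intensity = pmax(y, 0))
  })
}
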