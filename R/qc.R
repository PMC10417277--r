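#' Control-population summary for plate QC
#'
#' @param x Numeric readout values, one per replicate well (or a
#'   pre-computed summary via `mu`/`sigma`).
#' @param role `"negative"` or `"positive"`.
#' @param mu,sigma Optionally supply the mean and SD directly instead of
#'   `x`.
#' @return A `control_stats` object with `mu`, `sigma`, `n`, `role`.
#' @export
control_stats <- function(x = NULL, role = c("negative", "positive"),
                          mu = NULL, sigma = NULL) {
  role <- match.arg(role)
  if (is.null(x)) {
    stopifnot_scalar_number(mu, "mu")
    stopifnot_scalar_number(sigma, "sigma", lower = 0)
    n <- NA_integer_
  } else {
    if (!is.numeric(x) || length(x) < 1L) abort("`x` must be numeric.")
    mu <- mean(x)
    sigma <- if (length(x) > 1L) sd(x) else 0
    n <- length(x)
  }
  structure(list(mu = mu, sigma = sigma, n = n, role = role),
            class = "control_stats")
}

#' Z-prime factor of a screening plate
#'
#' The Z' factor summarises how well the negative- and positive-control
#' readout distributions are separated:
#' `SNR = (sigma_neg + sigma_pos) / |mu_neg - mu_pos|` and
#' `Z' = 1 - 3 * SNR`. Its theoretical maximum is 1.0 (noise-free
#' controls); values above ~0.4 are considered sufficient for screening and
#' values above ~0.6 robust. Z' is invariant under affine rescaling of the
#' readout and strictly decreasing in either control SD.
#'
#' @param neg,pos [control_stats()] of the negative and positive control
#'   wells (any object with `mu` and `sigma` works).
#' @return A `qc_result` with `zprime`, `snr` and a `verdict`
#'   (`robust`/`sufficient`/`insufficient`).
#' @examples
#' zprime(control_stats(mu = 100, sigma = 0, role = "negative"),
#'        control_stats(mu = 1000, sigma = 0, role = "positive"))
#' @export
zprime <- function(neg, pos) {
  for (ctl in list(neg, pos)) {
    stopifnot_scalar_number(ctl$mu, "mu")
    stopifnot_scalar_number(ctl$sigma, "sigma", lower = 0)
  }
  sep <- abs(neg$mu - pos$mu)
  if (sep == 0) {
    abort("control means are equal: zero separation, Z' undefined.")
  }
  snr <- (neg$sigma + pos$sigma) / sep
  z <- 1 - 3 * snr
  verdict <- if (z >= 0.6) "robust" else if (z >= 0.4) "sufficient" else
    "insufficient"
  structure(list(zprime = z, snr = snr, verdict = verdict,
                 neg = neg, pos = pos),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> Z' = %.3f (SNR %.3f) - %s\n",
              x$zprime, x$snr, x$verdict))
  invisible(x)
}

#' @export
tidy.qc_result <- function(x, ...) {
  tibble(role = c("negative", "positive"),
         mu = c(x$neg$mu, x$pos$mu),
         sigma = c(x$neg$sigma, x$pos$sigma),
         n = c(x$neg$n %||% NA_integer_, x$pos$n %||% NA_integer_))
}

#' @export
glance.qc_result <- function(x, ...) {
  tibble(zprime = x$zprime, snr = x$snr, verdict = x$verdict)
}

#' Plate QC from well summaries
#'
#' Convenience wrapper: collects a per-well readout (default the per-well
#' mean corrected RFP intensity `mean_corr_r`) over the two control arms and
#' computes [zprime()]. Per-well values are the replicates entering the
#' control statistics. Control arms are selected by `role` by default; pass
#' condition names to compare, e.g., wild-type against mutant reporter
#' wells instead.
#'
#' @param wells Well-summary tibble from [summarize_wells()] (needs `role`
#'   and the readout column).
#' @param readout Name of the readout column (default `"mean_corr_r"`).
#' @param negative,positive Condition names defining the control arms;
#'   default: wells with role `negative_control` / `positive_control`.
#' @return A `qc_result`.
#' @export
plate_qc <- function(wells, readout = "mean_corr_r",
                     negative = NULL, positive = NULL) {
  if (!readout %in% names(wells)) {
    abort(sprintf("readout column `%s` not found in well summaries.", readout))
  }
  pick <- function(cond, role) {
    if (is.null(cond)) wells[[readout]][wells$role == role]
    else wells[[readout]][wells$condition %in% cond]
  }
  neg <- pick(negative, "negative_control")
  pos <- pick(positive, "positive_control")
  if (!length(neg) || !length(pos)) {
    abort("plate_qc needs wells in both control arms (negative/positive).")
  }
  if (anyNA(neg) || anyNA(pos)) abort("control readouts contain NA.")
  zprime(control_stats(neg, "negative"), control_stats(pos, "positive"))
}

#' Welch two-sample t-test on replicate summaries
#'
#' Thin wrapper around [stats::t.test()] (two-sided, unequal variances)
#' returning a tidy one-row tibble. Intended for comparing per-well
#' replicate summaries between two conditions.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return Tibble with `statistic`, `p_value`, `df`, `estimate_a`,
#'   `estimate_b`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("each sample needs at least 2 replicates.")
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(tibble(statistic = 0, p_value = 1, df = NA_real_,
                    estimate_a = mean(sample_a), estimate_b = mean(sample_b)))
    }
    abort("both samples are constant; the t statistic is undefined.")
  }
  ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter),
         estimate_a = mean(sample_a), estimate_b = mean(sample_b))
}

#' Bonferroni multiple-comparison adjustment
#'
#' `min(1, p * m)` for each p-value, with `m` defaulting to the number of
#' comparisons supplied.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (>= `length(pvalues)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  if (m < length(pvalues)) {
    abort("`m` must be at least the number of p-values.")
  }
  p.adjust(pvalues, method = "bonferroni", n = m)
}

#' Dose-response deltas against matched scramble controls
#'
#' For every (condition, dose) pair of treated sample wells, computes the
#' change in the three class percentages relative to scramble-control wells
#' at the same dose: `delta_* = treated - control`, in percentage points.
#' Replicate wells are paired by `replicate` id when both arms have it,
#' otherwise each treated replicate is compared to the control mean. Because
#' the three classes partition the transfected cells, the three deltas sum
#' to ~0 within rounding.
#'
#' @param wells Well-summary tibble from [summarize_wells()] including
#'   `role` (`sample` vs `scramble_control`) and `dose`.
#' @return Tibble per (condition, dose): `n_pairs`, `delta_rfp`,
#'   `delta_gfp`, `delta_dual` (means over pairs) and their SDs.
#' @export
dose_response <- function(wells) {
  treated <- filter(wells, .data$role == "sample", !is.na(.data$dose))
  control <- filter(wells, .data$role == "scramble_control",
                    !is.na(.data$dose))
  if (nrow(treated) == 0L) abort("no treated sample wells with a dose.")
  missing <- setdiff(unique(treated$dose), unique(control$dose))
  if (length(missing)) {
    abort(sprintf("no scramble_control well matched to dose(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ctl <- control |>
    select("dose", "replicate", ctl_rfp = "pct_rfp", ctl_gfp = "pct_gfp",
           ctl_dual = "pct_dual")
  paired <- left_join(treated, ctl, by = c("dose", "replicate"))
  if (anyNA(paired$ctl_rfp)) {
    # fall back to the control mean at that dose
    ctl_mean <- ctl |>
      group_by(.data$dose) |>
      summarise(across(c("ctl_rfp", "ctl_gfp", "ctl_dual"), mean),
                .groups = "drop")
    paired <- treated |> left_join(ctl_mean, by = "dose")
  }
  paired |>
    mutate(d_rfp = .data$pct_rfp - .data$ctl_rfp,
           d_gfp = .data$pct_gfp - .data$ctl_gfp,
           d_dual = .data$pct_dual - .data$ctl_dual) |>
    group_by(.data$condition, .data$dose) |>
    summarise(n_pairs = dplyr::n(),
              delta_rfp = mean(.data$d_rfp), sd_rfp = sd0_or_na(.data$d_rfp),
              delta_gfp = mean(.data$d_gfp), sd_gfp = sd0_or_na(.data$d_gfp),
              delta_dual = mean(.data$d_dual),
              sd_dual = sd0_or_na(.data$d_dual),
              .groups = "drop") |>
    arrange(.data$condition, .data$dose)
}

sd0_or_na <- function(x) if (length(x) > 1L) sd(x) else NA_real_
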