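#' Canonical study-condition layouts for the synthetic assay
#'
#' These builders encode the reference conditions that the package's own
#' validation runs on, mirroring the biology of the two-colour exon 10
#' reporter assay:
#'
#' * `layout_reporter_comparison()` - a wild-type-like reporter condition
#'   (mean exon inclusion 0.35, matching the ~35% E10+ transcript level
#'   measured for the WT reporter) against a splice-switching-mutant-like
#'   condition (mean inclusion 0.85, the ~85% E10+ of the mutant reporter),
#'   plus an untransfected negative-control well for gating.
#' * `layout_bimodal_well()` - one well whose transfected cells are an
#'   equal mixture of a clearly exon-skipping population (mean psi 0.04)
#'   and a clearly exon-including population (mean psi 0.75), used for
#'   classification parameter-recovery checks. The component means are
#'   chosen so both regimes sit cleanly past the K- and J-equivalent psi
#'   thresholds even after unsubtracted cellular autofluorescence pulls
#'   every measured G/R ratio slightly towards 1; the well is plated
#'   sparsely (over more fields) to limit reporter crosstalk between
#'   touching cells.
#' * `layout_dose_titration()` - a scramble-control arm at the mutant-like
#'   inclusion level for every dose, and a treated arm in which the
#'   generator's mean inclusion is knocked down monotonically with dose
#'   (10, 25, 50, 100 nM -> mean psi 0.75, 0.60, 0.45, 0.25), emulating a
#'   dose-dependent silencing of exon-included transcripts.
#'
#' @param n_fields Fields per well.
#' @param cells_per_field Cells per field.
#' @param replicates Replicate wells per arm (dose titration only).
#' @return A [plate_layout()].
#' @name demo_layouts
NULL

untransfected_condition <- function(cells_per_field = 90L) {
  condition_spec("untransfected", cells_per_field = cells_per_field,
                 transfection_rate = 0, role = "negative_control")
}

#' @rdname demo_layouts
#' @export
layout_reporter_comparison <- function(n_fields = 4L, cells_per_field = 90L) {
  plate_layout(
    wells = tibble(well = c("A1", "A2", "A3"),
                   condition = c("wt", "mut", "untransfected")),
    conditions = list(
      wt = condition_spec("wt", cells_per_field = cells_per_field,
                          inclusion_mean = 0.35),
      mut = condition_spec("mut", cells_per_field = cells_per_field,
                           inclusion_mean = 0.85,
                           role = "positive_control"),
      untransfected = untransfected_condition(cells_per_field)),
    min_fields = n_fields)
}

#' @rdname demo_layouts
#' @export
layout_bimodal_well <- function(n_fields = 44L, cells_per_field = 55L) {
  plate_layout(
    wells = tibble(well = c("B1", "B2"),
                   condition = c("bimodal", "untransfected")),
    conditions = list(
      bimodal = condition_spec("bimodal", cells_per_field = cells_per_field,
                               transfection_rate = 0.85,
                               inclusion_mean = c(0.04, 0.75),
                               inclusion_concentration = 60,
                               inclusion_weights = c(0.5, 0.5)),
      untransfected = untransfected_condition(cells_per_field)),
    min_fields = n_fields)
}

DOSE_LEVELS <- c(10, 25, 50, 100)
KNOCKDOWN_MEANS <- c(0.75, 0.60, 0.45, 0.25)

#' @rdname demo_layouts
#' @export
layout_dose_titration <- function(n_fields = 3L, cells_per_field = 90L,
                                  replicates = 2L) {
  conds <- list(untransfected = untransfected_condition(cells_per_field),
                scramble = condition_spec(
                  "scramble", cells_per_field = cells_per_field,
                  inclusion_mean = 0.85, role = "scramble_control"))
  wells <- list(tibble(well = "N1", condition = "untransfected",
                       dose = NA_real_, replicate = 1L))
  for (i in seq_along(DOSE_LEVELS)) {
    nm <- sprintf("sirna_%dnM", DOSE_LEVELS[i])
    conds[[nm]] <- condition_spec(nm, cells_per_field = cells_per_field,
                                  inclusion_mean = KNOCKDOWN_MEANS[i],
                                  inclusion_concentration = 6,
                                  role = "sample")
    for (r in seq_len(replicates)) {
      wells[[length(wells) + 1L]] <-
        tibble(well = sprintf("T%d_%d", i, r), condition = nm,
               dose = DOSE_LEVELS[i], replicate = r)
      wells[[length(wells) + 1L]] <-
        tibble(well = sprintf("S%d_%d", i, r), condition = "scramble",
               dose = DOSE_LEVELS[i], replicate = r)
    }
  }
  plate_layout(bind_rows(wells), conds, min_fields = n_fields)
}
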