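VALID_ROLES <- c("sample", "negative_control", "positive_control",
                 "scramble_control")

#' Define a plate layout
#'
#' Maps wells to experimental conditions and control roles, carries the
#' optional siRNA dose (nM) and replicate id per well, and bundles the
#' [condition_spec()] objects referenced by the wells. At least 12 fields per
#' well are imaged by default, the usual minimum to score enough objects per
#' condition.
#'
#' @param wells Data frame with columns `well`, `condition` and optionally
#'   `role`, `dose` (nM), `replicate`. A missing `role` is inherited from the
#'   condition's own role.
#' @param conditions Named list of [condition_spec()]s covering every
#'   condition named in `wells`.
#' @param min_fields Fields imaged per well (default 12).
#' @param channels Channel names, in acquisition order.
#' @return A `plate_layout` object.
#' @export
plate_layout <- function(wells, conditions, min_fields = 12L,
                         channels = c("hoechst", "gfp", "rfp")) {
  wells <- as_tibble(wells)
  if (!all(c("well", "condition") %in% names(wells))) {
    abort("`wells` needs at least `well` and `condition` columns.")
  }
  if (anyDuplicated(wells$well)) {
    dup <- unique(wells$well[duplicated(wells$well)])
    abort(sprintf("duplicate well id(s): %s", paste(dup, collapse = ", ")))
  }
  if (!is.list(conditions) || is.null(names(conditions)) ||
      !all(vapply(conditions, inherits, logical(1), "condition_spec"))) {
    abort("`conditions` must be a named list of condition_spec objects.")
  }
  missing_cond <- setdiff(unique(wells$condition), names(conditions))
  if (length(missing_cond)) {
    abort(sprintf("condition(s) not defined: %s",
                  paste(missing_cond, collapse = ", ")))
  }
  if (!"role" %in% names(wells)) wells$role <- NA_character_
  inherit <- is.na(wells$role)
  wells$role[inherit] <-
    vapply(conditions[wells$condition[inherit]], `[[`, character(1), "role")
  bad_role <- setdiff(unique(wells$role), VALID_ROLES)
  if (length(bad_role)) {
    abort(sprintf("unknown role(s): %s (valid: %s)",
                  paste(bad_role, collapse = ", "),
                  paste(VALID_ROLES, collapse = ", ")))
  }
  if (!"dose" %in% names(wells)) wells$dose <- NA_real_
  wells$dose <- vapply(wells$dose, parse_dose, numeric(1))
  if (any(wells$dose < 0, na.rm = TRUE)) abort("doses must be non-negative.")
  if (!"replicate" %in% names(wells)) wells$replicate <- 1L
  stopifnot_scalar_number(min_fields, "min_fields", lower = 1)
  structure(list(wells = select(wells, "well", "condition", "role", "dose",
                                "replicate"),
                 conditions = conditions,
                 min_fields = as.integer(min_fields),
                 channels = channels),
            class = "plate_layout")
}

# Accepts 100, "100", or "100 nM"; NA stays NA.
parse_dose <- function(x) {
  if (is.na(x) || identical(x, "")) return(NA_real_)
  if (is.numeric(x)) return(as.double(x))
  m <- regmatches(x, regexec("^\\s*([0-9.]+)\\s*(nM)?\\s*$", x))[[1]]
  if (length(m) < 2 || m[2] == "") {
    abort(sprintf("cannot parse dose %s (expected a number, optionally 'nM')",
                  deparse(x)))
  }
  as.double(m[2])
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d wells, %d conditions, %d fields/well\n",
              nrow(x$wells), length(x$conditions), x$min_fields))
  print(x$wells, ...)
  invisible(x)
}

condition_to_list <- function(spec) {
  spec[c("cells_per_field", "transfection_rate", "inclusion_mean",
         "inclusion_concentration", "inclusion_weights",
         "expression_log_mean", "expression_log_sd", "role")]
}

#' Parse a plate-layout configuration
#'
#' Reads the YAML layout format: a `conditions` map (each entry holds
#' [condition_spec()] fields) and a `wells` map from well id to
#' `{condition, role, dose, replicate}`, plus optional globals `min_fields`
#' and `channels`. Doses may be written with their unit (`"100 nM"`).
#' Schema violations (duplicate wells, unknown roles, wells referencing
#' undefined conditions) fail with the offending entry named.
#'
#' @param text YAML text, or a path to a YAML file.
#' @return A [plate_layout()].
#' @seealso [format_layout()] for the inverse; parse -> format -> parse is
#'   the identity.
#' @export
parse_layout <- function(text) {
  doc <- tryCatch({
    if (length(text) == 1L && file.exists(text)) {
      yaml::read_yaml(text)
    } else {
      yaml::yaml.load(paste(text, collapse = "\n"))
    }
  }, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("Duplicate map key", msg)) {
      abort(paste("duplicate well or condition id in layout config:", msg))
    }
    abort(paste("malformed layout config:", msg))
  })
  if (!is.list(doc) || is.null(doc$wells) || is.null(doc$conditions)) {
    abort("layout config must have `conditions` and `wells` sections.")
  }
  conds <- purrr::imap(doc$conditions, function(cf, nm) {
    do.call(condition_spec, c(list(name = nm), cf))
  })
  well_ids <- names(doc$wells)
  if (anyDuplicated(well_ids)) {
    abort(sprintf("duplicate well id(s): %s",
                  paste(unique(well_ids[duplicated(well_ids)]), collapse = ", ")))
  }
  wells <- purrr::imap(doc$wells, function(wf, id) {
    if (is.character(wf) && length(wf) == 1L) wf <- list(condition = wf)
    if (is.null(wf$condition)) {
      abort(sprintf("well %s: missing `condition`", id))
    }
    tibble(well = id, condition = wf$condition,
           role = wf$role %||% NA_character_,
           dose = parse_dose(wf$dose %||% NA),
           replicate = as.integer(wf$replicate %||% 1L))
  }) |> bind_rows()
  plate_layout(wells, conds,
               min_fields = doc$min_fields %||% 12L,
               channels = unlist(doc$channels %||%
                                   c("hoechst", "gfp", "rfp")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a plate layout back to YAML text
#'
#' @param layout A [plate_layout()].
#' @return A single YAML string; `parse_layout(format_layout(x))` reproduces
#'   `x`.
#' @export
format_layout <- function(layout) {
  if (!inherits(layout, "plate_layout")) abort("`layout` must be a plate_layout.")
  wells <- purrr::pmap(layout$wells, function(well, condition, role, dose,
                                              replicate) {
    out <- list(condition = condition, role = role, replicate = replicate)
    if (!is.na(dose)) out$dose <- dose
    out
  })
  names(wells) <- layout$wells$well
  yaml::as.yaml(list(
    min_fields = layout$min_fields,
    channels = as.list(layout$channels),
    conditions = purrr::map(layout$conditions, condition_to_list),
    wells = wells))
}

#' @rdname format_layout
#' @param path File to write.
#' @export
write_layout <- function(layout, path) {
  writeLines(format_layout(layout), path)
  invisible(path)
}
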