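# Internal helpers shared across modules.

# Deterministic child seed derivation: keeps every stochastic sub-step
# reproducible from one user-facing seed while decoupling the streams of
# different wells/fields. Stays strictly below 2^31 - 1.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Matrices are stored row = y (image row), col = x; coordinates reported
# 0-based at pixel centres.
as_image_matrix <- function(img, arg = "img") {
  if (is.list(img) || is.null(dim(img)) || length(dim(img)) != 2L) {
    abort(sprintf("`%s` must be a 2-D single-channel image matrix.", arg))
  }
  storage.mode(img) <- "double"
  img
}
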