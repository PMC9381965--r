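# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive per-subject child seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_hod <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hodasym_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_modality <- function(modality, allowed = MODALITIES) {
  if (length(modality) != 1L || !modality %in% allowed) {
    stop_hod(
      sprintf(
        "modality must be one of %s (got '%s')",
        paste(allowed, collapse = ", "), paste(modality, collapse = ",")
      ),
      "hod_invalid_modality"
    )
  }
  modality
}

assert_side <- function(side) {
  if (length(side) != 1L || !side %in% SIDES) {
    stop_hod(sprintf("side must be one of %s", paste(SIDES, collapse = ", ")),
             "hod_invalid_side")
  }
  side
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
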