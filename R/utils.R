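# Internal helpers: typed conditions and seeded evaluation.

vfc_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "voxelfc_error")))
}

vfc_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "voxelfc_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded stages do not perturb the global stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
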