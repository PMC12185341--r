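# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so package functions never clobber user RNG flow.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, min = -Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s.", name, format(min)))
  if (integer && x != round(x)) abort(sprintf("`%s` must be an integer.", name))
  invisible(x)
}

check_matrix_image <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (any(!is.finite(image))) abort(sprintf("`%s` must be finite.", name))
  invisible(image)
}

# Sample skewness (adjusted Fisher-Pearson via e1071, type 3 default).
sample_skewness <- function(x) {
  if (length(unique(x)) < 2L) return(0)
  e1071::skewness(x)
}
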