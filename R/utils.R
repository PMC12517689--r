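#' @keywords internal
"_PACKAGE"

## Run `code` under a temporary RNG state seeded with `seed`; restores the
## caller's stream afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## derive a reproducible child seed from a master seed; keeps values < 2^31
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_invalid(what, " must be a square matrix")
  }
  invisible(m)
}
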