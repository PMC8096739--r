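# Internal helpers: reproducible seed handling and small checks.

#' Derive a child seed from a parent seed and a key
#'
#' All randomness in the package flows from a single user-supplied integer
#' seed. Independent components (runs, subjects, regions, noise draws) use
#' child seeds derived deterministically from the parent seed and a string
#' key, so that e.g. run 2 of an experiment is reproducible in isolation.
#' The derivation is a Lehmer-style integer hash modulo 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param ... character or numeric key components, concatenated with "/".
#' @return an integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  x <- (abs(as.numeric(seed)) + 1) %% 2147483647
  for (ch in utf8ToInt(key)) x <- (x * 48271 + ch) %% 2147483647
  as.integer(x %% 2147483645 + 1)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; restores the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  invisible(x)
}
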