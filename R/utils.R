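#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps generator functions deterministic
# without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

stop_mf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
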