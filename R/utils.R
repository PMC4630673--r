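# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a root seed and a stage name
#'
#' All randomness in the package flows from one root seed; each generator or
#' pipeline stage draws from its own substream, keyed by name, so that adding
#' or re-running one stage never perturbs the random numbers of another.
#'
#' @param seed Integer root seed.
#' @param name Character stage name (e.g. `"growth"`, `"sweep:BEM3"`).
#' @return An integer seed in `[0, 2^31 - 1]`, deterministic in `(seed, name)`.
#' @export
#' @examples
#' substream_seed(1, "growth")
#' substream_seed(1, "growth") == substream_seed(1L, "growth")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps the result a valid 32-bit R integer
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(name)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Stop unless all values are finite, positive numbers.
check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("all ", what, " must be finite and > 0"))
  }
  invisible(x)
}
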