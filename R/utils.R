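# classed error helper so tests can assert on failure modes
it_stop <- function(msg, class) {
  stop(structure(class = c(class, "inserttol_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded generators are pure functions of their arguments.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# derive a distinct sub-seed from a base seed, staying within 32-bit range
subseed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    it_stop(sprintf("'%s' must be a single finite number", name),
            "invalid_config")
  }
}
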