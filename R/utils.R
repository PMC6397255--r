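# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream. A `NULL` seed leaves the stream alone.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar checks used in preconditions
stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonneg = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Stage-level substreams: each pipeline stage draws its own seed
#' deterministically from the run seed, keeping stages independent. The
#' result stays below 2^31 - 1.
#'
#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 48271 + as.integer(offset)) %% 2147483587L
}
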