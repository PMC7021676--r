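#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state so seeded helpers do not perturb user sessions.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' One master seed reproduces the whole pipeline; each stage gets its own
#' stream via a fixed affine map kept below 2^31.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (>= 0).
#' @return integer seed.
#' @export
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(offset)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
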