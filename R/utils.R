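#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local random-number stream
#'
#' Seeds the generator with `seed`, evaluates `expr`, then restores the
#' caller's `.Random.seed`, so seeded package functions never disturb the
#' global random stream.
#'
#' @param seed Single integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from one master seed
#'
#' Deterministic fan-out of one user seed into per-stage substreams, so
#' pipeline stages can be re-run in isolation reproducibly. The result is
#' kept below 2^31 - 1, always a valid R integer.
#'
#' @param seed Master integer seed.
#' @param stage Character label of the stage or replicate.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going away from zero, the
#' convention of printed morphometric tables (base `round()` rounds half to
#' even, which disagrees with printed values such as 6.1/4 = 1.53).
#'
#' @param x Numeric vector.
#' @param digits Number of decimals.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_if_not_phylo <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("'tree' must be a \"phylo\" object (see parse_newick)", call. = FALSE)
  invisible(tree)
}
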