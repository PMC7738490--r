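#' Brownian-motion log-likelihood of a single trait on a tree
#'
#' Evaluates the multivariate-normal log-likelihood of tip values `x` under
#' Brownian motion with root state `a` and rate `sigma2`:
#' \deqn{\log L = -\tfrac12\left[n\log(2\pi) + \log|\sigma^2 C| +
#'   (x - a\mathbf 1)^\top(\sigma^2 C)^{-1}(x - a\mathbf 1)\right]}
#' where `C` is the phylogenetic covariance matrix of the tree.
#'
#' @param tree A `"phylo"` object.
#' @param x Named (or tip-ordered) numeric vector of tip values.
#' @param a Root (ancestral) state.
#' @param sigma2 Brownian rate, > 0, in squared trait units per unit branch
#'   length.
#' @return The log-likelihood (a single number).
#' @export
bm_loglik <- function(tree, x, a, sigma2) {
  stop_if_not_phylo(tree)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  x <- align_tip_values(tree, x)
  n <- length(x)
  C <- vcv_matrix(tree)
  L <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance matrix is singular", call. = FALSE))
  z <- backsolve(L, x - a, transpose = TRUE)
  logdetC <- 2 * sum(log(diag(L)))
  -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetC + sum(z^2) / sigma2)
}

#' Maximum-likelihood Brownian-motion fit of a single trait
#'
#' Closed-form generalized-least-squares estimates: root state
#' `a = (1'C^-1 x)/(1'C^-1 1)` and rate `sigma2 = (x-a)'C^-1(x-a)/n`
#' (the ML, not REML, divisor). A constant trait gives `sigma2 = 0`; such a
#' fit is flagged `degenerate` and its log-likelihood reported as `NA`,
#' and downstream placement treats the character as uninformative.
#'
#' @inheritParams bm_loglik
#' @return An object of class `"bm_fit"`: list with `a`, `sigma2`, `logLik`,
#'   `n`, `degenerate`.
#' @examples
#' tr <- parse_newick("(A:1,B:1,C:1);")
#' bm_mle(tr, c(A = 0, B = 1, C = 2)) # a = 1, sigma2 = 2/3
#' @export
bm_mle <- function(tree, x) {
  stop_if_not_phylo(tree)
  x <- align_tip_values(tree, x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 tips")
  C <- vcv_matrix(tree)
  L <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance matrix is singular", call. = FALSE))
  zx <- backsolve(L, x, transpose = TRUE)
  z1 <- backsolve(L, rep(1, n), transpose = TRUE)
  a <- sum(z1 * zx) / sum(z1^2)
  q <- sum((zx - a * z1)^2)
  sigma2 <- q / n
  # relative degeneracy check: residual variation at rounding-noise level
  degenerate <- sigma2 <= 1e-20 * max(mean(x^2), 1)
  if (degenerate) sigma2 <- 0
  logdetC <- 2 * sum(log(diag(L)))
  ll <- if (degenerate) NA_real_ else
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetC + n)
  structure(list(a = a, sigma2 = sigma2, logLik = ll, n = n,
                 degenerate = degenerate), class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("Brownian-motion ML fit\n")
  cat(sprintf("  root state a : %.6g\n", x$a))
  cat(sprintf("  rate sigma^2 : %.6g%s\n", x$sigma2,
              if (x$degenerate) " (degenerate: constant trait)" else ""))
  cat(sprintf("  log-likelihood: %.6g  (n = %d tips)\n", x$logLik, x$n))
  invisible(x)
}

# Match a value vector to the tree's tips; names are authoritative when
# present, otherwise positional order is assumed.
align_tip_values <- function(tree, x) {
  tips <- tree$tip.label
  if (!is.null(names(x))) {
    miss <- setdiff(tips, names(x))
    if (length(miss))
      stop("no trait value for tip(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- x[tips]
  } else if (length(x) != length(tips)) {
    stop("length of 'x' does not match the number of tips", call. = FALSE)
  }
  if (anyNA(x)) stop("missing trait values are not allowed here",
                     call. = FALSE)
  as.numeric(x)
}
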