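#' Phylogenetic principal component analysis
#'
#' Estimates the evolutionary (Brownian-motion) trait covariance by
#' generalized least squares,
#' \deqn{R = (X - \mathbf 1\hat a^\top)^\top C^{-1}
#'           (X - \mathbf 1\hat a^\top) / (n - 1),}
#' with `a_hat` the GLS root mean vector, then eigen-decomposes `R`
#' (covariance mode). Scores are the centered data projected on the
#' eigenvectors: `S = (X - 1 a_hat') V`. On a star tree with unit branch
#' lengths `C = I` and the analysis reduces to ordinary PCA on centered
#' data. Eigenvector signs are fixed by making each column's
#' largest-magnitude entry positive.
#'
#' @param tree A `"phylo"` object whose tips are the specimens; if the tree
#'   has tips absent from `X` they are pruned first.
#' @param X Numeric matrix or data frame, specimens as rownames, one column
#'   per continuous trait; no missing values.
#' @return An object of class `"phylo_pca"`: list with `mean` (GLS root
#'   mean), `R` (evolutionary covariance), `values` (eigenvalues,
#'   descending), `vectors` (orthonormal columns), `scores`
#'   (specimens x components), and `tree`.
#' @export
phylo_pca <- function(tree, X) {
  stop_if_not_phylo(tree)
  X <- as_trait_matrix(X)
  if (anyNA(X)) stop("missing trait values are not allowed in phylo_pca",
                     call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 specimens")
  extra <- setdiff(tree$tip.label, rownames(X))
  if (length(extra)) {
    if (length(tree$tip.label) - length(extra) < 3L)
      stop("fewer than 3 tree tips have trait data", call. = FALSE)
    tree <- ape::drop.tip(tree, extra)
  }
  miss <- setdiff(rownames(X), tree$tip.label)
  if (length(miss))
    stop("specimen(s) not in tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  C <- vcv_matrix(tree)
  L <- chol(C)
  Zx <- backsolve(L, X, transpose = TRUE)
  z1 <- backsolve(L, rep(1, n), transpose = TRUE)
  a <- drop(crossprod(z1, Zx)) / sum(z1^2)
  names(a) <- colnames(X)
  Xc <- sweep(X, 2L, a)
  Zc <- backsolve(L, Xc, transpose = TRUE)
  R <- crossprod(Zc) / (n - 1)
  dimnames(R) <- list(colnames(X), colnames(X))
  eg <- eigen(R, symmetric = TRUE)
  V <- eg$vectors
  # deterministic sign: largest-|entry| of each column positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- Xc %*% V
  structure(list(mean = a, R = R, values = pmax(eg$values, 0),
                 vectors = V, scores = scores, tree = tree),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat("Phylogenetic PCA (covariance mode)\n")
  cat(sprintf("  %d specimens, %d traits\n", nrow(x$scores), ncol(x$R)))
  pv <- x$values / sum(x$values) * 100
  cat("  eigenvalues: ", paste(sprintf("%.4g", x$values), collapse = ", "),
      "\n", sep = "")
  cat("  % variance : ", paste(sprintf("%.1f", pv), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Project a query specimen onto phylogenetic principal components
#'
#' Centers the query's trait vector with the tree-taxa GLS root mean and
#' projects it on the stored eigenvectors; the query never contributes to
#' the covariance structure, so no placement is needed beforehand.
#'
#' @param ppca A `"phylo_pca"` object.
#' @param q Named numeric vector of trait values over the same traits.
#' @return Numeric score vector, one entry per component.
#' @export
project_query <- function(ppca, q) {
  stopifnot(inherits(ppca, "phylo_pca"))
  traits <- rownames(ppca$vectors)
  if (!is.null(names(q))) {
    miss <- setdiff(traits, names(q))
    if (length(miss))
      stop("query is missing trait(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    q <- q[traits]
  } else if (length(q) != length(traits)) {
    stop("query length does not match the number of traits", call. = FALSE)
  }
  if (anyNA(q)) stop("query has missing trait values", call. = FALSE)
  drop((as.numeric(q) - ppca$mean) %*% ppca$vectors)
}
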