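#' Brute-force reference placement by dense grid search
#'
#' Independent, deliberately slow reference for [place_taxon()]: the query
#' is scored on a dense height grid along every edge, rebuilding the full
#' augmented phylogenetic covariance matrix and its Cholesky factor from
#' scratch at every candidate position instead of using the incremental
#' update the fast engine relies on. Intended for verification; cost grows
#' as `n_grid` times the number of edges times a full `(N+1)^3` Cholesky.
#'
#' @inheritParams place_taxon
#' @param n_grid Number of grid heights per edge (default 500).
#' @return List with `edge`, `height`, `pendant`, `logLik`, and `per_edge`
#'   (the per-edge maxima over the grid, in edge-index order).
#' @export
place_taxon_brute <- function(tree, X, q, n_grid = 500L,
                              contemporaneous = TRUE) {
  stop_if_not_phylo(tree)
  X <- as_trait_matrix(X)
  ppca <- phylo_pca(tree, X[tree$tip.label, , drop = FALSE])
  keep <- ppca$values > 1e-12 * max(ppca$values, 1e-300)
  S <- ppca$scores[, keep, drop = FALSE]
  sq <- project_query(ppca, q)[keep]
  tree <- ape::reorder.phylo(tree, "cladewise")
  C <- vcv_matrix(tree)
  S <- S[tree$tip.label, , drop = FALSE]
  et <- edges_table(tree)
  n <- nrow(C)
  m <- ncol(S)
  Th <- max(node_heights(tree)[seq_len(n)])
  tol <- 1e-8 * Th
  desc <- descendant_tip_sets(tree)
  Caug <- matrix(0, n + 1L, n + 1L)
  Caug[seq_len(n), seq_len(n)] <- C
  y <- rbind(S, sq)
  one <- rep(1, n + 1L)
  best_ll <- -Inf
  best_edge <- NA_integer_
  best_h <- NA_real_
  per_edge <- numeric(nrow(et))
  for (e in seq_len(nrow(et))) {
    below <- desc[[et$child[e]]]
    s0 <- C[, below[1L]]
    lo <- min(et$parent_height[e] + tol, et$child_height[e])
    hi <- max(et$child_height[e] - tol, lo)
    hs <- seq(lo, hi, length.out = n_grid)
    e_best <- -Inf
    for (h in hs) {
      cv <- s0
      cv[below] <- h
      Caug[n + 1L, seq_len(n)] <- cv
      Caug[seq_len(n), n + 1L] <- cv
      Caug[n + 1L, n + 1L] <- if (contemporaneous) Th else h
      U <- try(chol(Caug), silent = TRUE)
      if (inherits(U, "try-error")) next
      Z <- backsolve(U, y, transpose = TRUE)
      u1 <- backsolve(U, one, transpose = TRUE)
      ll <- 0
      for (j in seq_len(m)) {
        a <- sum(u1 * Z[, j]) / sum(u1^2)
        s2 <- sum((Z[, j] - a * u1)^2) / (n + 1L)
        if (s2 <= 0) {
          ll <- -Inf
          break
        }
        ll <- ll - 0.5 * ((n + 1L) * log(2 * pi) + (n + 1L) * log(s2) +
                            2 * sum(log(diag(U))) + (n + 1L))
      }
      if (ll > e_best) e_best <- ll
      if (ll > best_ll) {
        best_ll <- ll
        best_edge <- e
        best_h <- h
      }
    }
    per_edge[e] <- e_best
  }
  list(edge = best_edge, height = best_h,
       pendant = if (contemporaneous) Th - best_h else NA_real_,
       logLik = best_ll, per_edge = per_edge)
}
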