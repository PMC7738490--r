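# ---- internal likelihood engine -------------------------------------------
#
# Attaching a query at height h on a fixed edge augments the phylogenetic
# covariance C by one row/column: cov(query, tip i) = h for tips below the
# edge's child and the (h-independent) shared height otherwise, and
# var(query) = h + v. Given the Cholesky factor of the base C, the factor of
# the augmented matrix needs one triangular solve per edge (batched below),
# after which the profile log-likelihood at any (h, v) is scalar arithmetic
# in a handful of precomputed quantities, for all per-component BM fits at
# once. The height search is therefore vectorized over all candidate edges
# and heights simultaneously.

placement_prep <- function(tree, scores) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  S <- as.matrix(scores)[tree$tip.label, , drop = FALSE]
  C <- vcv_matrix(tree)
  U <- chol(C)                       # C = U'U ; lower factor is t(U)
  Z <- backsolve(U, S, transpose = TRUE)
  u1 <- backsolve(U, rep(1, n), transpose = TRUE)
  dts <- descendant_tip_sets(tree)
  et <- edges_table(tree)
  ne <- nrow(et)
  S0 <- matrix(0, n, ne)
  D <- matrix(0, n, ne)
  for (e in seq_len(ne)) {
    below <- dts[[et$child[e]]]
    D[below, e] <- 1
    s0 <- C[, below[1L]]
    s0[below] <- 0
    S0[, e] <- s0
  }
  W <- backsolve(U, cbind(S0, D), transpose = TRUE)
  W0 <- W[, seq_len(ne), drop = FALSE]
  Wd <- W[, ne + seq_len(ne), drop = FALSE]
  list(tree = tree, n = n, m = ncol(S),
       T = max(node_heights(tree)[seq_len(n)]),
       ZZ = colSums(Z^2), UZ = drop(crossprod(u1, Z)), UU = sum(u1^2),
       logdetC = 2 * sum(log(diag(U))),
       w00 = colSums(W0^2), w0d = colSums(W0 * Wd), wdd = colSums(Wd^2),
       w0U = drop(crossprod(W0, u1)), wdU = drop(crossprod(Wd, u1)),
       w0Z = crossprod(W0, Z), wdZ = crossprod(Wd, Z),
       et = et)
}

# Profile log-likelihood for edges `idx` (a vector of edge indices), heights
# H and pendant lengths V (matrices with one row per element of idx, or
# vectors/scalars recycled along columns). Returns a matrix shaped like H.
profile_loglik <- function(prep, idx, H, V, sq) {
  H <- as.matrix(H)
  np1 <- prep$n + 1
  m <- prep$m
  l2 <- (H + V) - (prep$w00[idx] + 2 * H * prep$w0d[idx] +
                     H * H * prep$wdd[idx])
  bad <- l2 <= 0
  l2[bad] <- 1
  sl <- sqrt(l2)
  un <- (1 - (prep$w0U[idx] + H * prep$wdU[idx])) / sl
  uu <- prep$UU + un * un
  sumlogQ <- 0
  for (j in seq_len(m)) {
    zn <- (sq[j] - (prep$w0Z[idx, j] + H * prep$wdZ[idx, j])) / sl
    Q <- (prep$ZZ[j] + zn * zn) - (prep$UZ[j] + un * zn)^2 / uu
    Q[Q <= 1e-300] <- NA
    sumlogQ <- sumlogQ + log(Q / np1)
  }
  ll <- -0.5 * (m * np1 * (log(2 * pi) + 1) + np1 * sumlogQ +
                  m * (prep$logdetC + log(l2)))
  ll[bad | is.na(ll)] <- -Inf
  ll
}

# Contemporaneous per-edge height optimization: a bracketing grid of
# `n_grid` heights per edge, refined by repeatedly zooming the grid into the
# two cells around the incumbent until the interval is below `tol`.
optimize_edges_contemporaneous <- function(prep, idx, sq, n_grid, tol) {
  k <- length(idx)
  lo <- pmin(prep$et$parent_height[idx] + tol,
             prep$et$child_height[idx])
  hi <- pmax(prep$et$child_height[idx] - tol, lo)
  rowseq <- function(a, b) {
    t(mapply(function(x, y) seq(x, y, length.out = n_grid), a, b))
  }
  H <- rowseq(lo, hi)
  if (k == 1L) H <- matrix(H, 1L)
  width <- hi - lo
  n_zoom <- max(1L, ceiling(log(max(width / max(tol, 1e-300), 1)) /
                              log((n_grid - 1) / 2)))
  for (it in seq_len(n_zoom + 1L)) {
    ll <- profile_loglik(prep, idx, H, prep$T - H, sq)
    b <- max.col(ll, ties.method = "first")
    if (it > n_zoom) break
    i1 <- pmax(b - 1L, 1L); i2 <- pmin(b + 1L, n_grid)
    a2 <- H[cbind(seq_len(k), i1)]
    b2 <- H[cbind(seq_len(k), i2)]
    H <- rowseq(a2, b2)
    if (k == 1L) H <- matrix(H, 1L)
  }
  hbest <- H[cbind(seq_len(k), b)]
  data.frame(edge = idx, height = hbest, pendant = prep$T - hbest,
             logLik = ll[cbind(seq_len(k), b)])
}

# Joint (height, pendant) optimization for the non-contemporaneous case.
optimize_edges_free <- function(prep, idx, sq, n_grid, tol) {
  T <- prep$T
  out <- lapply(idx, function(e) {
    lo <- min(prep$et$parent_height[e] + tol, prep$et$child_height[e])
    hi <- max(prep$et$child_height[e] - tol, lo)
    obj <- function(p) -profile_loglik(prep, e, p[1L], p[2L], sq)[1L]
    best <- c(NA, NA, -Inf)
    for (v0 in c(0.05, 0.5, 1) * T) {
      for (h0 in seq(lo, hi, length.out = 5L)) {
        o <- tryCatch(
          stats::optim(c(h0, v0), obj, method = "L-BFGS-B",
                       lower = c(lo, 0), upper = c(hi, 5 * T)),
          error = function(e) NULL)
        if (!is.null(o) && -o$value > best[3L]) best <- c(o$par, -o$value)
      }
    }
    data.frame(edge = e, height = best[1L], pendant = best[2L],
               logLik = best[3L])
  })
  do.call(rbind, out)
}

# Admissible attachment edges under a clade constraint: the edges of the
# minimal subtree spanning the constraint tips (all edges when NULL).
admissible_edges <- function(tree, constraint) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ne <- nrow(tree$edge)
  if (is.null(constraint)) return(seq_len(ne))
  tips <- match(constraint, tree$tip.label)
  if (anyNA(tips))
    stop("constraint tip(s) not in tree: ",
         paste(constraint[is.na(tips)], collapse = ", "), call. = FALSE)
  if (length(tips) == 1L) return(which(tree$edge[, 2L] == tips))
  dts <- descendant_tip_sets(tree)
  keep <- vapply(seq_len(ne), function(e) {
    D <- dts[[tree$edge[e, 2L]]]
    any(tips %in% D) && !all(tips %in% D)
  }, logical(1))
  which(keep)
}

# ---- public API ------------------------------------------------------------

#' Maximum-likelihood placement of a trait-only query taxon
#'
#' Places a specimen known only from continuous morphological traits onto a
#' molecular (typically ultrametric) tree. The tip data are first reduced by
#' phylogenetic PCA; the query is projected on the same components; then
#' every admissible branch is scored by the profile maximum of the summed
#' per-component Brownian-motion log-likelihoods of the enlarged
#' (N+1)-taxon tree, the attachment height being optimized along each edge
#' (bracketing grid with iterative refinement to `1e-8` of tree height).
#' Per-component root states and rates are re-estimated at every candidate
#' position. In contemporaneous mode (the default, for extant specimens on
#' ultrametric trees) the pendant branch always reaches the present; with
#' `contemporaneous = FALSE` the pendant length is optimized jointly.
#'
#' @param tree A `"phylo"` object (warned about if not ultrametric while
#'   `contemporaneous = TRUE`); at least 3 tips.
#' @param X Trait matrix covering every tip (see [as_trait_matrix()]).
#' @param q Named numeric vector: the query specimen's trait values.
#' @param constraint Optional character vector of tip labels; attachment is
#'   restricted to the edges of their spanning subtree.
#' @param contemporaneous Logical; see Details above.
#' @param label Tip label given to the placed query.
#' @param n_grid Bracketing grid size per edge.
#' @param details If `FALSE`, skip building the placed tree and the
#'   per-component rate estimates (used in tight simulation loops).
#' @return An object of class `"placement"`: list with `edge` (attachment
#'   edge index as in [edges_table()]), `height`, `pendant`, `logLik`,
#'   `rates` (per retained component), `edge_table` (per-edge optima,
#'   ranked), `tie` (`TRUE` when the optimum was tied and broken to the
#'   lowest edge index), `placed_tree`, `ppca`, `query` label.
#' @export
place_taxon <- function(tree, X, q, constraint = NULL,
                        contemporaneous = TRUE, label = "query",
                        n_grid = 25L, details = TRUE) {
  stop_if_not_phylo(tree)
  if (length(tree$tip.label) < 3L)
    stop("tree too small: placement needs at least 3 tips", call. = FALSE)
  if (label %in% tree$tip.label)
    stop("query label '", label, "' is already a tree tip; a query must be ",
         "trait-only", call. = FALSE)
  if (contemporaneous && !is_ultrametric(tree))
    warning("tree is not ultrametric; contemporaneous placement assumes ",
            "tips at a common height", call. = FALSE)
  X <- as_trait_matrix(X)
  miss <- setdiff(tree$tip.label, rownames(X))
  if (length(miss))
    stop("trait matrix lacks tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ppca <- phylo_pca(tree, X[tree$tip.label, , drop = FALSE])
  sq_all <- project_query(ppca, q)
  keep <- ppca$values > 1e-12 * max(ppca$values, 1e-300)
  if (!any(keep))
    stop("all trait components are degenerate (constant data)",
         call. = FALSE)
  S <- ppca$scores[, keep, drop = FALSE]
  sq <- sq_all[keep]
  prep <- placement_prep(tree, S)
  adm <- admissible_edges(tree, constraint)
  if (!length(adm)) stop("constraint admits no attachment edge",
                         call. = FALSE)
  tol <- 1e-8 * prep$T
  etab <- if (contemporaneous)
    optimize_edges_contemporaneous(prep, adm, sq, n_grid, tol)
  else
    optimize_edges_free(prep, adm, sq, n_grid, tol)
  etab <- etab[order(-etab$logLik, etab$edge), ]
  rownames(etab) <- NULL
  top <- which(etab$logLik >= etab$logLik[1L] - 1e-9)
  tie <- length(top) > 1L
  best <- etab[top[which.min(etab$edge[top])], ]
  placed <- NULL
  rates <- NULL
  if (details) {
    placed <- attach_tip(prep$tree, best$edge, best$height, best$pendant,
                         label)
    Saug <- rbind(S, matrix(sq, 1L, dimnames = list(label, colnames(S))))
    rates <- vapply(seq_len(ncol(S)), function(j)
      bm_mle(placed, Saug[, j])$sigma2, numeric(1))
    names(rates) <- colnames(S)
  }
  structure(list(edge = best$edge, height = best$height,
                 pendant = best$pendant, logLik = best$logLik,
                 rates = rates, edge_table = etab, tie = tie,
                 placed_tree = placed, ppca = ppca, query = label,
                 constraint = constraint,
                 contemporaneous = contemporaneous),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  et <- edges_table(x$ppca$tree)
  below <- et$child_label[match(x$edge, et$edge)]
  cat("ML placement of '", x$query, "'\n", sep = "")
  cat(sprintf("  attachment edge : #%d (above %s)\n", x$edge,
              if (is.na(below)) "an internal node" else below))
  cat(sprintf("  attachment height: %.6g   pendant length: %.6g\n",
              x$height, x$pendant))
  cat(sprintf("  log-likelihood  : %.4f%s\n", x$logLik,
              if (x$tie) "  (tied optimum; lowest edge index reported)"
              else ""))
  invisible(x)
}
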