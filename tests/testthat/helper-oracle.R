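# Independent oracles used across the suite. These deliberately avoid the
# package's incremental-Cholesky machinery: covariances are rebuilt densely
# from their definition and likelihoods evaluated by plain GLS algebra.

# Dense grid search for the ML attachment of a query with PC scores `sq`
# (tip scores `S`): for every edge and every grid height the augmented
# covariance matrix is rebuilt from scratch and the profile likelihood
# computed in closed form. Returns the best edge and log-likelihood.
oracle_place_grid <- function(tree, S, sq, n_grid = 500L,
                              contemporaneous = TRUE) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  C <- vcv_matrix(tree)
  S <- as.matrix(S)[tree$tip.label, , drop = FALSE]
  et <- edges_table(tree)
  n <- nrow(C); m <- ncol(S)
  T <- max(node_heights(tree)[seq_len(n)])
  tol <- 1e-8 * T
  ntip <- length(tree$tip.label)
  desc <- local({
    po <- ape::reorder.phylo(tree, "postorder")
    out <- vector("list", ntip + tree$Nnode)
    for (i in seq_len(ntip)) out[[i]] <- i
    for (k in seq_len(nrow(po$edge)))
      out[[po$edge[k, 1L]]] <- c(out[[po$edge[k, 1L]]],
                                 out[[po$edge[k, 2L]]])
    out
  })
  Caug <- matrix(0, n + 1L, n + 1L)
  Caug[seq_len(n), seq_len(n)] <- C
  y <- rbind(S, sq)
  one <- rep(1, n + 1L)
  best_ll <- -Inf; best_edge <- NA_integer_; best_h <- NA_real_
  per_edge <- numeric(nrow(et))
  for (e in seq_len(nrow(et))) {
    below <- desc[[et$child[e]]]
    s0 <- C[, below[1L]]
    lo <- min(et$parent_height[e] + tol, et$child_height[e])
    hi <- max(et$child_height[e] - tol, lo)
    hs <- seq(lo, hi, length.out = n_grid)
    e_best <- -Inf
    for (h in hs) {
      cv <- s0; cv[below] <- h
      Caug[n + 1L, seq_len(n)] <- cv
      Caug[seq_len(n), n + 1L] <- cv
      Caug[n + 1L, n + 1L] <- if (contemporaneous) T else h
      U <- try(chol(Caug), silent = TRUE)
      if (inherits(U, "try-error")) next
      Z <- backsolve(U, y, transpose = TRUE)
      u1 <- backsolve(U, one, transpose = TRUE)
      ll <- 0
      for (j in seq_len(m)) {
        a <- sum(u1 * Z[, j]) / sum(u1^2)
        q <- sum((Z[, j] - a * u1)^2)
        s2 <- q / (n + 1L)
        if (s2 <= 0) { ll <- -Inf; break }
        ll <- ll - 0.5 * ((n + 1L) * log(2 * pi) + (n + 1L) * log(s2) +
                            2 * sum(log(diag(U))) + (n + 1L))
      }
      if (ll > e_best) e_best <- ll
      if (ll > best_ll) { best_ll <- ll; best_edge <- e; best_h <- h }
    }
    per_edge[e] <- e_best
  }
  list(edge = best_edge, height = best_h, logLik = best_ll,
       per_edge = per_edge)
}

# Closed-form two-group F through the equal-variance t statistic (F = t^2).
oracle_f_from_t <- function(a, b) {
  unname(stats::t.test(a, b, var.equal = TRUE)$statistic^2)
}

# Numerical-optimization oracle for the single-trait BM MLE.
oracle_bm_optim <- function(tree, x) {
  f <- function(p) -bm_loglik(tree, x, p[1L], exp(p[2L]))
  o <- stats::optim(c(mean(x), log(stats::var(x) + 1e-3)), f)
  list(a = o$par[1L], sigma2 = exp(o$par[2L]), logLik = -o$value)
}

rand_tree <- function(n, seed) simulate_ultrametric_tree(n, seed = seed)
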