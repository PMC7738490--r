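#' Prune-and-replace randomization test of placement accuracy
#'
#' Per replicate, one tip is chosen uniformly at random (with replacement
#' across replicates) and pruned from the tree. It is then re-attached in
#' two ways: (a) by maximum-likelihood placement from its own trait values
#' ([place_taxon()]) and (b) at an edge chosen uniformly with attachment
#' height uniform along the edge and a contemporaneous pendant. Both
#' reconstructed trees are compared with the original by the branch-score
#' and quadratic path distances; systematically lower distances for the ML
#' arm show that the traits carry placement signal.
#'
#' @param tree An ultrametric `"phylo"` tree with at least 4 tips.
#' @param X Trait matrix covering every tip.
#' @param n_rep Number of replicates (default 100).
#' @param seed Integer seed.
#' @param random_free_pendant If `TRUE` the random arm also draws the
#'   pendant length uniformly on (0, tree height) instead of reaching the
#'   present.
#' @return An object of class `"randomization_report"`: data frame
#'   `replicates` with columns `tip`, `d_bs_ml`, `d_qp_ml`, `d_bs_random`,
#'   `d_qp_random`, plus `n_rep` and `seed`.
#' @export
randomization_test <- function(tree, X, n_rep = 100L, seed = 1L,
                               random_free_pendant = FALSE) {
  stop_if_not_phylo(tree)
  if (n_rep < 1L) stop("n_rep must be >= 1")
  if (length(tree$tip.label) < 4L)
    stop("randomization test needs at least 4 tips", call. = FALSE)
  X <- as_trait_matrix(X)
  miss <- setdiff(tree$tip.label, rownames(X))
  if (length(miss))
    stop("trait matrix lacks tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(X[tree$tip.label, ]))
    stop("trait matrix has missing values", call. = FALSE)
  rec <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    rec[[r]] <- with_seed(derive_seed(seed, paste0("rand-rep-", r)), {
      tip <- sample(tree$tip.label, 1L)
      pr <- prune_tip(tree, tip)
      base <- pr$tree
      Tq <- tree_height(base)
      # (a) ML placement from the tip's own traits
      pl <- place_taxon(base, X[base$tip.label, , drop = FALSE],
                        X[tip, ], label = tip)
      t_ml <- pl$placed_tree
      # (b) uniform random placement
      et <- edges_table(base)
      e <- sample(nrow(et), 1L)
      h <- stats::runif(1, et$parent_height[e], et$child_height[e])
      v <- if (random_free_pendant) stats::runif(1, 0, Tq) else Tq - h
      t_rd <- attach_tip(base, e, h, v, tip)
      data.frame(tip = tip,
                 d_bs_ml = branch_score_distance(tree, t_ml),
                 d_qp_ml = quadratic_path_distance(tree, t_ml),
                 d_bs_random = branch_score_distance(tree, t_rd),
                 d_qp_random = quadratic_path_distance(tree, t_rd),
                 stringsAsFactors = FALSE)
    })
  }
  structure(list(replicates = do.call(rbind, rec), n_rep = n_rep,
                 seed = seed), class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  r <- x$replicates
  cat(sprintf("Prune-and-replace randomization, %d replicates (seed %d)\n",
              x$n_rep, x$seed))
  s <- rbind(`ML placement` = c(stats::median(r$d_bs_ml),
                                stats::median(r$d_qp_ml)),
             `random placement` = c(stats::median(r$d_bs_random),
                                    stats::median(r$d_qp_random)))
  colnames(s) <- c("median branch-score", "median quadratic-path")
  print(round(s, 4))
  invisible(x)
}

#' Summary quantiles of a randomization report
#' @param object A `"randomization_report"`.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return Data frame of quantiles for the four distance columns.
#' @export
summary.randomization_report <- function(object,
                                         probs = c(.05, .25, .5, .75, .95),
                                         ...) {
  r <- object$replicates
  out <- sapply(r[, -1L], stats::quantile, probs = probs)
  data.frame(quantile = probs, out, check.names = FALSE)
}

#' Box plots of ML versus random placement distances
#'
#' The two-panel figure contrasting the branch-score and quadratic path
#' distance distributions of the ML and random arms.
#'
#' @param x A `"randomization_report"`.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.randomization_report <- function(x, ...) {
  r <- x$replicates
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(list(ML = r$d_bs_ml, random = r$d_bs_random),
                    ylab = "branch-score distance", ...)
  graphics::boxplot(list(ML = r$d_qp_ml, random = r$d_qp_random),
                    ylab = "quadratic path distance", ...)
  invisible(x)
}
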