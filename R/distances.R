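# Weighted bipartitions of a rooted tree, as a named vector of branch
# lengths keyed by the canonical side of each split (the side not containing
# the alphabetically first tip). The two edges meeting at the root of a
# binary rooted tree induce the same unrooted split; they are merged into a
# single entry carrying the larger of the two lengths, so the split set of a
# rooted tree matches its unrooted reading without double counting.
tree_splits <- function(tree) {
  stop_if_not_phylo(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  labs <- tree$tip.label
  ref <- min(labs)
  dts <- descendant_tip_sets(tree)
  out <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(labs[dts[[tree$edge[e, 2L]]]])
    if (ref %in% side) side <- sort(setdiff(labs, side))
    key <- paste(side, collapse = "\r")
    len <- tree$edge.length[e]
    if (exists(key, envir = out, inherits = FALSE))
      len <- max(len, get(key, envir = out, inherits = FALSE))
    assign(key, len, envir = out)
  }
  keys <- ls(out)
  stats::setNames(vapply(keys, get, numeric(1), envir = out), keys)
}

check_same_tips <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different tip label sets", call. = FALSE)
}

#' Branch-score distance between two weighted trees
#'
#' Square root of the sum, over the union of the two trees' bipartitions,
#' of squared branch-length differences; a split absent from one tree
#' counts with length zero there. Pendant splits are included, so
#' misplaced-tip pendant lengths contribute. Rooted trees are compared on
#' their induced unrooted weighted split sets.
#'
#' @param t1,t2 `"phylo"` trees over the same tip labels.
#' @return A non-negative number; 0 iff the weighted topologies agree.
#' @export
branch_score_distance <- function(t1, t2) {
  check_same_tips(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  keys <- union(names(s1), names(s2))
  l1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  l2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sqrt(sum((l1 - l2)^2))
}

#' Quadratic path distance between two weighted trees
#'
#' Square root of the sum over unordered tip pairs of squared differences
#' of patristic (path-length) distances.
#'
#' @param t1,t2 `"phylo"` trees over the same tip labels.
#' @return A non-negative number; 0 for identical weighted trees.
#' @export
quadratic_path_distance <- function(t1, t2) {
  check_same_tips(t1, t2)
  labs <- sort(t1$tip.label)
  d1 <- patristic_matrix(t1)[labs, labs]
  d2 <- patristic_matrix(t2)[labs, labs]
  sqrt(sum((d1[upper.tri(d1)] - d2[upper.tri(d2)])^2))
}
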