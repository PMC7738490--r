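#' Phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`; the
#' diagonal holds root-to-tip depths. Under Brownian motion with rate
#' `sigma2`, tip values are jointly normal with covariance `sigma2 * C`.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames, rows in `tree$tip.label` order.
#' @export
vcv_matrix <- function(tree) {
  stop_if_not_phylo(tree)
  ape::vcv.phylo(tree)
}

#' Patristic (tip-to-tip path length) matrix
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return A symmetric matrix with zero diagonal; `d(i, j) =
#'   depth(i) + depth(j) - 2 * C[i, j]`.
#' @export
patristic_matrix <- function(tree) {
  stop_if_not_phylo(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}
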