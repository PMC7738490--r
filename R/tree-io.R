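#' Parse a rooted Newick tree
#'
#' Reads a Newick string into an [ape::read.tree()] `"phylo"` object and
#' validates the contract every downstream analysis assumes: a single root,
#' unique tip labels, and non-negative branch lengths on all edges. Internal
#' node labels are discarded on read.
#'
#' @param text A single Newick string terminated by `;`, or the path of a
#'   file whose first tree is read.
#' @return A rooted `"phylo"` object with `edge.length` set.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' node_heights(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  str <- if (!grepl(";", text, fixed = TRUE) && file.exists(text))
    paste(readLines(text, warn = FALSE), collapse = "") else text
  if (!grepl(";", str, fixed = TRUE))
    stop("malformed Newick: missing terminating ';' in ",
         substr(str, 1, 40), call. = FALSE)
  tree <- tryCatch(
    ape::read.tree(text = str),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(tree))
    stop("malformed Newick string: ", substr(str, 1, 40), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("malformed Newick: branch lengths are required on all edges",
         call. = FALSE)
  if (anyNA(tree$edge.length))
    stop("malformed Newick: an edge is missing its branch length",
         call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    bad <- tree$edge[which(neg)[1L], 2L]
    lab <- if (bad <= length(tree$tip.label)) tree$tip.label[bad]
           else paste0("internal node ", bad)
    stop("negative branch length on the edge above ", lab, call. = FALSE)
  }
  tree$node.label <- NULL
  tree
}

#' Serialize a tree to canonical Newick
#'
#' Children of every internal node are ordered by their smallest descendant
#' tip label before writing, so two trees that are equal up to child rotation
#' serialize to identical strings. Internal labels are never written.
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; when given the string is written there.
#' @param digits Significant digits used for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 15L) {
  stop_if_not_phylo(tree)
  ntip <- length(tree$tip.label)
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  # smallest descendant label per node, computed bottom-up in postorder
  po <- ape::reorder.phylo(tree, "postorder")
  minlab <- character(ntip + tree$Nnode)
  minlab[seq_len(ntip)] <- tree$tip.label
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    minlab[p] <- if (minlab[p] == "" || minlab[ch] < minlab[p]) minlab[ch]
                 else minlab[p]
  }
  fmt <- function(x) {
    s <- sprintf(paste0("%.", digits, "g"), x)
    s
  }
  quote_lab <- function(lab) {
    if (grepl("[ ()\\[\\]:;,']", lab))
      paste0("'", gsub("'", "''", lab), "'") else lab
  }
  rec <- function(node) {
    if (node <= ntip) return(quote_lab(tree$tip.label[node]))
    ed <- kids[[as.character(node)]]
    ed <- ed[order(minlab[tree$edge[ed, 2L]], method = "radix")]
    parts <- vapply(ed, function(e) {
      paste0(rec(tree$edge[e, 2L]), ":", fmt(tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Heights of all nodes above the root
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Numeric vector over nodes `1..(Ntip+Nnode)`; the root has height 0
#'   and, on an ultrametric tree, every tip has height equal to the tree
#'   height.
#' @export
node_heights <- function(tree) {
  stop_if_not_phylo(tree)
  ape::node.depth.edgelength(tree)
}

#' Tree height (maximum root-to-tip depth)
#' @param tree A `"phylo"` object.
#' @return A single number.
#' @export
tree_height <- function(tree) max(node_heights(tree))

#' Test whether a tree is ultrametric
#'
#' A tree is accepted as ultrametric when the spread of root-to-tip depths
#' does not exceed `rel_tol` times the maximum depth. Time-calibrated trees
#' from Bayesian samplers are ultrametric only to floating precision, hence
#' a relative rather than absolute tolerance.
#'
#' @param tree A `"phylo"` object.
#' @param rel_tol Relative tolerance on the depth spread.
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  stop_if_not_phylo(tree)
  d <- node_heights(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= rel_tol * max(d)
}
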