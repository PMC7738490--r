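# Rebuild a proper "phylo" object from an edge list over arbitrary node ids.
# Tips are numbered 1..n following `tip_order` (a character vector of labels),
# internal nodes in preorder starting at the root (root = n + 1), and edges
# are emitted in cladewise order. Branch lengths are carried over exactly.
norm_phylo <- function(edge, edge.length, tip_id, tip_label, tip_order) {
  stopifnot(nrow(edge) == length(edge.length))
  root <- setdiff(unique(edge[, 1L]), edge[, 2L])
  if (length(root) != 1L) stop("edge list does not define a single root")
  n <- length(tip_id)
  new_id <- integer(0)
  lab_of <- stats::setNames(tip_label, as.character(tip_id))
  tip_new <- stats::setNames(match(tip_label, tip_order), as.character(tip_id))
  if (anyNA(tip_new)) stop("tip_order does not cover all tip labels")
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  out_e <- matrix(0L, nrow(edge), 2L)
  out_l <- numeric(nrow(edge))
  id_map <- new.env(parent = emptyenv())
  for (k in seq_along(tip_id))
    assign(as.character(tip_id[k]), tip_new[[k]], envir = id_map)
  next_int <- n + 1L
  row <- 0L
  # iterative preorder DFS; children visited in their stored edge order
  stack <- list(list(node = root, in_edge = NA_integer_))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nid <- as.character(top$node)
    if (!exists(nid, envir = id_map)) {
      assign(nid, next_int, envir = id_map)
      next_int <- next_int + 1L
    }
    me <- get(nid, envir = id_map)
    if (!is.na(top$in_edge)) {
      row <- row + 1L
      out_e[row, ] <- c(top$parent_new, me)
      out_l[row] <- edge.length[top$in_edge]
    }
    ed <- kids[[nid]]
    if (!is.null(ed)) {
      for (e in rev(ed))
        stack[[length(stack) + 1L]] <-
          list(node = edge[e, 2L], in_edge = e, parent_new = me)
    }
  }
  tr <- list(edge = out_e, edge.length = out_l,
             tip.label = tip_order, Nnode = next_int - n - 1L)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# Tip indices (1..Ntip) descending from each node; list indexed by node id.
descendant_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Tabulate the edges of a tree
#'
#' One row per edge in cladewise (preorder) order: the indices and heights of
#' its endpoint nodes and the set membership needed to reference an edge as a
#' candidate attachment site. Edge index = row number in this table is the
#' edge reference used throughout the package.
#'
#' @param tree A `"phylo"` object.
#' @return A data frame with columns `edge`, `parent`, `child`,
#'   `parent_height`, `child_height`, `length`, `child_label` (tip label or
#'   `NA` for internal children).
#' @export
edges_table <- function(tree) {
  stop_if_not_phylo(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  h <- node_heights(tree)
  ntip <- length(tree$tip.label)
  data.frame(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1L],
    child = tree$edge[, 2L],
    parent_height = h[tree$edge[, 1L]],
    child_height = h[tree$edge[, 2L]],
    length = tree$edge.length,
    child_label = ifelse(tree$edge[, 2L] <= ntip,
                         tree$tip.label[pmin(tree$edge[, 2L], ntip)], NA),
    stringsAsFactors = FALSE)
}

#' Remove a tip, keeping a record that allows exact restoration
#'
#' The pendant edge is removed and the degree-two node left behind is
#' suppressed by summing its two incident branch lengths. When the pruned
#' tip was a child of the root, the root itself is suppressed and all
#' heights shift accordingly; the record captures either case so
#' [restore_tip()] rebuilds the original tree exactly.
#'
#' @param tree A `"phylo"` object with at least 3 tips.
#' @param label Tip label to remove.
#' @return A list with elements `tree` (the pruned tree) and `record`.
#' @export
prune_tip <- function(tree, label) {
  stop_if_not_phylo(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("cannot prune: tree has fewer than 3 tips")
  tip <- match(label, tree$tip.label)
  if (is.na(tip)) stop("tip label not in tree: ", label, call. = FALSE)
  tree <- ape::reorder.phylo(tree, "cladewise")
  h <- node_heights(tree)
  e_tip <- which(tree$edge[, 2L] == tip)
  parent <- tree$edge[e_tip, 1L]
  v <- tree$edge.length[e_tip]
  sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], tip)
  root <- ntip + 1L
  dts <- descendant_tip_sets(tree)
  if (parent == root) {
    if (length(sibs) != 1L)
      stop("pruning at a multifurcating root is not supported")
    stem <- tree$edge.length[which(tree$edge[, 2L] == sibs)]
    record <- list(label = label, v = v, type = "root", stem = stem)
  } else {
    sib_below <- sort(tree$tip.label[dts[[sibs[1L]]]])
    record <- list(label = label, v = v, type = "edge",
                   h = h[parent], below = sib_below)
  }
  pruned <- ape::drop.tip(tree, tip)
  pruned <- ape::reorder.phylo(pruned, "cladewise")
  list(tree = pruned, record = record)
}

# Resolve an edge index from the sorted set of tip labels below its child.
find_edge_below <- function(tree, below) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  dts <- descendant_tip_sets(tree)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (identical(sort(tree$tip.label[dts[[ch]]]), below)) return(e)
  }
  stop("no edge spans exactly the tip set {",
       paste(below, collapse = ", "), "}", call. = FALSE)
}

#' Attach a new tip along an edge
#'
#' Inserts a new node at `attach_height` (measured from the root) on the
#' given edge and hangs a pendant edge of length `pendant_length` with the
#' new tip. Attaching at exactly the tree height with pendant length chosen
#' as `tree_height - attach_height` preserves ultrametricity.
#'
#' @param tree A `"phylo"` object.
#' @param edge Edge index as in [edges_table()] (cladewise row number).
#' @param attach_height Height of the insertion point, within the edge's
#'   height interval.
#' @param pendant_length Length of the new pendant edge (>= 0).
#' @param label Label of the new tip; must not already be present.
#' @return The enlarged `"phylo"` tree, in standard cladewise numbering with
#'   the new tip appended after the existing labels.
#' @export
attach_tip <- function(tree, edge, attach_height, pendant_length, label) {
  stop_if_not_phylo(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  if (label %in% tree$tip.label)
    stop("tip label already present: ", label, call. = FALSE)
  if (pendant_length < 0) stop("pendant_length must be >= 0")
  if (!is.numeric(edge) || edge < 1L || edge > nrow(tree$edge))
    stop("invalid edge index: ", edge, call. = FALSE)
  h <- node_heights(tree)
  p <- tree$edge[edge, 1L]; ch <- tree$edge[edge, 2L]
  hp <- h[p]; hc <- h[ch]
  tol <- 1e-9 * max(hc, 1)
  if (attach_height < hp - tol || attach_height > hc + tol)
    stop(sprintf("attach_height %.6g outside edge interval [%.6g, %.6g]",
                 attach_height, hp, hc), call. = FALSE)
  attach_height <- min(max(attach_height, hp), hc)
  nn <- ntip + tree$Nnode
  u <- nn + 1L        # new internal node (fresh id)
  tnew <- nn + 2L     # new tip (fresh id)
  e2 <- rbind(tree$edge[-edge, , drop = FALSE],
              c(p, u), c(u, ch), c(u, tnew))
  l2 <- c(tree$edge.length[-edge],
          attach_height - hp, hc - attach_height, pendant_length)
  norm_phylo(e2, l2,
             tip_id = c(seq_len(ntip), tnew),
             tip_label = c(tree$tip.label, label),
             tip_order = c(tree$tip.label, label))
}

#' Undo a [prune_tip()] using its removal record
#'
#' @param tree The pruned tree.
#' @param record The `record` element returned by [prune_tip()].
#' @return A tree equal to the one passed to [prune_tip()] (up to node
#'   numbering and child rotation; branch lengths exact).
#' @export
restore_tip <- function(tree, record) {
  stop_if_not_phylo(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  if (record$type == "edge") {
    e <- find_edge_below(tree, record$below)
    return(attach_tip(tree, e, record$h, record$v, record$label))
  }
  # tip hung from the original root: rebuild a root above the current one
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  newroot <- nn + 1L
  tnew <- nn + 2L
  e2 <- rbind(tree$edge, c(newroot, root), c(newroot, tnew))
  l2 <- c(tree$edge.length, record$stem, record$v)
  norm_phylo(e2, l2,
             tip_id = c(seq_len(ntip), tnew),
             tip_label = c(tree$tip.label, record$label),
             tip_order = c(tree$tip.label, record$label))
}
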