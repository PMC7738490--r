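#' Simulate correlated Brownian-motion traits on a tree
#'
#' Draws tip values from the matrix-normal distribution with among-tip
#' covariance `C` (the tree's phylogenetic covariance) and among-trait
#' covariance `R`: `X = 1 root' + A Z B'` with `A A' = C`, `B B' = R`,
#' `Z` iid standard normal.
#'
#' @param tree A `"phylo"` object.
#' @param R Trait covariance matrix (symmetric positive semi-definite), or a
#'   single number for one trait.
#' @param root_state Numeric vector of root states, one per trait
#'   (recycled from length 1).
#' @param seed Integer seed; the same seed always yields the same matrix.
#' @return Trait matrix, tips x traits, rownames = tip labels.
#' @export
simulate_bm <- function(tree, R, root_state = 0, seed) {
  stop_if_not_phylo(tree)
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("R must be symmetric", call. = FALSE)
  m <- ncol(R)
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    stop("R must be positive semi-definite", call. = FALSE)
  B <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m)
  root_state <- rep_len(root_state, m)
  C <- vcv_matrix(tree)
  n <- nrow(C)
  A <- t(chol(C))
  Z <- with_seed(seed, matrix(stats::rnorm(n * m), n, m))
  X <- A %*% Z %*% t(B)
  X <- sweep(X, 2L, root_state, "+")
  rownames(X) <- tree$tip.label
  colnames(X) <- colnames(R) %||% paste0("trait", seq_len(m))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ultrametric birth-death tree with a fixed tip count
#'
#' Forward birth-death simulation conditioned on `n_tips` surviving tips
#' (via [ape::rphylo()]), optionally rescaled to a fixed total height so
#' that Brownian rates are interpretable per unit tree depth.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param death_rate Extinction rate (>= 0, < `birth_rate`).
#' @param seed Integer seed.
#' @param height Rescale the tree to this total height; `NULL` keeps the
#'   simulated depth.
#' @return An ultrametric `"phylo"` tree with tips `t1..tn`.
#' @export
simulate_ultrametric_tree <- function(n_tips, birth_rate = 1,
                                      death_rate = 0, seed, height = 1) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (death_rate < 0 || death_rate >= birth_rate)
    stop("need 0 <= death_rate < birth_rate")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate,
                                    death = death_rate, fossils = FALSE))
  if (!is.null(height)) {
    tr$edge.length <- tr$edge.length * (height / tree_height(tr))
  }
  ape::reorder.phylo(tr, "cladewise")
}

#' Specification of a two-clade, mean-shifted trait simulation
#'
#' Describes the synthetic regime used throughout the package's validation:
#' two sister clades on an ultrametric unit-height tree, Brownian traits
#' with trait covariance `R`, and a fixed mean shift added to the second
#' clade's tips. The defaults emulate the scale of the fungal morphometric
#' data packaged in [table1_fixture()]: five traits (basidia length/width,
#' spore length/width in micrometres, spore shape ratio Q), per-trait rates
#' set so the within-clade spread at the tips matches the observed
#' within-lineage standard deviations, and a shift equal to the observed
#' Australian-minus-Patagonian mean contrast.
#'
#' @param n1,n2 Tips in clade 1 (labels `A*`) and clade 2 (labels `B*`).
#' @param R Trait covariance (matrix, or vector of per-trait rates taken as
#'   a diagonal).
#' @param shift Numeric vector added to every clade-2 tip (trait units).
#' @param root_state Root mean vector.
#' @param clade_height Height of each clade's crown below the present, as a
#'   fraction of the unit tree height.
#' @param birth_rate,death_rate Birth-death rates of the within-clade trees.
#' @param seed Integer seed.
#' @return A list of class `"clade_shift_spec"`.
#' @export
clade_shift_spec <- function(n1 = 10, n2 = 10,
                             R = c(basidia_L = 2.25, basidia_W = 0.0625,
                                   spore_L = 0.16, spore_W = 0.04,
                                   spore_Q = 0.0064),
                             shift = c(basidia_L = -5.7, basidia_W = -0.5,
                                       spore_L = -0.9, spore_W = -1.4,
                                       spore_Q = 0.46),
                             root_state = c(basidia_L = 28.9,
                                            basidia_W = 4.7, spore_L = 6.7,
                                            spore_W = 4.3, spore_Q = 1.6),
                             clade_height = 0.5, birth_rate = 1,
                             death_rate = 0, seed = 1) {
  if (n1 < 2L || n2 < 2L) stop("each clade needs at least 2 tips")
  if (!is.matrix(R)) {
    nm <- names(R)
    R <- diag(as.numeric(R), length(R))
    dimnames(R) <- list(nm, nm)
  }
  m <- ncol(R)
  shift <- rep_len(shift, m)
  root_state <- rep_len(root_state, m)
  if (clade_height <= 0 || clade_height >= 1)
    stop("clade_height must be in (0, 1)")
  structure(list(n1 = n1, n2 = n2, R = R, shift = shift,
                 root_state = root_state, clade_height = clade_height,
                 birth_rate = birth_rate, death_rate = death_rate,
                 seed = seed),
            class = "clade_shift_spec")
}

#' Simulate a two-clade tree with clade-shifted Brownian traits
#'
#' Builds a unit-height ultrametric tree whose two sister clades have the
#' requested sizes (each clade an independent birth-death tree of height
#' `clade_height`, joined by equal stems), simulates Brownian traits on it,
#' and adds the mean shift to clade 2.
#'
#' @param spec A [clade_shift_spec()].
#' @return List with `tree`, `traits` (tips x traits matrix), and `clade`
#'   (named character vector, `"clade1"`/`"clade2"` per tip).
#' @export
simulate_two_clade_dataset <- function(spec = clade_shift_spec()) {
  stopifnot(inherits(spec, "clade_shift_spec"))
  s1 <- derive_seed(spec$seed, "clade1-tree")
  s2 <- derive_seed(spec$seed, "clade2-tree")
  st <- derive_seed(spec$seed, "traits")
  t1 <- simulate_ultrametric_tree(spec$n1, spec$birth_rate, spec$death_rate,
                                  seed = s1, height = spec$clade_height)
  t2 <- simulate_ultrametric_tree(spec$n2, spec$birth_rate, spec$death_rate,
                                  seed = s2, height = spec$clade_height)
  t1$tip.label <- paste0("A", seq_len(spec$n1))
  t2$tip.label <- paste0("B", seq_len(spec$n2))
  stem <- 1 - spec$clade_height
  nwk <- paste0("(", sub(";$", "", write_newick(t1)), ":", stem, ",",
                sub(";$", "", write_newick(t2)), ":", stem, ");")
  tree <- parse_newick(nwk)
  X <- simulate_bm(tree, spec$R, root_state = spec$root_state, seed = st)
  in2 <- grepl("^B", rownames(X))
  X[in2, ] <- sweep(X[in2, , drop = FALSE], 2L, spec$shift, "+")
  clade <- ifelse(grepl("^A", tree$tip.label), "clade1", "clade2")
  names(clade) <- tree$tip.label
  list(tree = tree, traits = X, clade = clade)
}

#' Draw an independent query from a clade's marginal trait distribution
#'
#' Samples a trait vector from the marginal distribution of a single tip of
#' the chosen clade under the two-clade model: multivariate normal with mean
#' `root_state` (plus `shift` for clade 2) and covariance `R` times the unit
#' tree height. The draw is independent of any realized dataset, so it plays
#' the role of a new, unsequenced specimen from that clade.
#'
#' @param spec A [clade_shift_spec()].
#' @param clade `1` or `2`: which clade the query belongs to.
#' @param seed Integer seed.
#' @return Named numeric trait vector.
#' @export
draw_clade_query <- function(spec, clade = 2, seed) {
  stopifnot(inherits(spec, "clade_shift_spec"), clade %in% c(1, 2))
  R <- spec$R
  m <- ncol(R)
  eg <- eigen(R, symmetric = TRUE)
  B <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m)
  mu <- spec$root_state + if (clade == 2) spec$shift else 0
  z <- with_seed(seed, stats::rnorm(m))
  q <- drop(mu + B %*% z)
  names(q) <- colnames(R) %||% paste0("trait", seq_len(m))
  q
}

#' Does an edge lie within (or form the stem of) a set of tips?
#'
#' An edge "belongs" to a clade when every tip descended from its child node
#' is a member of `tips`. The clade's stem edge qualifies, since its child's
#' descendants are exactly the clade. Used to score whether a placement
#' recovered the correct clade.
#'
#' @param tree A `"phylo"` object.
#' @param edge Edge index as in [edges_table()].
#' @param tips Character vector of tip labels defining the clade.
#' @return `TRUE` or `FALSE`.
#' @export
edge_in_clade <- function(tree, edge, tips) {
  stop_if_not_phylo(tree)
  dts <- descendant_tip_sets(tree)
  child <- edges_table(tree)$child[edge]
  all(tree$tip.label[dts[[child]]] %in% tips)
}
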