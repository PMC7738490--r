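#' Likelihood-ratio statistic of two placement models
#'
#' `LR = 2 * (logL_unconstrained - logL_constrained)`; non-negative up to
#' numerical error because the constrained attachment edges are a subset of
#' the unconstrained ones.
#'
#' @param logL_unconstrained,logL_constrained Maximized log-likelihoods.
#' @return The likelihood-ratio statistic.
#' @export
lr_statistic <- function(logL_unconstrained, logL_constrained) {
  2 * (logL_unconstrained - logL_constrained)
}

#' Format a p-value the way comparison tables print it
#'
#' Values below `threshold` are reported as `"< threshold"`, others to two
#' decimals.
#'
#' @param p P-value in (0, 1].
#' @param threshold Reporting floor.
#' @return A character scalar, e.g. `"< 0.01"` or `"0.27"`.
#' @export
format_p_value <- function(p, threshold = 0.01) {
  if (p < threshold) paste0("< ", format(threshold)) else sprintf("%.2f", p)
}

#' Parametric-bootstrap likelihood-ratio test of a constrained placement
#'
#' Tests whether restricting the query's attachment to a given clade
#' significantly worsens the placement likelihood. The observed statistic
#' compares unconstrained and constrained ML placements. Its null
#' distribution is simulated parametrically: traits are generated by
#' Brownian motion on the constrained-placement tree (with GLS-estimated
#' root means and evolutionary trait covariance, i.e. the constrained model
#' taken as true), and each simulated dataset is re-analyzed with both the
#' unconstrained and the constrained search, recomputing the phylogenetic
#' PCA each time. The p-value uses the add-one rule
#' `p = (1 + #\{LR_null >= LR_obs\}) / (1 + n_sim)`, so it is never zero.
#'
#' @inheritParams place_taxon
#' @param constraint Character vector of tip labels defining the constrained
#'   clade (required here).
#' @param n_sim Number of null simulations (>= 1).
#' @param seed Integer seed governing all simulations.
#' @return An object of class `"placement_lrt"`: list with
#'   `logL_unconstrained`, `logL_constrained`, `lr`, `null_lr` (length
#'   `n_sim`), `p_value`, `n_sim`, `seed`, and the two `"placement"` fits.
#' @export
placement_lrt <- function(tree, X, q, constraint, n_sim = 100L, seed = 1L,
                          contemporaneous = TRUE, label = "query") {
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (is.null(constraint) || !length(constraint))
    stop("a non-empty constraint is required", call. = FALSE)
  X <- as_trait_matrix(X)
  unc <- place_taxon(tree, X, q, constraint = NULL,
                     contemporaneous = contemporaneous, label = label)
  con <- place_taxon(tree, X, q, constraint = constraint,
                     contemporaneous = contemporaneous, label = label)
  lr <- max(0, lr_statistic(unc$logLik, con$logLik))
  # null model: the constrained placement is true; estimate BM parameters
  # on the constrained (N+1)-taxon tree from the observed traits
  traits <- colnames(X)
  qv <- if (is.null(names(q))) stats::setNames(q, traits) else q[traits]
  Y <- rbind(X[tree$tip.label, , drop = FALSE],
             matrix(qv, 1L, dimnames = list(label, traits)))
  fit <- phylo_pca(con$placed_tree, Y)
  # per-edge optima are independent, so one unconstrained search yields
  # both maxima: the constrained optimum is the best admissible edge
  adm <- admissible_edges(tree, constraint)
  null_lr <- vapply(seq_len(n_sim), function(i) {
    Ysim <- simulate_bm(con$placed_tree, fit$R, root_state = fit$mean,
                        seed = derive_seed(seed, paste0("lrt-null-", i)))
    colnames(Ysim) <- traits
    qs <- Ysim[label, ]
    Xs <- Ysim[tree$tip.label, , drop = FALSE]
    u <- place_taxon(tree, Xs, qs, constraint = NULL,
                     contemporaneous = contemporaneous, label = label,
                     details = FALSE)
    k_ll <- max(u$edge_table$logLik[u$edge_table$edge %in% adm])
    max(0, lr_statistic(u$logLik, k_ll))
  }, numeric(1))
  p <- (1 + sum(null_lr >= lr)) / (1 + n_sim)
  structure(list(logL_unconstrained = unc$logLik,
                 logL_constrained = con$logLik, lr = lr,
                 null_lr = null_lr, p_value = p, n_sim = n_sim,
                 seed = seed, unconstrained = unc, constrained = con),
            class = "placement_lrt")
}

#' Render a likelihood-ratio comparison as a small report table
#'
#' @param logL_unconstrained,logL_constrained Maximized log-likelihoods.
#' @param p_value P-value of the constrained model against the
#'   unconstrained one.
#' @param constraint_name Row label of the constrained model.
#' @return Character vector of report lines.
#' @export
lrt_report <- function(logL_unconstrained, logL_constrained, p_value,
                       constraint_name = "Constrained") {
  c("Model\tlog(L)\tP-value (compared to unconstrained model)",
    sprintf("Unconstrained\t%.2f\t-", logL_unconstrained),
    sprintf("%s\t%.2f\t%s", constraint_name, logL_constrained,
            format_p_value(p_value)),
    sprintf("LR = %.2f", lr_statistic(logL_unconstrained,
                                      logL_constrained)))
}

#' @export
print.placement_lrt <- function(x, ...) {
  writeLines(lrt_report(x$logL_unconstrained, x$logL_constrained,
                        x$p_value))
  cat(sprintf("(null distribution: %d parametric simulations, seed %d)\n",
              x$n_sim, x$seed))
  invisible(x)
}
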