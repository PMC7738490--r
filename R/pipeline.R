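#' Read a flat key-value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Recognized keys
#' mirror [run_pipeline()]'s arguments: `tree`, `traits`, `query`,
#' `constraint` (comma-separated tip labels), `groups`, `n_rand`, `n_sim`,
#' `seed`, `out_dir`, `contemporaneous`, `random_free_pendant`.
#'
#' @param path Path of the configuration file.
#' @return Named list of configuration values (all character; coerced by
#'   [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("cannot parse config line(s): ",
                     paste(ln[bad], collapse = "; "), call. = FALSE)
  stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                  vapply(kv, `[`, character(1), 2L))
}

#' Run the full placement workflow
#'
#' Reproduces the analysis chain end to end on one tree and one trait
#' table: ML placement of the query, the prune-and-replace randomization
#' test, the constrained-placement likelihood-ratio test (when a constraint
#' is given), and the two-clade morphometric comparison (when a grouping is
#' given). All outputs are plain text under `out_dir`, together with a
#' machine-readable manifest (input checksums, seed, package version) and a
#' human-readable log. Every stage draws from a substream derived from the
#' single seed, so stages can be re-run in isolation reproducibly.
#'
#' @param config Named list (or path to a file readable by
#'   [read_run_config()]) with entries: `tree` (Newick path), `traits`
#'   (delimited table path), `query` (row label in the trait table, absent
#'   from the tree), optional `constraint` (character vector or
#'   comma-separated string of tip labels), optional `groups` (two-column
#'   specimen,clade file for the morphometric report), `n_rand`, `n_sim`,
#'   `seed`, `out_dir`, `contemporaneous`, `random_free_pendant`.
#' @return Invisibly, a list with elements `placement`, `randomization`,
#'   `lrt` (or `NULL`), `morphology` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  get_cfg <- function(key, default = NULL) {
    v <- config[[key]]
    if (is.null(v) || (is.character(v) && !nzchar(v))) default else v
  }
  tree_path <- get_cfg("tree"); traits_path <- get_cfg("traits")
  query <- get_cfg("query")
  if (is.null(tree_path) || is.null(traits_path) || is.null(query))
    stop("config must provide 'tree', 'traits' and 'query'", call. = FALSE)
  out_dir <- get_cfg("out_dir", "morphoplace_out")
  seed <- as.integer(get_cfg("seed", 1L))
  n_rand <- as.integer(get_cfg("n_rand", 100L))
  n_sim <- as.integer(get_cfg("n_sim", 100L))
  contemporaneous <- !identical(as.character(get_cfg("contemporaneous",
                                                     "TRUE")), "FALSE")
  free_pend <- identical(as.character(get_cfg("random_free_pendant",
                                              "FALSE")), "TRUE")
  constraint <- get_cfg("constraint")
  if (is.character(constraint) && length(constraint) == 1L)
    constraint <- trimws(strsplit(constraint, ",")[[1L]])
  tree <- parse_newick(tree_path)
  X <- read_trait_table(traits_path)
  if (query %in% tree$tip.label)
    stop("query '", query, "' is a tree tip; a query must be trait-only",
         call. = FALSE)
  if (!query %in% rownames(X))
    stop("query '", query, "' not found in the trait table", call. = FALSE)
  miss <- setdiff(tree$tip.label, rownames(X))
  if (length(miss))
    stop("tree tip(s) missing from the trait table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("morphoplace pipeline, seed %d", seed)
  say("tree: %s (%d tips) | traits: %s (%d specimens, %d traits)",
      tree_path, length(tree$tip.label), traits_path, nrow(X), ncol(X))

  Xtips <- X[tree$tip.label, , drop = FALSE]
  qv <- X[query, ]
  pl <- place_taxon(tree, Xtips, qv, contemporaneous = contemporaneous,
                    label = query)
  write_newick(pl$placed_tree, file.path(out_dir, "placed_tree.nwk"))
  utils::write.table(pl$edge_table, file.path(out_dir, "edge_loglik.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("placement: edge #%d, height %.4g, pendant %.4g, logL %.4f%s",
      pl$edge, pl$height, pl$pendant, pl$logLik,
      if (pl$tie) " (tie)" else "")

  rz <- randomization_test(tree, Xtips, n_rep = n_rand,
                           seed = derive_seed(seed, "randomization"),
                           random_free_pendant = free_pend)
  utils::write.table(rz$replicates,
                     file.path(out_dir, "randomization_replicates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(summary(rz),
                     file.path(out_dir, "randomization_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("randomization: %d replicates; median d_BS ML %.4g vs random %.4g",
      n_rand, stats::median(rz$replicates$d_bs_ml),
      stats::median(rz$replicates$d_bs_random))

  lrt <- NULL
  if (!is.null(constraint) && length(constraint)) {
    lrt <- placement_lrt(tree, Xtips, qv, constraint, n_sim = n_sim,
                         seed = derive_seed(seed, "lrt"),
                         contemporaneous = contemporaneous, label = query)
    writeLines(lrt_report(lrt$logL_unconstrained, lrt$logL_constrained,
                          lrt$p_value),
               file.path(out_dir, "lrt_report.tsv"))
    utils::write.table(data.frame(replicate = seq_along(lrt$null_lr),
                                  lr = lrt$null_lr),
                       file.path(out_dir, "lrt_null_sample.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    say("LRT: LR = %.4f, p %s (n_sim = %d)", lrt$lr,
        format_p_value(lrt$p_value), n_sim)
  }

  morph <- NULL
  groups_path <- get_cfg("groups")
  if (!is.null(groups_path)) {
    g <- utils::read.table(groups_path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
    grouping <- stats::setNames(as.character(g[[2L]]), as.character(g[[1L]]))
    morph <- clade_morphology_report(X, grouping)
    an <- do.call(rbind, lapply(names(morph$anova), function(tr) {
      a <- morph$anova[[tr]]
      data.frame(trait = tr, f = a$f, df_between = a$df_between,
                 df_within = a$df_within, p_value = a$p_value,
                 p_printed = format_p_value(a$p_value))
    }))
    utils::write.table(an, file.path(out_dir, "morphology_anova.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(morph$descriptives,
                       file.path(out_dir, "morphology_descriptives.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    say("morphometrics: %d traits compared between %s and %s",
        length(morph$anova), morph$clades[1L], morph$clades[2L])
  }

  manifest <- c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("morphoplace"))),
    sprintf("seed = %d", seed),
    sprintf("tree_md5 = %s", unname(tools::md5sum(tree_path))),
    sprintf("traits_md5 = %s", unname(tools::md5sum(traits_path))),
    sprintf("query = %s", query),
    sprintf("n_rand = %d", n_rand),
    sprintf("n_sim = %d", n_sim),
    sprintf("contemporaneous = %s", contemporaneous))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  writeLines(log_lines, logf)
  invisible(list(placement = pl, randomization = rz, lrt = lrt,
                 morphology = morph, manifest = manifest))
}
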