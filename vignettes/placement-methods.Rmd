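---
title: "Morphological placement of sequence-less taxa: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological placement of sequence-less taxa: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoplace)
```

## The problem

A type specimen with no sequenceable DNA — say, a fungal holotype collected
decades ago — must be placed in a time-calibrated molecular phylogeny using
only continuous morphological measurements (basidia and spore lengths and
widths, spore shape ratio Q). `morphoplace` implements the full workflow:
a Brownian-motion (BM) likelihood engine, phylogenetic PCA, an exhaustive
per-edge maximum-likelihood attachment search, a prune-and-replace
randomization test of placement accuracy, and a parametric-bootstrap
likelihood-ratio test (LRT) of clade-constrained placements.

## Model

Under BM with rate $\sigma^2$ and root state $a$, tip values on a rooted
tree are jointly normal, $x \sim \mathcal N(a\mathbf 1, \sigma^2 C)$, where
$C_{ij}$ is the height of the most recent common ancestor of tips $i$ and
$j$. The maximized log-likelihood has the closed GLS form used throughout
(`bm_mle()`): $\hat a = (\mathbf 1^\top C^{-1}x)/(\mathbf 1^\top C^{-1}
\mathbf 1)$ and $\hat\sigma^2 = (x-\hat a\mathbf 1)^\top C^{-1}
(x-\hat a\mathbf 1)/n$ (ML divisor $n$, not $n-1$).

Multiple traits are first decorrelated by phylogenetic PCA (`phylo_pca()`,
covariance mode): the evolutionary covariance $R$ is estimated by GLS with
divisor $n-1$, eigen-decomposed, and tip scores are the GLS-centered data
projected on the eigenvectors. The query is projected on the *same*
components (`project_query()`); it never contributes to $R$. Components
whose eigenvalue is below $10^{-12}$ of the largest are treated as
degenerate (numerically constant) and dropped before placement. Component
scores are then modelled as independent BM characters; the placement
log-likelihood is the sum of per-component profile maxima.

## The attachment search

`place_taxon()` scores every edge of the tree. Attaching the query at
height $h$ (from the root) on an edge, with pendant length $v$, extends $C$
by one row/column: covariance $h$ with tips below the edge, the fixed
shared height with all others, and variance $h+v$. The engine factorizes
the base $C = U^\top U$ once, pre-computes two triangular solves per edge,
and evaluates the profile likelihood at any $(h,v)$ with scalar arithmetic
— no refactorization per candidate. In the default contemporaneous mode
(extant specimens, ultrametric tree) the pendant always reaches the
present, $v = T - h$; with `contemporaneous = FALSE`, $v$ is optimized
jointly by bounded quasi-Newton restarts.

Numerical choices, all deliberate:

* **Height refinement.** Per edge, a bracketing grid of `n_grid` (25)
  heights is zoomed iteratively around the incumbent until the bracket is
  below `1e-8` of tree height. Edge intervals are inset by the same
  tolerance so candidate positions never sit exactly on a node (which
  would make the augmented covariance singular).
* **Ties.** Both root-child edges meet at the root, so a height-zero
  optimum is an exact tie; symmetric data produce further ties. Optima
  within `1e-9` log-units are reported as ties (`$tie`) and broken
  deterministically to the lowest edge index in the fixed cladewise edge
  numbering of `edges_table()`.
* **Degeneracy.** A component with (numerically) zero rate would make the
  likelihood unbounded; such components are dropped up front, and
  `bm_mle()` flags constant traits (`degenerate`, relative threshold)
  rather than reporting a spurious likelihood.
* **Search space.** Candidate attachments are the *existing* edges only.
  Extending the tree below its root (making the query an outgroup) is a
  different model and intentionally outside the search space; a root-edge
  attachment at height $\to 0$ is the in-space analogue.

A deliberately slow reference, `place_taxon_brute()`, rebuilds the full
augmented covariance and its Cholesky factor from scratch on a dense
per-edge height grid; the test suite holds the fast engine to it
(the optimizer may never fall below any grid point, and can exceed a
500-point grid's maximum only by the grid's own discretization error).

## Constrained placement and the LRT

A taxonomic hypothesis ("the specimen belongs to this clade") restricts
the search to the edges of the constraint's minimal spanning subtree —
an edge is admissible when its descendant tips intersect the constraint
set without containing all of it; a single-tip constraint admits just that
pendant edge. `placement_lrt()` compares the constrained and
unconstrained maxima with $LR = 2(\ell_u - \ell_c) \ge 0$ and calibrates
it by parametric bootstrap: BM traits are simulated on the
constrained-placement tree (GLS-estimated root means and trait
covariance), each simulated dataset is re-analyzed — pPCA recomputed,
one unconstrained search per dataset, the constrained maximum read off
the admissible rows of the same per-edge table — and the p-value uses the
add-one rule $(1 + \#\{LR^* \ge LR\})/(1 + n_{\mathrm{sim}})$.

## Validation by prune-and-replace

`randomization_test()` prunes a uniformly chosen tip, re-attaches it
(a) by ML from its own traits and (b) at a uniform random edge and height
with a contemporaneous pendant, and compares both reconstructions to the
original tree by two metrics:

* **Branch-score distance**: square root of summed squared length
  differences over the union of the two trees' bipartitions, pendant
  bipartitions included. Bipartitions are compared unrooted; the two
  root-child edges induce the same bipartition and are merged by taking
  the larger of their lengths. (Consequence: perturbing one *non-root*
  edge by $\delta$ changes the distance by exactly $|\delta|$; for the
  two root edges the merge makes the effect one-sided.)
* **Quadratic path distance**: square root of summed squared differences
  of tip-to-tip patristic distances over unordered tip pairs.

Placement signal shows up as systematically smaller distances for the ML
arm; the suite tests this with one-sided sign tests at $\alpha = 0.01$.

## Synthetic data: what the generator does and does not emulate

`simulate_two_clade_dataset()` builds a unit-height ultrametric tree with
two sister clades (independent birth-death crowns of height
`clade_height`, default 0.5, joined by equal stems), simulates correlated
BM traits, and adds a fixed mean shift to the second clade.
`clade_shift_spec()` defaults are scaled to the packaged fungal
morphometric table (`table1_fixture()`): five traits in micrometres
(plus the dimensionless Q), per-trait rates chosen so the tip-level
within-clade spread matches the observed within-lineage standard
deviations (e.g. basidia length rate 2.25 µm²/height), and a shift equal
to the observed between-lineage mean contrast (e.g. −5.7 µm in basidia
length). `draw_clade_query()` samples an *independent* specimen from a
clade's marginal distribution — a new, unsequenced collection rather than
a pruned tip.

The generator emulates scale and contrast, not process detail: it does not
model measurement error, within-specimen replicate structure, non-BM
evolution (selection, bounds, rate shifts), or missing data. Tips within a
clade are phylogenetically correlated, so naive two-sample tests on
simulated clades over-reject; the calibrated check of the generator is the
GLS contrast test with the true tree covariance, which the test suite uses.

## Problem sizes and costs

The package is tuned for the regime it targets: tens of tips, a handful of
traits. A 20-tip placement costs ~15 ms; a 99-simulation LRT on 10 tips
runs in under a second; the 100-replicate randomization test on 20 tips
takes seconds. The brute-force reference costs seconds per dataset and is
used for verification only.

```{r example, eval = FALSE}
sp <- clade_shift_spec(seed = 1)
d <- simulate_two_clade_dataset(sp)
q <- draw_clade_query(sp, clade = 2, seed = 2)
pl <- place_taxon(d$tree, d$traits, q, label = "holotype")
print(pl)
```
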