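---
title: "Population trees for single-cell counts: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population trees for single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tmctree` builds binary cell-population trees by recursive spectral
bipartition with a Newman–Girvan modularity stopping rule, then supports
pruning, per-node overlays and headless radial rendering. This vignette is
the package's own account of the method: what is computed, which knobs
matter, what the synthetic data do and do not emulate, and where we made
judgment calls.

## The model

**Normalization.** Raw counts are filtered — cells with at least 250
transcripts (inclusive), then genes detected in at least 1 surviving cell,
in that order and without iterating to a fixpoint — and TF-IDF weighted:
`x(c,g) = tf(c,g) · ln(N/df_g)`, with `tf` the within-cell count fraction
and `df_g` the number of cells detecting `g`. We use the natural log and no
offset, the information-retrieval default; a consequence we accept is that
a gene detected in *every* cell carries weight `ln 1 = 0` and its column
vanishes. TF-IDF emphasizes genes that are informative *because they are
selectively detected*, which is also why it assumes sparse count data:
on a dense matrix most IDF terms approach zero and the representation
degenerates.

**Bipartition.** At each node the row-L2-normalized submatrix is
decomposed by SVD and cells are split by the sign of the second left
singular vector (an LSA-style spectral cut: the first vector captures the
common profile, the second the dominant axis of contrast). The sign
convention fixes the largest-magnitude component positive, so the split is
reproducible across platforms. Numerically zero components join side A; in
the corner case where the strictly-negative side is empty but zeros and
positives both exist (e.g. two exactly orthogonal cells), the zeros form
side B. If the second singular value is zero within a relative tolerance
of `1e-8` — all rows identical, or a rank-1 submatrix — the split is
degenerate and the node becomes a leaf.

**Stopping rule.** A candidate split is scored by Newman–Girvan modularity
`Q = Σ_i (e_ii − a_i²)` on the *truncated-cosine* similarity graph of the
node's cells: `w(i,j) = max(0, cos(x_i, x_j))`, zero diagonal. Negative
cosines are clipped because modularity expects non-negative weights; at
the desk scales this package targets, the dense graph is exact and cheap,
and it makes the quantity directly checkable against the brute-force
double-sum definition (the test suite does this on random graphs to
1e-10). The split is accepted iff `Q > min_modularity` (default 0), and
the accepted `Q` is stored as the node's *split distance*. The trivial
one-community partition returns `Q = 0` exactly, by construction.

**Why trees need pruning.** On a dense similarity graph, the spectral cut
of pure sampling noise almost always attains a *small positive* `Q` (we
measure roughly 0.003–0.02 on homogeneous simulations), so the `Q > 0`
rule keeps subdividing genuinely homogeneous populations into small,
shallow-distance nodes. This is intrinsic to modularity on weighted
complete graphs, not an implementation artifact, and the practical remedy
is the one used in the drug-persister workflow this package reproduces:
**minimum-distance pruning at 0.019**, which collapses every subtree whose
split distance falls below the cutoff. Genuine population splits sit an
order of magnitude higher (about 0.09–0.19 on the packaged simulations),
so the cutoff separates signal from noise splits cleanly. The package
therefore treats `build_tree()` + `prune_min_distance(0.019)` as the
canonical pipeline; `build_tree()` alone is the raw, maximally resolved
tree.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `min_transcripts` | `filter_matrix` | 250 | minimum per-cell total count (inclusive); the standard preprocessing default |
| `min_cells_per_feature` | `filter_matrix` | 1 | genes must be detected in this many surviving cells |
| `min_modularity` | `build_tree` | 0 | strict lower bound on split `Q`; raising it can only shrink the tree (tested property) |
| `min_split_size` | `build_tree` | 2 | nodes smaller than this are leaves |
| distance cutoff | `prune_min_distance` | — | 0.019 in the reference workflow; strict `<`, applied top-down with short-circuiting |
| `n` | `prune_min_cells` | — | if *either* child has fewer than `n` cells both children are removed (a binary tree cannot drop one child); guarantees every non-root node holds ≥ `n` cells |
| `pseudocount` | `differential_log2fc` | 1 | added to both group means before the log2 ratio; standard for count data |

Pruning, re-rooting and depth cuts are recorded as a `prune_history`, a
replayable list of steps serialized inside the render configuration, so a
figure's exact tree state can be reproduced from its JSON config alone;
replaying a prefix implements undo.

## The synthetic data

`simulate_block_counts()` plants `B` transcriptionally distinct blocks:
negative-binomial counts with mean `baseline_mean` everywhere, times
`marker_fold` on each block's private, disjoint marker set. Dispersion is
shared across genes (`variance = μ + 0.5 μ²` at the default 0.5, a typical
droplet-data overdispersion). The defaults — 3 × 50 cells, 2000 genes,
baseline mean 0.3, 100 markers per block at 8-fold — were chosen so a
simulated cell looks like a small droplet-experiment cell: about 800
transcripts (comfortably above the 250-transcript filter, which the
pipeline applies to simulated data exactly as to real data), roughly
three-quarters of entries zero, and a few percent of the transcriptome
differentially expressed between cell types — the regimes TF-IDF and
cosine similarity are designed for.

What the generator does **not** emulate: library-size gradients, doublets,
ambient RNA, batch effects, correlated gene modules, zero-inflation beyond
NB, or nested sub-block structure. Passing the recovery tests therefore
shows the pipeline identifies well-separated discrete populations under
realistic sparsity and overdispersion; it does not certify behavior on
continuous trajectories or confounded designs.

`simulate_random_tree()` grows a full binary tree by splitting uniformly
chosen leaves, with uniform(0,1) split distances — deliberately
structure-free, since it only exercises pruning, overlay and rendering
invariants that must hold on *any* valid tree.

## Numerical and design choices

- **Exact SVD, not iterative.** Bipartitions use LAPACK's `svd()` on the
  dense submatrix. At desk scale this is fast, and it is exactly
  deterministic, which an iterative Lanczos/power solver only achieves
  with extra seeding machinery; determinism matters because the test suite
  asserts byte-identical batch output.
- **Upper-quartile normalization** divides each cell by the 75th
  percentile of its *nonzero* counts (linear interpolation between order
  statistics, R's type-7 percentile — a concrete, reproducible convention)
  and rescales by the median of the per-cell divisors so magnitudes remain
  comparable across cells.
- **Mann–Whitney U** comes from `stats::wilcox.test`: exact enumeration
  when both groups have ≤ 20 cells and no ties, otherwise the
  tie-corrected normal approximation with continuity correction. Two-sided
  by default with a one-sided option. Group means include zeros.
- **Tree serialization** writes distances at full double precision so
  read∘write is the identity; the JSON schema (`_id`, `_distance`,
  `_cells`, `children`) is this package's documented dialect.
- **Radial layout** allocates sibling angular spans by leaf count (a
  cells-weighted option exists); leaf-count allocation gives visually
  balanced trees regardless of population sizes. With distance scaling
  enabled, edge lengths are the parent's split distance floored at 1% of
  the deepest cumulative distance so near-zero splits stay visible.
- **Node glyphs** are pies of label composition when labels are supplied
  (a blend/majority option exists for PNG), otherwise circles on a
  monotone two-color scale over the overlay's [min, max]. Every glyph
  carries its `data-node-id`, making figures scriptably inspectable.
- **PNG export** draws the same layout through R's native bitmap device
  (`grDevices::png`), honoring the requested width and the configured
  aspect ratio. SVG is the primary, fully structured output; the PNG
  backend trades the arc-perfect links for device portability
  (arcs are approximated by 24-segment polylines).
- **Degenerate inputs.** Empty matrices are errors; all-identical cells
  yield a single-leaf tree; zero-weight graphs return `Q = 0` with a
  warning; a cell whose TF-IDF row is all zero is an error at graph
  construction (it has no direction), which in practice cannot follow the
  standard filter.
- **Feature store.** One gzip-compressed little-endian float64 column per
  gene plus a TSV name index — the simplest layout that honors the
  "import once, render many" contract without a database server, and
  bit-exact for integer counts. I/O instrumentation counters
  (`io_counters()`) let tests *prove* the contract: a batch run performs
  one tree parse, one store open, zero matrix reads.

## Problem sizes in the test suite

The packaged experiments run at deliberately small scale: 150-cell /
2000-gene simulations (20 seeds for recovery, 20 for the homogeneous
null), 200 random trees for pruning guarantees, 100 random graphs for the
modularity oracle, 100 tree/vector pairs for overlay conservation. These
sizes give stable pass/fail behavior (recovery is 18–20 of 20 seeds across
generator seeds) while keeping the whole suite under a minute of compute.

## Known limitations

- The dense cosine graph and exact SVD are O(n²)–O(n·g·min(n,g)) per node;
  the package targets desk-scale matrices (thousands of cells), not
  atlas-scale streamed clustering.
- `Q > 0` over-splits by design (see above); interpret raw trees through
  `prune_min_distance` or `prune_min_cells`.
- TF-IDF discards genes detected in all cells; on small dense toy matrices
  this can zero out most of the signal (the realistic sparse regime does
  not suffer from this).
- `set_root` keeps original node ids and distances and does not recompute
  anything — by design, so overlays computed on the full tree remain
  cross-referenceable — but it means a re-rooted tree's distances are not
  comparable to a tree rebuilt from the subset's cells alone.
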