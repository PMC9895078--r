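---
title: "Decomposing tumor spatial transcriptomics: models and design choices"
author: "spotmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing tumor spatial transcriptomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A spatial transcriptomics (ST) spot covers several cells, so its expression
profile `S` is a mixture of the transcriptomes of every cell it captures.
In tumor tissue the mixture has an awkward asymmetry: immune and stromal
cells are transcriptionally stereotyped across patients and can be described
by a reference atlas, while malignant cells are patient-specific — no
external reference profile fits them well. spotmix addresses this with three
sequential stages.

# Stage 1 — malignant fraction without a malignant reference

Malignant cells are recognized not by a fixed expression program but by the
genome-wide footprint of copy-number alterations (CNA), which is
cancer-type-characteristic and correlates with expression dosage. Stage 1
works as follows.

1. **Cluster the spots.** Agglomerative (Ward) clustering on Euclidean
   distances over the 2000 most variable genes in `log2(TPM/10 + 1)` space;
   the tree is cut at K = 2–9 and K is chosen by the mean-silhouette rule:
   the K preceding the largest decrease in silhouette (argmax silhouette if
   the profile never decreases). When a sharp collapse of the silhouette is
   split across two adjacent steps the largest drop is near-tied, so drops
   within 25% of the largest are treated as candidates and resolved toward
   the higher silhouette — without this, a crisp two-cluster structure can
   be cut at K = 3.
2. **Call malignant clusters.** Every gene is mean-centered across spots and
   each spot is Pearson-correlated with the cancer-type CNA signature (first
   choice) or expression signature (fallback when no cluster passes; the
   pan-cancer expression signature when the cancer type is not in the
   dictionary). A cluster is malignant when (a) its spots' correlations are
   significantly greater than zero (one-sided Wilcoxon signed-rank,
   p < 0.05) and (b) its proportion of positively, significantly correlated
   spots exceeds the dataset-wide proportion. Note the signed-rank test
   caps how small a cluster can be called: with n = 3 spots its one-sided
   p value cannot go below 1/8, so only clusters of at least 6 spots can
   clear p < 0.05; clusters under 3 spots are excluded outright.
3. **Score every spot.** The ST-specific malignant profile `R_malignant` is
   the mean TPM profile of the malignant-cluster spots; every spot is
   re-correlated against it and the correlations are mapped to fractions.
   The default mapping rescales r linearly so that the mean of the bottom
   5% of spots (ceiling(0.05 n)) maps to 0 and the mean of the top 5% maps
   to 1, clipped to [0, 1] — the only mapping consistent with a "normalized
   to 0–1" fraction. A `literal` mode that divides r by the top–bottom
   range without shifting is available for comparison; it compresses but
   does not re-anchor the scale. `F_nonmalignant = 1 - F_malignant` holds
   exactly.

If no signature produces a malignant cluster, all malignant fractions are
zero and stage 2 receives the full budget — a tumor-free section is a valid
input.

# Stage 2 — hierarchical constrained deconvolution

With `R_malignant` and `F_malignant` fixed, the nonmalignant signal of a
spot is `S_nonmalignant = S - R_malignant * F_malignant` (negative entries
clipped to zero — TPM space is non-negative and stage 1 can slightly
overestimate). Level one solves, over the union of the major lineages'
marker genes,

    minimize || S_nonmalignant - sum_c R_c F_c ||^2
    subject to F_c >= 0, sum_c F_c <= F_nonmalignant

and defines `F_unidentifiable = 1 - F_malignant - sum_c F_c`, the budget
left unexplained. The unidentifiable component absorbs unknown cell types
and dropout noise; restricting the regression to marker space is what
justifies dropping the unknown-type term — marker genes of the atlas are by
construction lowly expressed in sufficiently different unknown types, so
their reference contribution is approximately zero there. The complement is
also the failure mode: an unknown type expressing a large share of the
marker space masquerades as known types and shrinks the unidentifiable
fraction (the `scenario_unknown()` stress test measures exactly this).

Level two repeats the solve within each sublineage family (e.g. M1/M2 under
macrophage): the level-one contributions of all *other* major lineages are
subtracted from `S_nonmalignant`, the residual is restricted to the family's
sublineage marker union, and the family's fractions are budgeted by the
parent's level-one fraction. Level-one estimates are held fixed rather than
re-estimated jointly; this is what confines collinearity among sublineages —
perturbing sibling reference profiles cannot move any level-one fraction,
whereas a flat one-level solve over all leaf types shifts major-lineage
totals (both shown in the test suite).

Our simulations also show the limits of that argument: on synthetic spots
whose ground truth literally mixes individual sublineage cells, the flat
solve is the correctly-specified model, and the parent-lineage RMSE of the
two schemes ties to within a few parts per thousand (the sum of collinear
non-negative coefficients is stable even when their split is not). The
hierarchy's benefit is the structural protection above plus stable
sublineage estimates, not a parent-level accuracy gain in this regime.

## The constrained solver

The sum-budget problem is solved exactly in two phases: a plain
Lawson–Hanson non-negative least squares first (if its solution respects
the budget it is the global optimum); otherwise, by convexity, the budget
binds, and the problem is re-solved with a non-negative slack variable and
a heavily weighted penalty row enforcing `sum(F) + slack = budget`
(weight `1e4 * max(|R|)`), followed by an exact projection back onto the
budget. A brute-force simplex-grid oracle (step 0.01) bounds the solver's
objective in the tests; conservation (`F_malignant + sum F_c +
F_unidentifiable = 1`) holds to 1e-9 by construction.

## Cancer-cell states

Spots with `F_malignant > 0.7` are re-clustered with the same silhouette
rule; each state's profile is the mean TPM profile of its spots, and
per-spot state fractions are estimated exactly like sublineages (constrained
solve with the malignant fraction as budget) over the most variable genes of
the selected spots. User-supplied module gene sets are scored as the mean
expression of their genes per spot.

# Stage 3 — colocalization and ligand–receptor evidence

Colocalization is the Spearman correlation of two cell types' estimated
fractions across spots, always read against the Spearman correlation of
their reference profiles so that lookalike references are not mistaken for
co-occurrence. Signaling evidence comes from a directed ligand–receptor
network: per spot, the network score

    NS = sum_i E_Li * E_Ri / < sum_i E_Li * E_Ri >_null

divides the sum of ligand-by-receptor expression products over the real
edges by the mean of the same sum over degree-preserving randomized
networks (directed double-edge swaps, 10 |E| attempts per network,
duplicate edges rejected — every ligand keeps its out-degree and every
receptor its in-degree exactly). Under uniform expression every edge product
is identical and NS = 1 identically, a property the tests assert exactly.
Empirical p values use the pseudo-counted form `(1 + #{null >= obs}) /
(1 + N)` and so are never zero. All interactions are scored within a spot;
no neighbor-spot terms are used.

For a candidate pair, spots are partitioned into colocalized (top 15% in
both fractions), either-dominated (top 15% in one, bottom 75% in the
other), and other, with nearest-rank quantiles and ties broken by spot
index so the categories always partition the spots. The pair is called
interacting when colocalized spots carry higher network scores than the
pooled dominated spots (two-sided Wilcoxon rank-sum p < 0.05 and pooled-SD
Cohen's d > 0).

Pair-level identification is a two-step screen designed to kill the two
false-positive categories: (1) Spearman correlation of ligand and receptor
across the colocalized spots, BH-adjusted over pairs, requiring adjusted
p < 0.05 and rho > 0 — this rejects pairs co-expressed only in single-cell
data without spatial proximity; (2) a CellPhoneDB-style single-cell score,
mean ligand expression in the sender type times mean receptor expression in
the receiver type, against a null of 1000 reshufflings of the two types'
cell labels — this rejects pairs that co-vary spatially but originate from
one cell type. Both directions are scored; a call requires step 1 plus a
permutation p < 0.05 in either direction.

Interface distances are Euclidean: each interaction spot's distance to its
nearest boundary spot, averaged, against a null of equal-size draws from
the dominated spots. Boundary spots are an explicit input — in real studies
they come from pathology annotation, and the package does not guess a
segmentation. A lattice-geodesic distance is a conceivable alternative on
hexagonal arrays; it is not implemented.

# The synthetic-data generator

The generator exists so that every stage is testable against planted ground
truth, offline. What it emulates, and how:

- **Cell types.** Each nonmalignant type is a log-normal baseline
  (meanlog = log 5, sdlog = 1) with a contiguous block of marker genes
  elevated `marker_fc`-fold (default 10). Sublineages sharing a parent share
  the parent's block and differ in small weaker blocks of their own, so
  sibling templates are strongly correlated, as real sublineages are.
  Cells are log-normal perturbations of their template
  (`noise_level` = 0.5 by default), TPM-normalized.
- **Malignant cells.** A dosage gradient over contiguous blocks of the
  non-marker gene range (values -1 … +1, emulating chromosome-arm
  gains/losses) multiplies the malignant template by `2^dosage`. Keeping
  the gradient off the marker blocks keeps the two planted signals
  orthogonal; when a random marker block lands on a strongly altered
  region, the marker term dominates the centered-profile variance and can
  even flip the sign of the CNA correlation — an instructive failure, but
  not a controllable ground truth.
- **Spots.** 1200 spots by default, in three malignant strata: 0% (500
  spots), 50% (200), 100% (500). Per spot, 1–3 nonmalignant types and 3–10
  cells are drawn, type weights come from a symmetric Dirichlet (α = 1 — a
  concentration the protocol leaves open; uniform over the simplex is the
  neutral choice), cells are allocated by largest-remainder rounding, and
  the selected cells' profiles are averaged. In the 50% stratum half the
  cells (rounding half up) are malignant — how "50%" is realized at the
  cell level is a generator decision, and the recorded ground truth is the
  realized cell-count proportion, not the nominal level. With several
  malignant states, each malignant spot draws its cells from one state.
  Spots are laid out row-major on a square lattice ordered by stratum, so
  the malignant region is contiguous and has an interface.
- **Planted colocalization.** An optional coupled pair shares a niche whose
  intensity varies per spot (a Beta(2, 2) share of the nonmalignant budget,
  split equally, with at least one filler type taking the rest). The filler
  matters: without it, coupled spots sit at the simplex boundary where the
  compositional constraint forces the pair's realized fractions to be
  *anti*-correlated (they only compete for rounding error), and no
  co-expression signal survives into the mixtures.
- **What is not emulated.** Platform artifacts (UMI saturation, spatially
  autocorrelated noise), per-spot sequencing-depth variation beyond the
  gene-downsampling utility, batch effects between datasets beyond library
  size and cell resampling, and any spatial smoothness of composition
  beyond the stratum layout. Passing the validation suite therefore shows
  the machinery is correct under its stated model, not that the model
  captures every property of real Visium data.

# Validation scenarios and problem sizes

The `scenario_*()` functions freeze the study conditions shared by the test
suite and `scripts/acceptance.R`: the benchmark study (6 types × 200 cells,
1000 genes, 1200 spots), the sublineage study (M1/M2 at reference
correlation ≥ 0.95, 380 spots × 10 seeds), the interaction study (7 types,
700 spots, 3 planted L–R pairs among expression-matched decoys plus one
same-cell-type pair, 200 rewired nulls and 500 permutations per run × 10
seeds), and the unknown-type study (elevated-gene overlap 10% vs 60% with
the reference marker union, 5 seeds each). These sizes were chosen as the
smallest at which the planted effects are comfortably detectable;
ligand–receptor and decoy genes are drawn from moderate-expression strata
because curated L–R lists contain signaling genes, not the heavy right tail
of housekeeping expression, and a single mega-expressed decoy product would
otherwise dominate every spot's network score.

# Numerical conventions

- TPM columns sum to 1e6; all-zero spots stay zero and are flagged.
- Degenerate correlations (constant vectors) are reported as r = 0 with a
  flag, never NA.
- Marker selection is limma one-vs-rest in `log2(TPM/10 + 1)` space: among
  overexpressed genes ranked by BH-adjusted p, the top 500 are screened at
  log2 fold change > 0.25 and adjusted p < 0.01. One-vs-rest (pooled
  others) was chosen over minimum-across-pairwise contrasts; for the
  planted fixtures both recover the same blocks.
- CNA signatures average patients after excluding the floor(n/4) lowest by
  total absolute CNA burden; expression signatures require ≥ 10 normal
  samples and are differences of group means in `log2(TPM/10 + 1)` space.
- Gene indices are opaque symbols; duplicate symbols collapse by summation
  at read time; datasets are intersected on shared genes before combining.

# Known limitations

- Stage 1 needs the CNA-driven (or tumor-vs-normal) expression footprint to
  dominate the spot-to-spot variance among malignant spots; chromosomally
  quiet tumors fall through to the expression and pan-cancer signatures
  with weaker guarantees.
- The unidentifiable component conflates unknown cell types with dropout;
  the two are separable only with external information.
- Level-two estimates inherit any level-one bias through the fixed
  subtraction of other lineages' contributions.
- Interaction evidence is within-spot co-expression; juxtacrine signaling
  across neighboring spots is invisible by design.
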