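# spotmix

Cell-type decomposition and cell–cell interaction mapping for tumor
spatial transcriptomics (ST).

Each ST spot captures a handful of cells, so its expression profile is a
mixture. In tumors the mixture is doubly hard: immune and stromal cells can
be described by a cross-patient reference atlas, but malignant cells are
patient-specific and match no external reference. spotmix is for
computational biologists analyzing tumor Visium/ST sections (or validating
deconvolution methodology) who need per-spot cell fractions **without a
matched malignant reference**, plus spatial evidence for cell–cell
signaling.

## The model

**Stage 1 — malignant fraction, reference-free.** Spots are clustered
(Ward/silhouette); each spot's mean-centered profile is correlated with a
cancer-type copy-number-alteration (CNA) signature (falling back to a
tumor-vs-normal expression signature, then a pan-cancer signature). Clusters
whose correlations are significantly positive, and enriched for significant
spots, are malignant. Their mean profile `R_malignant` re-scores all spots,
and correlations `r` are normalized by the top/bottom 5% means:

    F_malignant = clip( (r − r_bottom5%) / (r_top5% − r_bottom5%), 0, 1 )
    F_nonmalignant = 1 − F_malignant

**Stage 2 — hierarchical constrained deconvolution.** With
`S_nonmalignant = S − R_malignant · F_malignant` (clipped at 0), major
lineage fractions solve, over the reference marker-gene union,

    min ‖ S_nonmalignant − Σ_c R_c F_c ‖²   s.t.  F_c ≥ 0,  Σ_c F_c ≤ F_nonmalignant
    F_unidentifiable = 1 − F_malignant − Σ_c F_c

and sublineage families (e.g. F_M1 + F_M2 ≤ F_Macrophage) are solved at
level two with their parent's fraction as the budget, confining sublineage
collinearity away from the level above. The unidentifiable component
absorbs unknown cell types and dropout noise.

**Stage 3 — interactions.** Colocalization is the Spearman correlation of
fraction vectors (read against reference-profile similarity); per-spot
ligand–receptor activity is the network score

    NS = Σᵢ E_Li·E_Ri / ⟨ Σᵢ E_Li·E_Ri ⟩_rewired-nulls

with empirical p from degree-preserving rewired networks. A colocalized
pair is *interacting* when colocalized spots out-score single-type-dominated
spots (rank-sum p < 0.05, Cohen's d > 0); individual L–R pairs must pass
both a spatial co-expression step and a single-cell permutation step.

A synthetic-data module (`generate_synthetic_scrna`, `simulate_st`,
`generate_synthetic_dictionary`, plus `scenario_*()` studies) simulates
single-cell sets with planted markers and CNA gradients, Dirichlet spot
mixtures in three malignant strata (500/200/500 spots at 0%/50%/100%
malignant by default), and matching signature dictionaries — so the whole
pipeline validates offline against known ground truth.

## Worked example

```r
library(spotmix)

# simulate a small tumor section with known ground truth
sc   <- generate_synthetic_scrna(n_genes = 600, n_cells_per_type = 100, seed = 7)
sim  <- simulate_st(sc, simulation_design(
          n_spots_per_stratum = c("0" = 200, "50" = 80, "100" = 200), seed = 8))
dict <- generate_synthetic_dictionary(sc, "SYN")

# stage 1: malignant fractions from the CNA signature
mal <- infer_malignant_fraction(sim$st, dict, cancer_type = "SYN")
mal
#> <malignant_inference> 480 spots; signature mode: cna; K = 6; malignant clusters: 6
#>   mean F_malignant = 0.537

# stage 2: immune/stromal fractions by hierarchical constrained NNLS
ref <- build_hierarchical_reference(sc)
dec <- deconvolve_major(sim$st, ref, mal)
dec
#> <deconvolution_result> 480 spots x 5 major lineages
#>   mean fractions: malignant 0.537, identified 0.436, unidentifiable 0.027

# compare against the simulator's ground truth
evaluate_predictions(
  cbind(Malignant = dec$F_malignant, dec$level1),
  sim$truth$fractions, shuffle_seed = 1)
#> <evaluation_report>
#>    cell_type pearson_r       rmse degenerate
#>    Malignant 0.9807219 0.11657127      FALSE
#>          CAF 0.9914121 0.04029902      FALSE
#>  Endothelial 0.9935806 0.03161910      FALSE
#>        Bcell 0.9895013 0.05769209      FALSE
#>        Tcell 0.9898195 0.05451382      FALSE
#>   Macrophage 0.9914272 0.03983998      FALSE
#>   shuffled-control median r = -0.008
```

Reading the output: stage 1 identified the malignant spot cluster from the
planted CNA gradient (`mode: cna`) and its fraction estimates correlate
r = 0.98 with the simulator's true per-spot malignant content; the five
nonmalignant lineages are recovered at r ≈ 0.99 with RMSE 0.03–0.06, while
shuffling spot identities collapses the correlation to ≈ 0 — the recovery
is not an artifact of fraction distributions. Only 2.7% of the average
spot's budget lands in the unidentifiable component, as expected when the
reference covers every simulated type.

Stage 3 functions (`colocalization`, `rewire_network`, `network_score`,
`classify_spots_pair`, `test_pair_interaction`, `identify_lr_pairs`,
`interface_distance`) follow the same pattern; `scenario_interaction()`
runs the full planted-niche study in one call.

A thin command-line interface wrapping these functions ships at
`inst/cli/spotmix.R` (subcommands `simulate`, `build-dictionary`,
`build-reference`, `deconvolve`, `interactions`, `evaluate`; see
`Rscript <path> --help`).

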