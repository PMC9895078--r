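#' Validation scenarios
#'
#' Self-contained simulation studies exercising the full pipeline under
#' controlled, planted ground truth. They define the package's validation
#' conditions in one place, shared by the test suite and the acceptance
#' script. Each scenario derives all of its randomness from one `seed`.
#'
#' `scenario_benchmark()` is the reference study: the default six-type
#' single-cell set (200 cells/type, moderate noise), the default 1200-spot
#' design, a matching synthetic dictionary, stage-1 malignant inference, the
#' hierarchical reference, and level-1 deconvolution.
#'
#' @param seed integer; internal stage seeds are derived as small offsets.
#' @return A list with the scenario's single-cell set, simulation, reference
#'   and analysis results (fields vary by scenario; see each description).
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_benchmark <- function(seed = 11) {
  sc <- generate_synthetic_scrna(seed = seed)
  sim <- simulate_st(sc, simulation_design(seed = seed + 1))
  dict <- generate_synthetic_dictionary(sc)
  mal <- infer_malignant_fraction(sim$st, dict, cancer_type = "SYN")
  ref <- build_hierarchical_reference(sc)
  dec <- deconvolve_major(sim$st, ref, mal)
  list(sc = sc, sim = sim, dict = dict, mal = mal, ref = ref, dec = dec)
}

#' @rdname scenarios
#' @details `scenario_sublineage()` plants an M1/M2 macrophage family whose
#'   sibling references are strongly collinear (shared lineage block, weak
#'   state-specific markers), for comparing the hierarchical scheme with a
#'   flat one-level solve.
#' @export
scenario_sublineage <- function(seed) {
  hier <- c(Malignant = "Malignant", CAF = "CAF", Endothelial = "Endothelial",
            M1 = "Macrophage", M2 = "Macrophage")
  sc <- generate_synthetic_scrna(
    n_genes = 600, cell_types = names(hier), markers_per_type = 40,
    n_cells_per_type = 100, noise_level = 0.6, seed = seed,
    hierarchy = hier, marker_fc = 8,
    sublineage_markers_per_type = 6, sublineage_fc = 2)
  des <- simulation_design(
    n_spots_per_stratum = c("0" = 150, "50" = 80, "100" = 150),
    seed = seed + 100)
  sim <- simulate_st(sc, des)
  dict <- generate_synthetic_dictionary(sc)
  mal <- infer_malignant_fraction(sim$st, dict, "SYN")
  ref <- build_hierarchical_reference(sc)
  list(sc = sc, sim = sim, dict = dict, mal = mal, ref = ref)
}

#' @rdname scenarios
#' @details `scenario_interaction()` plants a CAF/M2-macrophage niche
#'   (coupled abundances) signaling through three planted ligand-receptor
#'   pairs among expression-matched decoys, plus one spatially co-varying
#'   pair confined to CAF cells (the false-positive category the two-step
#'   screen must reject). Runs stages 1-3 and the pair-level screen.
#' @param n_networks rewired null networks for the network score.
#' @param n_perm single-cell label permutations for the pair screen.
#' @export
scenario_interaction <- function(seed, n_networks = 200, n_perm = 500) {
  types <- c("Malignant", "CAF", "M2mac", "Tcell", "Bcell", "Endothelial",
             "DC")
  sc <- generate_synthetic_scrna(
    n_genes = 700, cell_types = types, markers_per_type = 40,
    n_cells_per_type = 100, noise_level = 0.25, seed = seed)
  des <- simulation_design(
    n_spots_per_stratum = c("0" = 400, "50" = 100, "100" = 200),
    n_cells_range = c(10, 20),
    coupled_pair = c("CAF", "M2mac"), coupling_prob = 0.7,
    seed = seed + 100)
  sim <- simulate_st(sc, des)
  dict <- generate_synthetic_dictionary(sc)
  mal <- infer_malignant_fraction(sim$st, dict, "SYN")
  ref <- build_hierarchical_reference(sc)
  dec <- deconvolve_major(sim$st, ref, mal)
  co <- colocalization(dec, ref)

  pick_mid <- function(genes, n) {
    b <- sc$meta$baseline[genes]
    genes[order(abs(b - stats::median(b)))][seq_len(n)]
  }
  ligs <- pick_mid(sc$meta$markers$CAF, 4)
  recs <- pick_mid(sc$meta$markers$M2mac, 3)
  same_lig <- ligs[4]
  same_rec <- pick_mid(setdiff(sc$meta$markers$CAF, ligs), 1)
  free <- paste0("g", 561:700)
  bl <- sc$meta$baseline
  pool <- free[bl[free] >= stats::quantile(bl[free], 0.3) &
                 bl[free] <= stats::quantile(bl[free], 0.7)]
  decoy <- withr::with_seed(999, data.frame(ligand = sample(pool, 10),
                                            receptor = sample(pool, 10)))
  net_ns <- lr_network(rbind(data.frame(ligand = ligs[1:3], receptor = recs),
                             decoy), rownames(sim$st$expr))
  net_lr <- lr_network(rbind(data.frame(ligand = c(ligs[1:3], same_lig),
                                        receptor = c(recs, same_rec)),
                             decoy), rownames(sim$st$expr))
  nulls <- rewire_network(net_ns, n_networks, seed = seed + 200)
  ns <- network_score(sim$st, net_ns, nulls)
  cats <- classify_spots_pair(dec, "CAF", "M2mac")
  tp <- test_pair_interaction(ns$ns, cats)
  lr <- identify_lr_pairs(sim$st, cats, sc, "CAF", "M2mac", net_lr,
                          n_perm = n_perm, seed = seed + 300)
  list(sc = sc, sim = sim, dec = dec, co = co, ns = ns, cats = cats,
       tp = tp, lr = lr, planted_idx = 1:3, same_idx = 4)
}

#' @rdname scenarios
#' @details `scenario_unknown()` simulates spots containing a cell type
#'   absent from the reference whose expression elevates a controlled
#'   fraction of the reference marker genes, and reports the median
#'   known-type recovery correlation plus the correlation between the
#'   unidentifiable fraction and the unknown type's true fraction.
#' @param overlap fraction of the unknown type's elevated genes drawn from
#'   the reference marker union.
#' @export
scenario_unknown <- function(seed, overlap) {
  types <- c("Malignant", "CAF", "Endothelial", "Bcell", "Tcell")
  sc0 <- generate_synthetic_scrna(
    n_genes = 700, cell_types = types, markers_per_type = 40,
    n_cells_per_type = 120, noise_level = 0.5, seed = seed)
  ref <- build_hierarchical_reference(sc0)
  marker_union <- unique(unlist(ref$markers))
  sc1 <- add_unknown_type(sc0, marker_union, overlap, n_cells = 120,
                          n_elevated = 150, seed = seed + 400)
  des <- simulation_design(
    n_spots_per_stratum = c("0" = 200, "50" = 80, "100" = 120),
    seed = seed + 100)
  sim <- simulate_st(sc1, des)
  dict <- generate_synthetic_dictionary(sc0)
  mal <- infer_malignant_fraction(sim$st, dict, "SYN")
  dec <- deconvolve_major(sim$st, ref, mal)
  rs <- vapply(colnames(dec$level1), function(tp)
    stats::cor(dec$level1[, tp], sim$truth$fractions[, tp]), numeric(1))
  list(sc = sc1, sim = sim, dec = dec,
       median_r = stats::median(rs),
       unid_r = stats::cor(dec$F_unidentifiable,
                           sim$truth$fractions[, "Unknown"]))
}
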