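#' Cell-type colocalization and reference-similarity matrices
#'
#' Colocalization is the Spearman correlation of estimated cell-type
#' fractions across spots, for every cell-type pair. To rule out apparent
#' colocalization caused by similar reference profiles, the Spearman
#' correlation between the types' reference profiles is computed alongside;
#' pairs with high colocalization but low reference similarity are flagged
#' as candidates.
#'
#' @param result a `deconvolution_result` (level-1 fractions are used).
#' @param reference a [hier_reference()].
#' @param coloc_min,ref_max thresholds flagging candidate pairs.
#' @return List with `coloc` (symmetric, unit diagonal), `ref_similarity`,
#'   and `candidates` (data.frame of flagged pairs).
#' @export
colocalization <- function(result, reference, coloc_min = 0.3, ref_max = 0.5) {
  fr <- result$level1
  if (nrow(fr) < 10) stop("need >= 10 spots for colocalization")
  types <- colnames(fr)
  constant <- apply(fr, 2, function(v) max(v) == min(v))
  coloc <- suppressWarnings(stats::cor(fr, method = "spearman"))
  coloc[is.na(coloc)] <- 0
  diag(coloc) <- 1
  if (any(constant)) {
    warning("constant fraction vectors (correlation set to 0 off-diagonal): ",
            paste(types[constant], collapse = ", "))
  }
  prof <- reference$profiles[, types, drop = FALSE]
  ref_sim <- suppressWarnings(stats::cor(prof, method = "spearman"))
  ref_sim[is.na(ref_sim)] <- 0
  diag(ref_sim) <- 1
  pairs <- which(upper.tri(coloc) & coloc > coloc_min & ref_sim < ref_max,
                 arr.ind = TRUE)
  candidates <- data.frame(type_a = types[pairs[, 1]],
                           type_b = types[pairs[, 2]],
                           coloc = coloc[pairs],
                           ref_similarity = ref_sim[pairs])
  candidates <- candidates[order(-candidates$coloc), , drop = FALSE]
  rownames(candidates) <- NULL
  list(coloc = coloc, ref_similarity = ref_sim, candidates = candidates)
}

#' Degree-preserving randomizations of a ligand-receptor network
#'
#' Each randomized network is produced by directed double-edge swaps: two
#' edges (L1 -> R1, L2 -> R2) are repeatedly chosen at random and their
#' receptor endpoints exchanged, rejecting swaps that would duplicate an
#' existing edge. `swap_factor * |edges|` swaps are attempted per network,
#' so every ligand keeps its out-degree and every receptor its in-degree
#' exactly.
#'
#' @param net an [lr_network()].
#' @param n_networks number of randomized networks (the null ensemble).
#' @param seed integer seed.
#' @param swap_factor attempted swaps per edge (default 10).
#' @return List of [lr_network()] objects.
#' @export
rewire_network <- function(net, n_networks, seed = 1, swap_factor = 10) {
  if (n_networks < 1) stop("n_networks must be >= 1")
  m <- nrow(net$edges)
  if (m < 2) {
    warning("fewer than 2 edges; randomizations equal the original network")
    return(replicate(n_networks, net, simplify = FALSE))
  }
  lig <- net$edges$ligand
  rec <- net$edges$receptor
  n_attempts <- swap_factor * m
  withr::with_seed(seed, {
    lapply(seq_len(n_networks), function(i) {
      r <- rec
      key <- paste(lig, r)
      for (a in seq_len(n_attempts)) {
        ij <- sample.int(m, 2)
        i1 <- ij[1]; i2 <- ij[2]
        if (r[i1] == r[i2]) next
        k1 <- paste(lig[i1], r[i2]); k2 <- paste(lig[i2], r[i1])
        if (k1 %in% key || k2 %in% key) next
        key[c(i1, i2)] <- c(k1, k2)
        tmp <- r[i1]; r[i1] <- r[i2]; r[i2] <- tmp
      }
      lr_network(data.frame(ligand = lig, receptor = r),
                 net$gene_universe)
    })
  })
}

#' Per-spot ligand-receptor network score with empirical p values
#'
#' For each spot, the network score NS is the sum of ligand x receptor
#' expression products over the real edges, divided by the mean of the same
#' sum over the randomized networks. The empirical p value is the
#' pseudo-counted tail probability that a randomized network's sum reaches
#' the real one: (1 + #\{sum_random >= sum_real\}) / (1 + n_networks), so it
#' is never exactly 0. Spots whose null mean is 0 get NS = NA and p = 1.
#'
#' @param st a [spatial_expr()].
#' @param net an [lr_network()]; edges with genes absent from `st` are
#'   ignored (with the same filtering applied to the null networks).
#' @param randomized_nets list of networks from [rewire_network()].
#' @return List with `ns` and `p` per spot, plus `n_edges` used.
#' @export
network_score <- function(st, net, randomized_nets) {
  if (length(randomized_nets) == 0) stop("randomized_nets must be nonempty")
  genes <- rownames(st$expr)
  edge_sum <- function(e) {
    keep <- e$ligand %in% genes & e$receptor %in% genes
    e <- e[keep, , drop = FALSE]
    if (nrow(e) == 0) return(rep(0, ncol(st$expr)))
    colSums(st$expr[e$ligand, , drop = FALSE] *
              st$expr[e$receptor, , drop = FALSE])
  }
  real <- edge_sum(net$edges)
  null_sums <- vapply(randomized_nets, function(nn) edge_sum(nn$edges),
                      numeric(ncol(st$expr)))
  if (is.null(dim(null_sums))) null_sums <- matrix(null_sums, nrow = 1)
  null_mean <- rowMeans(null_sums)
  ns <- ifelse(null_mean > 0, real / null_mean, NA_real_)
  exceed <- rowSums(null_sums >= real)
  p <- (1 + exceed) / (1 + length(randomized_nets))
  p[null_mean == 0] <- 1
  names(ns) <- names(p) <- colnames(st$expr)
  list(ns = ns, p = p,
       n_edges = sum(net$edges$ligand %in% genes &
                       net$edges$receptor %in% genes))
}

#' Classify spots by the joint abundance of a cell-type pair
#'
#' Spots in the top `top_q` quantile of both types' fractions are
#' "colocalized"; top in A but bottom `bottom_q` in B are "A-dominated"
#' (and symmetrically); everything else is "other". Quantiles are
#' nearest-rank on the fraction order, ties broken by spot index, so the
#' categories always partition the spots.
#'
#' @param result a `deconvolution_result`; types are looked up in level-1
#'   then level-2 fractions.
#' @param typeA,typeB cell-type names.
#' @param top_q,bottom_q quantile parameters (defaults 0.15 and 0.75).
#' @return Named factor over spots with levels `colocalized`,
#'   `A_dominated`, `B_dominated`, `other`.
#' @export
classify_spots_pair <- function(result, typeA, typeB,
                                top_q = 0.15, bottom_q = 0.75) {
  get_frac <- function(tp) {
    if (tp %in% colnames(result$level1)) return(result$level1[, tp])
    if (!is.null(result$level2) && tp %in% colnames(result$level2)) {
      return(result$level2[, tp])
    }
    stop("cell type absent from deconvolution result: ", tp)
  }
  fA <- get_frac(typeA); fB <- get_frac(typeB)
  n <- length(fA)
  spots <- rownames(result$level1)
  if (max(fA) == min(fA) || max(fB) == min(fB)) {
    warning("degenerate fraction distribution; all spots classified 'other'")
    return(stats::setNames(factor(rep("other", n),
                                  levels = c("colocalized", "A_dominated",
                                             "B_dominated", "other")), spots))
  }
  rank_desc <- function(f) order(order(-f, seq_len(n)))
  k_top <- ceiling(top_q * n)
  k_bottom <- ceiling(bottom_q * n)
  topA <- rank_desc(fA) <= k_top
  topB <- rank_desc(fB) <= k_top
  botA <- (n + 1 - rank_desc(fA)) <= k_bottom  # ascending rank in bottom set
  botB <- (n + 1 - rank_desc(fB)) <= k_bottom
  cat_lab <- rep("other", n)
  cat_lab[topA & botB] <- "A_dominated"
  cat_lab[topB & botA] <- "B_dominated"
  cat_lab[topA & topB] <- "colocalized"
  stats::setNames(factor(cat_lab, levels = c("colocalized", "A_dominated",
                                             "B_dominated", "other")), spots)
}

#' Test whether colocalized spots carry stronger L-R activity
#'
#' Compares the network scores of colocalized spots against the pooled
#' single-type-dominated spots with a two-sided Wilcoxon rank-sum test, and
#' reports Cohen's d (pooled-SD form). The pair is called interacting when
#' p < alpha and d > 0 (colocalized spots score higher).
#'
#' @param ns per-spot network scores from [network_score()].
#' @param categories factor from [classify_spots_pair()].
#' @param alpha significance level (default 0.05).
#' @param min_n minimum group size (default 3).
#' @return List with `cohens_d`, `p`, `interacting`, group sizes, and a
#'   `reason` when the test is skipped.
#' @export
test_pair_interaction <- function(ns, categories, alpha = 0.05, min_n = 3) {
  x <- ns[categories == "colocalized"]
  y <- ns[categories %in% c("A_dominated", "B_dominated")]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < min_n || length(y) < min_n) {
    return(list(cohens_d = NA_real_, p = NA_real_, interacting = FALSE,
                n_colocalized = length(x), n_dominated = length(y),
                reason = "group smaller than min_n"))
  }
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  d <- if (sp > 0) (mean(x) - mean(y)) / sp else 0
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  list(cohens_d = d, p = p, interacting = is.finite(p) && p < alpha && d > 0,
       n_colocalized = length(x), n_dominated = length(y), reason = NULL)
}

#' Identify the ligand-receptor pairs mediating a cell-type interaction
#'
#' Two-step screen combining spatial and single-cell evidence, so that
#' neither co-expression without distinct cell sources nor single-cell
#' co-expression without spatial proximity produces a call. Step 1: Spearman
#' correlation of ligand and receptor expression across the colocalized
#' spots, BH-adjusted over pairs; pairs with adjusted p < alpha and rho > 0
#' proceed. Step 2: in the single-cell data, the pair is scored as (mean
#' ligand expression in the sender type) x (mean receptor expression in the
#' receiver type); the label-shuffling null redistributes the two types'
#' cells `n_perm` times and the pseudo-counted tail probability is the
#' permutation p. Both directions (A->B and B->A) are scored; the pair is
#' called when step 1 passes and either direction's permutation p < alpha.
#'
#' @param st a [spatial_expr()].
#' @param categories factor from [classify_spots_pair()].
#' @param sc_sets a [single_cell_set()] or list of them (cells of the two
#'   types are pooled across sets).
#' @param typeA,typeB the interacting cell types (A is the reference sender).
#' @param net an [lr_network()] of candidate pairs.
#' @param n_perm label permutations (default 1000).
#' @param seed integer seed.
#' @param alpha significance level for both steps.
#' @return data.frame, one row per testable pair: spatial rho/p/adjusted p,
#'   single-cell scores and permutation p for both directions, and `called`.
#' @export
identify_lr_pairs <- function(st, categories, sc_sets, typeA, typeB, net,
                              n_perm = 1000, seed = 1, alpha = 0.05) {
  coloc_spots <- names(categories)[categories == "colocalized"]
  if (length(coloc_spots) == 0) stop("no colocalized spots")
  if (inherits(sc_sets, "single_cell_set")) sc_sets <- list(sc_sets)

  genes_st <- rownames(st$expr)
  edges <- net$edges[net$edges$ligand %in% genes_st &
                       net$edges$receptor %in% genes_st, , drop = FALSE]
  if (nrow(edges) == 0) stop("no L-R pair measurable in the ST data")
  E <- st$expr[, coloc_spots, drop = FALSE]
  rho <- p_rho <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    lv <- E[edges$ligand[i], ]; rv <- E[edges$receptor[i], ]
    if (stats::sd(lv) == 0 || stats::sd(rv) == 0) {
      rho[i] <- 0; p_rho[i] <- 1
    } else {
      ct <- suppressWarnings(stats::cor.test(lv, rv, method = "spearman",
                                             exact = FALSE))
      rho[i] <- unname(ct$estimate); p_rho[i] <- ct$p.value
    }
  }
  p_adj <- stats::p.adjust(p_rho, method = "BH")
  step1 <- p_adj < alpha & rho > 0

  # Pool single cells of the two types across sets (shared genes).
  genes_sc <- Reduce(intersect, lapply(sc_sets, function(s) rownames(s$expression)))
  pool <- lapply(sc_sets, function(s) {
    idx <- s$cell_type %in% c(typeA, typeB)
    list(expr = s$expression[genes_sc, idx, drop = FALSE],
         label = s$cell_type[idx])
  })
  sc_expr <- do.call(cbind, lapply(pool, `[[`, "expr"))
  sc_label <- unlist(lapply(pool, `[[`, "label"))
  if (!all(c(typeA, typeB) %in% sc_label)) {
    stop("single-cell sets must contain cells of both types")
  }
  nA <- sum(sc_label == typeA)
  n_cells <- length(sc_label)

  measurable <- edges$ligand %in% genes_sc & edges$receptor %in% genes_sc
  if (any(!measurable)) {
    message(sum(!measurable), " pair(s) skipped: gene absent from single-cell data")
  }
  score_ab <- p_ab <- score_ba <- p_ba <- rep(NA_real_, nrow(edges))
  test_idx <- which(step1 & measurable)
  if (length(test_idx)) {
    need <- unique(c(edges$ligand[test_idx], edges$receptor[test_idx]))
    Esc <- sc_expr[need, , drop = FALSE]
    isA <- sc_label == typeA
    withr::with_seed(seed, {
      # indicator matrix of permuted type-A membership, cells x perms
      P <- vapply(seq_len(n_perm), function(i) {
        z <- logical(n_cells); z[sample.int(n_cells, nA)] <- TRUE; z
      }, logical(n_cells))
    })
    meanA_perm <- (Esc %*% P) / nA                 # genes x perms
    meanB_perm <- (Esc %*% (1 - P)) / (n_cells - nA)
    meanA <- rowMeans(Esc[, isA, drop = FALSE])
    meanB <- rowMeans(Esc[, !isA, drop = FALSE])
    for (i in test_idx) {
      lg <- edges$ligand[i]; rg <- edges$receptor[i]
      score_ab[i] <- meanA[lg] * meanB[rg]
      score_ba[i] <- meanB[lg] * meanA[rg]
      null_ab <- meanA_perm[lg, ] * meanB_perm[rg, ]
      null_ba <- meanB_perm[lg, ] * meanA_perm[rg, ]
      p_ab[i] <- (1 + sum(null_ab >= score_ab[i])) / (1 + n_perm)
      p_ba[i] <- (1 + sum(null_ba >= score_ba[i])) / (1 + n_perm)
    }
  }
  called <- step1 & measurable &
    (pmin(p_ab, p_ba, na.rm = TRUE) < alpha)
  called[is.na(called)] <- FALSE
  data.frame(ligand = edges$ligand, receptor = edges$receptor,
             rho = rho, p = p_rho, p_adj = p_adj, step1 = step1,
             score_ab = score_ab, p_ab = p_ab,
             score_ba = score_ba, p_ba = p_ba,
             called = called, row.names = NULL)
}

#' Distance of interaction spots to a tissue interface
#'
#' The distance of a spot to the interface is the Euclidean distance to its
#' nearest boundary spot; the statistic is the mean over the interaction
#' spots. The null repeatedly draws the same number of spots from the
#' single-type-dominated pool; the empirical p is the pseudo-counted
#' probability that a null draw lies at least as close to the interface.
#'
#' @param coords data.frame with columns `x`, `y` and spot ids as rownames.
#' @param interaction_spots,boundary_spots,dominated_spots spot id vectors.
#' @param n_rand null draws (default 1000).
#' @param seed integer seed.
#' @return List with `observed` (mean distance), `distances` (per
#'   interaction spot), `null` (vector of null means) and `p`.
#' @export
interface_distance <- function(coords, interaction_spots, boundary_spots,
                               dominated_spots, n_rand = 1000, seed = 1) {
  if (length(boundary_spots) == 0) stop("boundary_spots must be nonempty")
  xy <- as.matrix(coords[, c("x", "y")])
  rownames(xy) <- rownames(coords)
  bxy <- xy[boundary_spots, , drop = FALSE]
  min_dist <- function(ids) {
    sxy <- xy[ids, , drop = FALSE]
    d2 <- outer(rowSums(sxy^2), rowSums(bxy^2), "+") - 2 * sxy %*% t(bxy)
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  dist_obs <- min_dist(interaction_spots)
  observed <- mean(dist_obs)
  k <- length(interaction_spots)
  replace <- k > length(dominated_spots)
  if (replace) warning("dominated pool smaller than interaction set; sampling with replacement")
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      ids <- sample(dominated_spots, k, replace = replace)
      mean(min_dist(ids))
    }, numeric(1))
  })
  p <- (1 + sum(null <= observed)) / (1 + n_rand)
  list(observed = observed, distances = dist_obs, null = null, p = p)
}
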