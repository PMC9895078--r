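test_that("the silhouette rule picks the K preceding the largest drop", {
  # stated example: s(2..5) = 0.40, 0.55, 0.54, 0.20 -> the largest drop is
  # from K=4 to K=5, so K=4 is chosen
  expect_equal(choose_k_by_silhouette(c(0.40, 0.55, 0.54, 0.20), 2:5), 4)
  # non-decreasing silhouettes: fall back to the argmax
  expect_equal(choose_k_by_silhouette(c(0.2, 0.3, 0.45), 2:4), 4)
  # single candidate
  expect_equal(choose_k_by_silhouette(0.5, 3), 3)
})

test_that("well-separated blobs are clustered at the right K", {
  set.seed(77)
  blob <- function(center, n) {
    matrix(stats::rlnorm(60 * n, log(center), 0.1), 60, n)
  }
  expr <- cbind(blob(c(rep(200, 30), rep(5, 30)), 25),
                blob(c(rep(5, 30), rep(200, 30)), 25))
  rownames(expr) <- paste0("g", 1:60)
  st <- spatial_expr(expr * 1e6 / mean(colSums(expr)))
  cl <- cluster_spots(st, k_range = 2:6, n_var_genes = 60)
  expect_equal(cl$K, 2)
  lab <- cl$labels
  expect_length(unique(lab[1:25]), 1)
  expect_length(unique(lab[26:50]), 1)
  expect_false(lab[1] == lab[26])
})

test_that("three planted spot populations are found across seeded runs", {
  hits <- 0
  for (run in 1:20) {
    sc <- generate_synthetic_scrna(
      n_genes = 300, cell_types = c("CAF", "Tcell", "Bcell"),
      markers_per_type = 30, n_cells_per_type = 30, noise_level = 0.3,
      seed = 700 + run)
    # one dominant type per spot: three separable populations
    sim <- simulate_st(sc, simulation_design(
      n_spots_per_stratum = c("0" = 90, "50" = 0, "100" = 0),
      n_types_range = c(1, 1), seed = 800 + run))
    cl <- cluster_spots(sim$st, k_range = 2:6, n_var_genes = 200)
    if (cl$K == 3) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of 20 runs
})

test_that("spot-signature correlations match direct Pearson computation", {
  genes <- paste0("g", 1:5)
  sig <- c(g1 = 2, g2 = -1, g3 = 0.5, g4 = 0, g5 = -1.5)
  expr <- matrix(stats::rlnorm(5 * 30, log(50), 1), 5, 30,
                 dimnames = list(genes, paste0("s", 1:30)))
  st <- spatial_expr(expr)
  out <- correlate_signature(st, sig, min_genes = 5)
  centered <- expr - rowMeans(expr)
  for (s in c(1, 17, 30)) {
    x <- centered[, s]; y <- sig
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(out$r[s]), r_hand, tolerance = 1e-12)
  }
  # a spot constructed so its centered profile is exactly a positive
  # multiple of the signature (accounting for its own effect on the mean)
  expr2 <- expr
  expr2[, 1] <- rowMeans(expr2[, -1]) + (30 / 29) * 3 * sig
  out2 <- correlate_signature(spatial_expr(expr2), sig, min_genes = 5)
  expect_equal(unname(out2$r[1]), 1, tolerance = 1e-9)
  # constant signature: flagged degenerate, r = 0, p = 1
  outc <- correlate_signature(st, c(g1 = 1, g2 = 1, g3 = 1, g4 = 1, g5 = 1),
                              min_genes = 5)
  expect_true(all(outc$degenerate))
  expect_true(all(outc$r == 0) && all(outc$p == 1))
  # insufficient overlap is refused with the overlap size named
  expect_error(correlate_signature(st, sig[1:3], min_genes = 5), "3 genes")
})

test_that("malignant cluster calling applies both criteria", {
  # planted: cluster 1 (6 spots, the smallest size whose one-sided exact
  # signed-rank test can reach p < 0.05) strongly positive, others null
  set.seed(12)
  labels <- c(rep(1, 6), rep(2, 10), rep(3, 10))
  r <- c(stats::runif(6, 0.6, 0.9), stats::rnorm(20, 0, 0.05))
  p <- c(stats::runif(6, 1e-4, 0.002), stats::runif(20, 0.2, 1))
  expect_equal(identify_malignant_clusters(labels, r, p), 1L)
  # an all-negative cluster fails the signed-rank requirement
  r2 <- c(-r[1:6], r[7:26])
  expect_length(identify_malignant_clusters(labels, r2, p), 0)
  # equally-correlated spots: the strict enrichment inequality fails everywhere
  r3 <- rep(0.5, 26); p3 <- rep(0.001, 26)
  expect_length(identify_malignant_clusters(labels, r3, p3), 0)
  # clusters below 3 spots are excluded with a warning
  expect_warning(identify_malignant_clusters(c(1, 1, rep(2, 10)),
                                             rep(0.5, 12), rep(0.5, 12)),
                 "fewer than 3")
})

test_that("correlation normalization maps the 5% tail means onto [0, 1]", {
  set.seed(5)
  r <- stats::runif(100, -0.5, 0.9)
  out <- normalize_correlations(r)
  # independent direct evaluation
  k <- ceiling(0.05 * 100)
  sr <- sort(r)
  rb <- mean(sr[1:k]); rt <- mean(sr[(100 - k + 1):100])
  expect_equal(out$r_bottom5, rb)
  expect_equal(out$r_top5, rt)
  expect_equal(out$fraction, pmin(pmax((r - rb) / (rt - rb), 0), 1))
  # endpoints: the extremes clip to exactly 0 and 1
  expect_equal(unname(out$fraction[which.min(r)]), 0)
  expect_equal(unname(out$fraction[which.max(r)]), 1)
  # literal mode divides without shifting
  lit <- normalize_correlations(r, mode = "literal")
  expect_equal(lit$fraction, pmin(pmax(r / (rt - rb), 0), 1))
  # evenly spaced example re-evaluated independently
  r2 <- seq(-1, 1, length.out = 100)
  out2 <- normalize_correlations(r2)
  k2 <- 5
  rb2 <- mean(sort(r2)[1:k2]); rt2 <- mean(sort(r2)[96:100])
  expect_equal(out2$fraction, pmin(pmax((r2 - rb2) / (rt2 - rb2), 0), 1))
  # monotonicity
  expect_true(all(diff(out2$fraction[order(r2)]) >= 0))
  # degenerate range
  expect_error(normalize_correlations(rep(0.3, 50)), "degenerate")
  expect_error(normalize_correlations(stats::runif(10)), ">= 20 spots")
})

test_that("stage 1 recovers malignant fractions on simulated tumors", {
  x <- main_pipeline()
  truth <- x$sim$truth$fractions[, "Malignant"]
  expect_equal(x$mal$mode, "cna")
  expect_gte(stats::cor(x$mal$F_malignant, truth), 0.9)
  strata_means <- tapply(x$mal$F_malignant, x$sim$truth$stratum, mean)
  expect_gt(strata_means[["100"]], strata_means[["50"]])
  expect_gt(strata_means[["50"]], strata_means[["0"]])
  # exact complement
  expect_equal(x$mal$F_malignant + x$mal$F_nonmalignant,
               stats::setNames(rep(1, length(x$mal$F_malignant)),
                               names(x$mal$F_malignant)))
  # R_malignant is the column mean over malignant-cluster spots
  mal_spots <- x$mal$cluster_labels %in% x$mal$malignant_clusters
  expect_equal(x$mal$R_malignant,
               rowMeans(x$sim$st$expr[, mal_spots]), tolerance = 1e-12)
})

test_that("a zeroed CNA column activates the expression signature fallback", {
  x <- main_pipeline()
  dict0 <- x$dict
  dict0$cna[, "SYN"] <- 0
  mal <- infer_malignant_fraction(x$sim$st, dict0, "SYN")
  expect_equal(mal$mode, "expression")
  expect_gte(stats::cor(mal$F_malignant, x$sim$truth$fractions[, "Malignant"]),
             0.8)
})

test_that("an absent cancer type falls back to the pan-cancer signature", {
  x <- main_pipeline()
  mal <- infer_malignant_fraction(x$sim$st, x$dict, "NOT_IN_DICT")
  expect_equal(mal$mode, "pan_cancer")
  expect_gte(stats::cor(mal$F_malignant, x$sim$truth$fractions[, "Malignant"]),
             0.8)
})

test_that("stage 1 without any malignant signal yields zero fractions", {
  sc <- generate_synthetic_scrna(
    n_genes = 400, cell_types = c("CAF", "Tcell", "Bcell"),
    markers_per_type = 30, n_cells_per_type = 40, noise_level = 0.4, seed = 9)
  sim <- simulate_st(sc, simulation_design(
    n_spots_per_stratum = c("0" = 120, "50" = 0, "100" = 0), seed = 10))
  # a signature of pure noise, unrelated to any spot structure
  dict <- signature_dictionary(
    expr = matrix(withr::with_seed(1, stats::rnorm(400)), ncol = 1,
                  dimnames = list(rownames(sim$st$expr), "X")))
  mal <- infer_malignant_fraction(sim$st, dict, "X")
  expect_equal(mal$mode, "none")
  expect_true(all(mal$F_malignant == 0))
  expect_true(all(mal$F_nonmalignant == 1))
  # downstream deconvolution proceeds on the full budget
  ref <- build_hierarchical_reference(sc)
  dec <- deconvolve_major(sim$st, ref, mal)
  expect_true(all(abs(dec$F_malignant + rowSums(dec$level1) +
                        dec$F_unidentifiable - 1) < 1e-9))
})

test_that("stage 1 is invariant to spot order", {
  x <- subl_pipeline()
  st <- x$sim$st
  perm <- withr::with_seed(3, sample(ncol(st$expr)))
  stp <- spatial_expr(st$expr[, perm], st$coords[perm, ])
  dict <- generate_synthetic_dictionary(x$sc)
  m1 <- infer_malignant_fraction(st, dict, "SYN")
  m2 <- infer_malignant_fraction(stp, dict, "SYN")
  expect_equal(unname(m2$F_malignant), unname(m1$F_malignant[perm]),
               tolerance = 1e-8)
})
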