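make_result <- function(level1) {
  structure(list(level1 = level1, level2 = NULL), class = "deconvolution_result")
}

test_that("colocalization is the Spearman correlation of fraction vectors", {
  set.seed(3)
  n <- 40
  fA <- stats::runif(n)
  level1 <- cbind(A = fA, B = fA, C = 1 - rank(fA) / n, D = stats::runif(n))
  rownames(level1) <- paste0("s", 1:n)
  prof <- matrix(stats::rlnorm(30 * 4, log(50), 1), 30, 4,
                 dimnames = list(paste0("g", 1:30), colnames(level1)))
  ref <- hier_reference(prof, stats::setNames(
    rep(list(character(0)), 4), colnames(level1)),
    stats::setNames(colnames(level1), colnames(level1)))
  co <- colocalization(make_result(level1), ref)
  expect_equal(co$coloc["A", "B"], 1)       # identical fractions
  expect_equal(co$coloc["A", "C"], -1)      # exactly reversed ranks
  expect_equal(co$coloc, t(co$coloc))       # symmetry
  expect_true(all(diag(co$coloc) == 1))
  # a constant fraction vector is flagged and zeroed
  level1c <- cbind(level1, E = rep(0.1, n))
  profc <- cbind(prof, E = prof[, 1])
  refc <- hier_reference(profc, stats::setNames(
    rep(list(character(0)), 5), colnames(level1c)),
    stats::setNames(colnames(level1c), colnames(level1c)))
  expect_warning(coc <- colocalization(make_result(level1c), refc), "constant")
  expect_equal(unname(coc$coloc["E", "A"]), 0)
})

test_that("a planted co-occurring pair shows the largest colocalization", {
  # nonmalignant-only simulations deconvolved with a null stage-1 result
  hits <- 0
  for (run in 1:20) {
    sc <- generate_synthetic_scrna(
      n_genes = 400, cell_types = c("CAF", "Macrophage", "Tcell", "Bcell",
                                    "Endothelial"),
      markers_per_type = 30, n_cells_per_type = 60, noise_level = 0.4,
      seed = 900 + run)
    sim <- simulate_st(sc, simulation_design(
      n_spots_per_stratum = c("0" = 200, "50" = 0, "100" = 0),
      n_cells_range = c(8, 16),
      coupled_pair = c("CAF", "Macrophage"), coupling_prob = 0.8,
      seed = 950 + run))
    ref <- build_hierarchical_reference(sc)
    mal0 <- structure(list(
      F_malignant = stats::setNames(rep(0, 200), colnames(sim$st$expr)),
      F_nonmalignant = stats::setNames(rep(1, 200), colnames(sim$st$expr)),
      R_malignant = NULL, mode = "none"), class = "malignant_inference")
    dec <- deconvolve_major(sim$st, ref, mal0)
    co <- colocalization(dec, ref)
    cm <- co$coloc; diag(cm) <- NA
    best <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    if (setequal(colnames(cm)[best], c("CAF", "Macrophage"))) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("rewiring preserves directed degree sequences exactly", {
  edges <- data.frame(ligand = c("A", "C"), receptor = c("B", "D"))
  net <- lr_network(edges)
  # the only legal swap of {A->B, C->D} is {A->D, C->B}
  rw <- rewire_network(net, 20, seed = 1)
  for (x in rw) {
    expect_true(identical(sort(paste(x$edges$ligand, x$edges$receptor)),
                          c("A B", "C D")) ||
                  identical(sort(paste(x$edges$ligand, x$edges$receptor)),
                            c("A D", "C B")))
    expect_identical(degree_signature(x$edges), degree_signature(edges))
  }
  # a single-edge network cannot be rewired
  single <- lr_network(data.frame(ligand = "A", receptor = "B"))
  expect_warning(rw1 <- rewire_network(single, 3, seed = 1), "fewer than 2")
  expect_identical(rw1[[1]]$edges, single$edges)
})

test_that("every rewired network lies in the enumerated null space", {
  edges <- data.frame(ligand = c("L1", "L2", "L3"),
                      receptor = c("R1", "R2", "R3"))
  net <- lr_network(edges)
  universe <- enumerate_rewirings(edges)
  keys <- vapply(universe, function(e)
    paste(sort(paste(e$ligand, e$receptor)), collapse = "|"), character(1))
  rw <- rewire_network(net, 50, seed = 7)
  for (x in rw) {
    k <- paste(sort(paste(x$edges$ligand, x$edges$receptor)), collapse = "|")
    expect_true(k %in% keys)
    expect_identical(degree_signature(x$edges), degree_signature(edges))
  }
  # with 3 distinct ligands and receptors there are 3! = 6 legal networks
  expect_length(universe, 6)
})

test_that("network scores are 1 under uniform expression and match enumeration", {
  genes <- c("L1", "L2", "R1", "R2")
  edges <- data.frame(ligand = c("L1", "L1", "L2"),
                      receptor = c("R1", "R2", "R2"))
  net <- lr_network(edges)
  # uniform expression: every edge product equals e^2, NS = 1 exactly
  stu <- spatial_expr(matrix(7, 4, 5, dimnames = list(genes, paste0("s", 1:5))))
  rw <- rewire_network(net, 25, seed = 3)
  nsu <- network_score(stu, net, rw)
  expect_true(all(nsu$ns == 1))
  # single-edge network: nulls are identical to the real network
  net1 <- lr_network(edges[1, ])
  expect_warning(rw1 <- rewire_network(net1, 10, seed = 4), "fewer than 2")
  ns1 <- network_score(stu, net1, rw1)
  expect_true(all(ns1$ns == 1))
  # 4-gene, 3-edge toy against the exhaustively enumerated null ensemble
  expr <- matrix(c(2, 5, 3, 7,
                   1, 4, 6, 2), 4, 2,
                 dimnames = list(genes, c("s1", "s2")))
  st <- spatial_expr(expr)
  null_nets <- lapply(enumerate_rewirings(edges), lr_network)
  ns <- network_score(st, net, null_nets)
  for (s in 1:2) {
    e <- expr[, s]
    real <- unname(e["L1"] * e["R1"] + e["L1"] * e["R2"] + e["L2"] * e["R2"])
    null_sums <- vapply(null_nets, function(nn)
      sum(e[nn$edges$ligand] * e[nn$edges$receptor]), numeric(1))
    expect_equal(unname(ns$ns[s]), real / mean(null_sums), tolerance = 1e-12)
    expect_equal(unname(ns$p[s]),
                 (1 + sum(null_sums >= real)) / (1 + length(null_nets)))
  }
  # a zero-expression platform yields flagged scores
  st0 <- spatial_expr(matrix(0, 4, 2, dimnames = list(genes, c("a", "b"))))
  ns0 <- network_score(st0, net, null_nets)
  expect_true(all(is.na(ns0$ns)) && all(ns0$p == 1))
})

test_that("pair classification counts match a direct quantile census", {
  set.seed(21)
  n <- 100
  level1 <- cbind(CAF = stats::runif(n), M2 = stats::runif(n))
  rownames(level1) <- paste0("s", 1:n)
  cats <- classify_spots_pair(make_result(level1), "CAF", "M2")
  # direct census with the same nearest-rank definitions
  topA <- rank(-level1[, "CAF"], ties.method = "first") <= 15
  topB <- rank(-level1[, "M2"], ties.method = "first") <= 15
  botA <- rank(level1[, "CAF"], ties.method = "first") <= 75
  botB <- rank(level1[, "M2"], ties.method = "first") <= 75
  expect_equal(sum(cats == "colocalized"), sum(topA & topB))
  expect_equal(sum(cats == "A_dominated"), sum(topA & botB))
  expect_equal(sum(cats == "B_dominated"), sum(topB & botA))
  # the categories partition the spots
  expect_equal(sum(table(cats)), n)
  # an all-zero type degenerates to 'other' everywhere, with a warning
  level0 <- cbind(CAF = rep(0, n), M2 = stats::runif(n))
  rownames(level0) <- paste0("s", 1:n)
  expect_warning(cats0 <- classify_spots_pair(make_result(level0), "CAF", "M2"),
                 "degenerate")
  expect_true(all(cats0 == "other"))
})

test_that("the interaction test requires a positive, significant NS contrast", {
  withr::with_seed(5, {
    cats <- factor(rep(c("colocalized", "A_dominated", "B_dominated", "other"),
                       each = 30),
                   levels = c("colocalized", "A_dominated", "B_dominated",
                              "other"))
    names(cats) <- paste0("s", seq_along(cats))
    base <- stats::rnorm(120, 1, 0.2)
    names(base) <- names(cats)
    # identical distributions: no call
    t0 <- test_pair_interaction(base, cats)
    expect_false(t0$interacting)
    expect_lt(abs(t0$cohens_d), 0.5)
    # +3 pooled SDs in colocalized spots: called
    shift <- base
    shift[cats == "colocalized"] <- shift[cats == "colocalized"] + 0.6
    t1 <- test_pair_interaction(shift, cats)
    expect_true(t1$interacting)
    expect_gt(t1$cohens_d, 2)
    # reversed shift: significant but wrong direction, not called
    rev <- base
    rev[cats == "colocalized"] <- rev[cats == "colocalized"] - 0.6
    t2 <- test_pair_interaction(rev, cats)
    expect_false(t2$interacting)
    expect_lt(t2$cohens_d, 0)
    # undersized groups are skipped with a reason
    small <- cats
    small[small == "colocalized"] <- "other"
    small[1:2] <- "colocalized"
    t3 <- test_pair_interaction(base, small)
    expect_false(t3$interacting)
    expect_match(t3$reason, "min_n")
  })
})

test_that("ligand-receptor screening needs both spatial and single-cell support", {
  x <- fx_get("interaction_run1", function() interaction_run(1))
  lr <- x$lr
  # the planted cross-type pairs pass both steps
  expect_true(all(lr$step1[x$planted_idx]))
  expect_true(any(lr$called[x$planted_idx]))
  # the same-cell-type pair co-varies spatially but fails the single-cell
  # permutation step: the first false-positive category
  expect_true(lr$step1[x$same_idx])
  expect_false(lr$called[x$same_idx])
  expect_gt(min(lr$p_ab[x$same_idx], lr$p_ba[x$same_idx]), 0.05)
  # genes absent everywhere: zero correlation, p = 1, never called
  st <- x$sim$st
  zero_genes <- c("gz1", "gz2")
  expr2 <- rbind(st$expr, matrix(0, 2, ncol(st$expr),
                                 dimnames = list(zero_genes, colnames(st$expr))))
  st2 <- spatial_expr(expr2, st$coords)
  net0 <- lr_network(data.frame(ligand = c("gz1", lr$ligand[1]),
                                receptor = c("gz2", lr$receptor[1])))
  lr0 <- suppressMessages(
    identify_lr_pairs(st2, x$cats, x$sc, "CAF", "M2mac", net0,
                      n_perm = 100, seed = 2))
  z <- lr0[lr0$ligand == "gz1", ]
  expect_equal(z$rho, 0)
  expect_equal(z$p, 1)
  expect_false(z$called)
})

test_that("interface distances separate boundary-adjacent interaction spots", {
  # 20 x 20 lattice; boundary at x = 10
  coords <- expand.grid(x = 1:20, y = 1:20)
  rownames(coords) <- paste0("s", seq_len(nrow(coords)))
  boundary <- rownames(coords)[coords$x == 10]
  inter <- rownames(coords)[coords$x == 11 & coords$y <= 10]
  dominated <- rownames(coords)[coords$x >= 17]
  res <- interface_distance(coords, inter, boundary, dominated,
                            n_rand = 500, seed = 6)
  expect_equal(res$observed, 1)           # all adjacent to the interface
  expect_lte(res$p, 0.01)
  # a spot that is itself on the boundary has distance zero
  res0 <- interface_distance(coords, boundary[1], boundary, dominated,
                             n_rand = 10, seed = 1)
  expect_equal(unname(res0$distances[1]), 0)
  # exchangeable null: interaction set drawn from the dominated pool itself
  resx <- interface_distance(coords, dominated[1:20], boundary, dominated,
                             n_rand = 1000, seed = 8)
  expect_gt(resx$p, 0.2)
  expect_lt(resx$p, 0.8)
  # undersized pools sample with replacement, with a warning
  expect_warning(interface_distance(coords, inter, boundary, dominated[1:3],
                                    n_rand = 20, seed = 9), "replacement")
})
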