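# Shared fixtures and independent oracles. Expensive pipelines are built
# once per test run and cached; scenario conditions live in the package's
# scenario_* functions so tests and the acceptance script agree.

.fixture_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

main_pipeline <- function() {
  fx_get("main_pipeline", function() scenario_benchmark(11))
}

subl_run <- function(run) scenario_sublineage(100 + run)

subl_pipeline <- function() {
  fx_get("subl_pipeline", function() {
    x <- subl_run(1)
    x$dec <- deconvolve_major(x$sim$st, x$ref, x$mal)
    x$dec2 <- deconvolve_sublineages(x$sim$st, x$ref, x$dec)
    x
  })
}

interaction_run <- function(run) scenario_interaction(100 + run)

unknown_run <- function(run, overlap) {
  x <- scenario_unknown(100 + run, overlap)
  list(median_r = x$median_r, unid_r = x$unid_r)
}

# --- independent oracles ----------------------------------------------------

# Brute-force simplex-grid oracle for the constrained NNLS problem:
# minimum of ||S - R F||^2 over the grid {0, step, ...}^k with sum(F) <= budget.
grid_oracle <- function(S, R, budget, step = 0.01) {
  k <- ncol(R)
  vals <- seq(0, 1, by = step)
  G <- as.matrix(do.call(expand.grid, rep(list(vals), k)))
  G <- G[rowSums(G) <= budget + 1e-12, , drop = FALSE]
  fit <- G %*% t(R)
  resid <- sweep(fit, 2, as.numeric(S))
  min(rowSums(resid^2))
}

# Exhaustive enumeration of degree-preserving directed rewirings of a small
# edge list: every assignment of the receptor multiset to the ligand slots
# that creates no duplicate edge, deduplicated as edge sets.
enumerate_rewirings <- function(edges) {
  m <- nrow(edges)
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  seen <- character(0)
  nets <- list()
  for (p in perm_all(seq_len(m))) {
    e <- data.frame(ligand = edges$ligand, receptor = edges$receptor[p])
    key_edges <- paste(e$ligand, e$receptor)
    if (anyDuplicated(key_edges)) next
    key <- paste(sort(key_edges), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    nets[[length(nets) + 1]] <- e
  }
  nets
}

# Degree sequences of a directed edge list, for exact preservation checks.
degree_signature <- function(edges) {
  list(out = sort(table(edges$ligand)), `in` = sort(table(edges$receptor)))
}
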