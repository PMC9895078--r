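#' Non-negative least squares with a sum-budget inequality
#'
#' Solves min ||S - R F||_2 subject to F >= 0 and sum(F) <= budget. A plain
#' Lawson-Hanson solve is tried first; if its solution exceeds the budget,
#' the constraint is active at the optimum (the problem is convex), so the
#' inequality is converted to an equality with a non-negative slack variable
#' and enforced through a heavily weighted penalty row, then tightened by an
#' exact projection back onto the budget.
#'
#' @param S numeric gene vector (the mixed signal).
#' @param R gene x type matrix of reference profiles, rows aligned with `S`.
#' @param budget total fraction available to the types, in [0, 1] (or any
#'   non-negative scale).
#' @return Named fraction vector, one entry per column of `R`.
#' @export
solve_constrained_nnls <- function(S, R, budget) {
  R <- as.matrix(R)
  if (any(!is.finite(S)) || any(!is.finite(R))) stop("inputs contain non-finite values")
  if (!is.finite(budget) || budget < 0) stop("budget must be a non-negative number")
  k <- ncol(R)
  out <- stats::setNames(numeric(k), colnames(R))
  if (budget == 0 || k == 0) return(out)

  fit <- pracma::lsqnonneg(R, as.numeric(S))$x
  if (sum(fit) <= budget * (1 + 1e-10)) {
    out[] <- fit
    out[] <- out * min(1, budget / max(sum(out), .Machine$double.eps))
    return(out)
  }
  # Budget binds: solve with slack s >= 0 and penalty row M*(sum F + s) = M*b.
  M <- 1e4 * max(1, max(abs(R)))
  A <- rbind(cbind(R, 0), c(rep(M, k), M))
  y <- c(as.numeric(S), M * budget)
  x <- pracma::lsqnonneg(A, y)$x
  f <- x[seq_len(k)]
  if (sum(f) > budget) f <- f * budget / sum(f)
  out[] <- f
  out
}

#' Level-1 deconvolution of nonmalignant major-lineage fractions
#'
#' Per spot, the malignant signal is removed (S - R_malignant * F_malignant,
#' negative entries clipped to 0, since TPM space is non-negative and the
#' malignant fraction can be slightly overestimated), the result is
#' restricted to the union of major-lineage marker genes, and fractions are
#' estimated by [solve_constrained_nnls()] with budget F_nonmalignant. The
#' unidentifiable fraction is the budget left unexplained:
#' 1 - F_malignant - sum(F_c). It absorbs unknown cell types and dropout
#' noise. A `flat = TRUE` solve competes all leaf types (sublineages
#' replacing their parents) in a single regression — used to quantify the
#' benefit of the hierarchical scheme under sublineage collinearity.
#'
#' @param st a [spatial_expr()] in TPM space.
#' @param reference a [hier_reference()].
#' @param mal a `malignant_inference` from [infer_malignant_fraction()].
#' @param flat solve one level over leaf types instead of major lineages.
#' @return An object of class `deconvolution_result` with `level1`
#'   (spot x major-lineage fractions), `F_malignant`, `F_unidentifiable`,
#'   `residual_norm`, `gene_space`; for flat solves also `leaf` fractions.
#' @export
deconvolve_major <- function(st, reference, mal, flat = FALSE) {
  majors <- reference_majors(reference)
  types <- if (flat) {
    unname(unlist(lapply(majors, function(m) {
      ch <- names(reference$tree)[reference$tree == m]
      if (length(ch)) ch else m
    })))
  } else majors
  marker_union <- unique(unlist(reference$markers[types]))
  if (length(marker_union) == 0) stop("reference marker union is empty")
  genes <- intersect(marker_union, rownames(st$expr))
  if (length(genes) == 0) stop("no marker genes present in the ST matrix")
  if (length(genes) < 0.5 * length(marker_union)) {
    warning(sprintf("only %d of %d marker genes present in the ST data",
                    length(genes), length(marker_union)))
  }

  R <- reference$profiles[genes, types, drop = FALSE]
  n <- ncol(st$expr)
  S_all <- st$expr[genes, , drop = FALSE]
  if (!is.null(mal$R_malignant)) {
    S_all <- S_all - outer(mal$R_malignant[genes], unname(mal$F_malignant))
    S_all[S_all < 0] <- 0
  }
  frac <- matrix(0, n, length(types),
                 dimnames = list(colnames(st$expr), types))
  resid <- numeric(n)
  for (s in seq_len(n)) {
    f <- solve_constrained_nnls(S_all[, s], R, mal$F_nonmalignant[[s]])
    frac[s, ] <- f
    resid[s] <- sqrt(sum((S_all[, s] - R %*% f)^2))
  }
  level1 <- if (flat) {
    agg <- matrix(0, n, length(majors),
                  dimnames = list(colnames(st$expr), majors))
    parent <- vapply(types, function(tp)
      if (tp %in% names(reference$tree)) unname(reference$tree[tp]) else tp,
      character(1))
    for (m in majors) agg[, m] <- rowSums(frac[, parent == m, drop = FALSE])
    agg
  } else frac
  res <- list(level1 = level1,
              leaf = if (flat) frac else NULL,
              level2 = NULL,
              F_malignant = mal$F_malignant,
              F_unidentifiable = 1 - mal$F_malignant - rowSums(level1),
              residual_norm = stats::setNames(resid, colnames(st$expr)),
              gene_space = genes,
              S_nonmalignant = S_all,
              flat = flat)
  structure(res, class = "deconvolution_result")
}

#' Level-2 deconvolution of sublineage fractions
#'
#' For each sublineage family (e.g. M1/M2 under macrophage) and each spot,
#' the level-1 contributions of all other major lineages are subtracted from
#' the nonmalignant signal, the residual is restricted to the family's
#' sublineage marker union, and sublineage fractions are estimated with the
#' parent's level-1 fraction as the budget. Confining the solve to the
#' family keeps collinearity among sublineages from disturbing fractions at
#' the level above. Spots with a zero parent fraction get zero sublineage
#' fractions without solving.
#'
#' @param st a [spatial_expr()] (gene index only; the nonmalignant signal is
#'   carried in `level1_result`).
#' @param reference a [hier_reference()].
#' @param level1_result a `deconvolution_result` from [deconvolve_major()].
#' @return The `deconvolution_result` with `level2` (spot x sublineage)
#'   filled in.
#' @export
deconvolve_sublineages <- function(st, reference, level1_result) {
  if (isTRUE(level1_result$flat)) stop("level-2 requires a hierarchical level-1 result")
  fams <- reference_families(reference)
  if (length(fams) == 0) stop("the tree has no sublineage family")
  majors <- colnames(level1_result$level1)
  subl <- unname(unlist(fams))
  n <- nrow(level1_result$level1)
  level2 <- matrix(0, n, length(subl),
                   dimnames = list(rownames(level1_result$level1), subl))
  S_non_full <- level1_result$S_nonmalignant  # marker-union gene space

  for (fam in names(fams)) {
    children <- fams[[fam]]
    fam_markers <- unique(unlist(reference$markers[children]))
    genes <- intersect(fam_markers, rownames(S_non_full))
    genes <- intersect(genes, rownames(reference$profiles))
    if (length(genes) == 0) {
      warning("no sublineage marker genes available for family ", fam)
      next
    }
    R_fam <- reference$profiles[genes, children, drop = FALSE]
    others <- setdiff(majors, fam)
    R_oth <- reference$profiles[genes, others, drop = FALSE]
    for (s in seq_len(n)) {
      pf <- level1_result$level1[s, fam]
      if (pf <= 0) next
      resid <- S_non_full[genes, s] -
        as.numeric(R_oth %*% level1_result$level1[s, others])
      level2[s, children] <- solve_constrained_nnls(resid, R_fam, pf)
    }
  }
  level1_result$level2 <- level2
  level1_result
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> %d spots x %d major lineages%s\n",
              nrow(x$level1), ncol(x$level1),
              if (!is.null(x$level2))
                sprintf(" (+%d sublineages)", ncol(x$level2)) else ""))
  cat(sprintf("  mean fractions: malignant %.3f, identified %.3f, unidentifiable %.3f\n",
              mean(x$F_malignant), mean(rowSums(x$level1)),
              mean(x$F_unidentifiable)))
  invisible(x)
}

#' Explore cancer cell states among malignant spots
#'
#' Spots with a malignant fraction above `threshold` are clustered with the
#' silhouette rule; each state's profile is the mean TPM profile of its
#' spots. Per-spot state fractions are then estimated for all spots the same
#' way as sublineages: constrained NNLS over the state profiles with the
#' spot's malignant fraction as the budget, in the space of the most
#' variable genes among the selected spots. Optional module scores are mean
#' expression of user-supplied gene sets per spot.
#'
#' @param st a [spatial_expr()].
#' @param mal a `malignant_inference`.
#' @param threshold malignant-fraction cutoff for state discovery
#'   (default 0.7).
#' @param module_gene_sets optional named list of gene sets.
#' @param k_range candidate state counts.
#' @param n_var_genes feature count for clustering/regression.
#' @return List with `state_labels` (for selected spots), `state_profiles`
#'   (gene x state), `state_fractions` (all spots x states) and
#'   `module_scores` (modules x spots), or an empty result with a warning
#'   when no spot passes the threshold.
#' @export
identify_cancer_states <- function(st, mal, threshold = 0.7,
                                   module_gene_sets = NULL,
                                   k_range = 2:9, n_var_genes = 2000) {
  module_scores <- NULL
  if (!is.null(module_gene_sets)) {
    module_scores <- t(vapply(module_gene_sets, function(gs) {
      gs <- intersect(gs, rownames(st$expr))
      if (length(gs) == 0) return(rep(NA_real_, ncol(st$expr)))
      colMeans(st$expr[gs, , drop = FALSE])
    }, numeric(ncol(st$expr))))
    colnames(module_scores) <- colnames(st$expr)
  }
  sel <- which(mal$F_malignant > threshold)
  if (length(sel) == 0) {
    warning("no spot has malignant fraction above ", threshold)
    return(list(state_labels = NULL, state_profiles = NULL,
                state_fractions = NULL, module_scores = module_scores))
  }
  sub <- spatial_expr(st$expr[, sel, drop = FALSE],
                      if (!is.null(st$coords)) st$coords[sel, ] else NULL)
  cl <- cluster_spots(sub, k_range = k_range, n_var_genes = n_var_genes)
  states <- sort(unique(cl$labels))
  profiles <- vapply(states, function(k)
    rowMeans(sub$expr[, cl$labels == k, drop = FALSE]),
    numeric(nrow(st$expr)))
  colnames(profiles) <- paste0("state", states)

  y <- log_tpm(sub$expr)
  v <- apply(y, 1, stats::var)
  genes <- rownames(st$expr)[utils::head(order(v, decreasing = TRUE),
                                         min(n_var_genes, nrow(y)))]
  Rs <- profiles[genes, , drop = FALSE]
  fracs <- matrix(0, ncol(st$expr), ncol(profiles),
                  dimnames = list(colnames(st$expr), colnames(profiles)))
  for (s in seq_len(ncol(st$expr))) {
    fracs[s, ] <- solve_constrained_nnls(st$expr[genes, s], Rs,
                                         mal$F_malignant[[s]])
  }
  list(state_labels = cl$labels, state_profiles = profiles,
       state_fractions = fracs, module_scores = module_scores)
}
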