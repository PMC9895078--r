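#' Cluster spots by hierarchical clustering with silhouette-based K
#'
#' Spots are clustered with Ward-linkage agglomerative clustering on
#' Euclidean distances over the most variable genes in log2(TPM/10 + 1)
#' space, and the tree is cut into K clusters for each K in `k_range`. The
#' chosen K is the point preceding the largest decrease in mean silhouette;
#' if the silhouette never decreases over the range, the K with the maximum
#' silhouette is chosen.
#'
#' @param st a [spatial_expr()].
#' @param k_range integer vector of candidate cluster counts (default 2:9).
#' @param n_var_genes number of most-variable genes used as features.
#' @return List with `labels` (per-spot integer cluster id), `K` (chosen
#'   count) and `silhouettes` (named mean silhouette per K).
#' @export
cluster_spots <- function(st, k_range = 2:9, n_var_genes = 2000) {
  n <- ncol(st$expr)
  if (n <= max(k_range)) {
    k_range <- k_range[k_range < n]
    if (length(k_range) == 0) stop("too few spots to cluster")
    warning("fewer spots than k_max; range shrunk to ",
            paste(range(k_range), collapse = "-"))
  }
  y <- log_tpm(st$expr)
  v <- apply(y, 1, stats::var)
  feats <- utils::head(order(v, decreasing = TRUE), min(n_var_genes, nrow(y)))
  d <- stats::dist(t(y[feats, , drop = FALSE]))
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  K <- choose_k_by_silhouette(sil, k_range)
  list(labels = stats::setNames(stats::cutree(hc, k = K), colnames(st$expr)),
       K = K, silhouettes = sil)
}

#' Choose a cluster count from a silhouette profile
#'
#' Returns the K immediately preceding the largest decrease in mean
#' silhouette; when the silhouette never decreases over the range, the K
#' with the maximum silhouette. When a sharp collapse is spread over two
#' steps the largest drop can be split between the true K and the next one,
#' so drops within 25% of the largest are treated as candidates and resolved
#' toward the higher silhouette.
#'
#' @param sil mean silhouette per candidate K.
#' @param k_range the candidate Ks, aligned with `sil`.
#' @return The chosen K.
#' @export
choose_k_by_silhouette <- function(sil, k_range = as.integer(names(sil))) {
  stopifnot(length(sil) == length(k_range))
  drops <- if (length(sil) > 1) sil[-length(sil)] - sil[-1] else numeric(0)
  if (length(drops) && any(drops > 0, na.rm = TRUE)) {
    cands <- which(drops >= 0.75 * max(drops, na.rm = TRUE))
    k_range[cands[which.max(sil[cands])]]
  } else {
    k_range[which.max(sil)]
  }
}

#' Correlate each spot profile with a gene signature
#'
#' Expression is first mean-centered across spots for each gene; each spot's
#' centered profile is then Pearson-correlated with the signature over their
#' shared genes, with a two-sided test p value per spot. Degenerate cases
#' (zero-variance spot or constant signature) yield r = 0, p = 1 and are
#' flagged.
#'
#' @param st a [spatial_expr()].
#' @param signature named gene vector (CNA values, log2 fold changes, or a
#'   malignant mean profile).
#' @param min_genes minimum shared-gene overlap (default 50).
#' @return List with `r`, `p`, `degenerate` (per spot) and `n_genes`.
#' @export
correlate_signature <- function(st, signature, min_genes = 50) {
  signature <- signature[is.finite(signature)]
  shared <- intersect(rownames(st$expr), names(signature))
  if (length(shared) < min_genes) {
    stop(sprintf("only %d genes shared with the signature (need >= %d)",
                 length(shared), min_genes))
  }
  x <- st$expr[shared, , drop = FALSE]
  x <- x - rowMeans(x)
  out <- cor_with_vector(x, signature[shared])
  out$n_genes <- length(shared)
  out
}

#' Identify spot clusters dominated by malignant cells
#'
#' A cluster is called malignant when (1) its spots' correlation
#' coefficients are significantly greater than zero (one-sided Wilcoxon
#' signed-rank test, p < alpha), and (2) the proportion of its spots
#' positively and significantly correlated with the signature (r > 0, test
#' p < alpha) exceeds that proportion in the whole dataset. Clusters of
#' fewer than 3 spots cannot support the signed-rank test and are excluded.
#'
#' @param labels per-spot cluster ids.
#' @param r,p per-spot correlation and test p from [correlate_signature()].
#' @param alpha significance level (default 0.05).
#' @return Integer vector of malignant cluster ids (possibly empty).
#' @export
identify_malignant_clusters <- function(labels, r, p, alpha = 0.05) {
  stopifnot(length(labels) == length(r), length(r) == length(p))
  global_prop <- mean(r > 0 & p < alpha)
  out <- integer(0)
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    if (sum(in_cl) < 3) {
      warning("cluster ", cl, " has fewer than 3 spots; excluded")
      next
    }
    rc <- r[in_cl]
    if (all(rc == 0)) next
    w <- suppressWarnings(
      stats::wilcox.test(rc, mu = 0, alternative = "greater"))
    crit1 <- w$p.value < alpha
    crit2 <- mean(r[in_cl] > 0 & p[in_cl] < alpha) > global_prop
    if (crit1 && crit2) out <- c(out, cl)
  }
  out
}

#' Normalize per-spot correlations to malignant fractions
#'
#' The means of the top and bottom 5% of spots sorted on r (ceiling(0.05 n)
#' spots each) anchor the scale. The default mapping rescales r so the
#' bottom-5% mean maps to 0 and the top-5% mean to 1; the `"literal"` mode
#' divides r by the top-bottom range without shifting. Both clip to [0, 1].
#'
#' @param r per-spot correlation coefficients (>= 20 spots).
#' @param mode `"minmax"` (default) or `"literal"`.
#' @param tail_frac tail size as a fraction of spots (default 0.05).
#' @return List with `fraction` (per spot), `r_top5`, `r_bottom5`.
#' @export
normalize_correlations <- function(r, mode = c("minmax", "literal"),
                                   tail_frac = 0.05) {
  mode <- match.arg(mode)
  n <- length(r)
  if (n < 20) stop("need >= 20 spots so the 5% tails are nonempty")
  k <- ceiling(tail_frac * n)
  sr <- sort(r)
  r_bottom <- mean(sr[seq_len(k)])
  r_top <- mean(sr[seq(n - k + 1, n)])
  if (r_top == r_bottom) stop("degenerate correlation range: top and bottom 5% means coincide")
  f <- switch(mode,
              minmax = (r - r_bottom) / (r_top - r_bottom),
              literal = r / (r_top - r_bottom))
  list(fraction = pmin(pmax(f, 0), 1), r_top5 = r_top, r_bottom5 = r_bottom)
}

#' Infer per-spot malignant cell fractions without a malignant reference
#'
#' Orchestrates stage 1: spots are clustered; spot profiles are correlated
#' with the cancer-type CNA signature (the first option, as chromosomal
#' instability is a consistent tumor feature); if no cluster passes the
#' malignant criteria the expression signature is tried; if the cancer type
#' is absent from the dictionary the pan-cancer expression signature is
#' used. On success, the ST-specific malignant profile is the mean TPM
#' profile of the malignant-cluster spots, all spots are re-correlated
#' against it, and those correlations are normalized to fractions. If no
#' signature yields a malignant cluster, all malignant fractions are 0 and
#' the mode is `"none"`.
#'
#' @param st a [spatial_expr()] in TPM space.
#' @param dictionary a [signature_dictionary()].
#' @param cancer_type dictionary column to use; NULL requests pan-cancer.
#' @param k_range,n_var_genes passed to [cluster_spots()].
#' @param min_genes,alpha,mode tuning for the correlation, cluster calling
#'   and normalization steps.
#' @return An object of class `malignant_inference` with per-spot `r`,
#'   `F_malignant`, `F_nonmalignant` (= 1 - F_malignant exactly),
#'   `r_top5`/`r_bottom5`, `mode`, `cluster_labels`, `malignant_clusters`
#'   and `R_malignant`.
#' @export
infer_malignant_fraction <- function(st, dictionary, cancer_type = NULL,
                                     k_range = 2:9, n_var_genes = 2000,
                                     min_genes = 50, alpha = 0.05,
                                     mode = c("minmax", "literal")) {
  mode <- match.arg(mode)
  cl <- cluster_spots(st, k_range = k_range, n_var_genes = n_var_genes)

  candidates <- list()
  in_dict <- !is.null(cancer_type) &&
    (cancer_type %in% colnames(dictionary$expr) ||
       (!is.null(dictionary$cna) && cancer_type %in% colnames(dictionary$cna)))
  if (in_dict) {
    if (!is.null(dictionary$cna) && cancer_type %in% colnames(dictionary$cna)) {
      v <- dictionary$cna[, cancer_type]
      if (any(v != 0, na.rm = TRUE)) {
        candidates$cna <- stats::setNames(v, rownames(dictionary$cna))
      }
    }
    if (cancer_type %in% colnames(dictionary$expr)) {
      candidates$expression <-
        stats::setNames(dictionary$expr[, cancer_type], rownames(dictionary$expr))
    }
  } else {
    candidates$pan_cancer <-
      stats::setNames(dictionary$pan_cancer, rownames(dictionary$expr))
  }

  used <- "none"; mal_clusters <- integer(0)
  for (nm in names(candidates)) {
    cors <- correlate_signature(st, candidates[[nm]], min_genes = min_genes)
    mal_clusters <- suppressWarnings(
      identify_malignant_clusters(cl$labels, cors$r, cors$p, alpha = alpha))
    if (length(mal_clusters)) { used <- nm; break }
  }

  n <- ncol(st$expr)
  if (used == "none") {
    res <- list(r = stats::setNames(rep(NA_real_, n), colnames(st$expr)),
                r_top5 = NA_real_, r_bottom5 = NA_real_,
                F_malignant = stats::setNames(rep(0, n), colnames(st$expr)),
                F_nonmalignant = stats::setNames(rep(1, n), colnames(st$expr)),
                mode = "none", cluster_labels = cl$labels, chosen_K = cl$K,
                malignant_clusters = integer(0), R_malignant = NULL)
    return(structure(res, class = "malignant_inference"))
  }

  mal_spots <- cl$labels %in% mal_clusters
  R_malignant <- rowMeans(st$expr[, mal_spots, drop = FALSE])
  cors2 <- correlate_signature(st, R_malignant, min_genes = min_genes)
  nc <- normalize_correlations(cors2$r, mode = mode)
  F_mal <- nc$fraction
  res <- list(r = cors2$r, r_top5 = nc$r_top5, r_bottom5 = nc$r_bottom5,
              F_malignant = F_mal, F_nonmalignant = 1 - F_mal,
              mode = used, cluster_labels = cl$labels, chosen_K = cl$K,
              malignant_clusters = mal_clusters, R_malignant = R_malignant)
  structure(res, class = "malignant_inference")
}

#' @export
print.malignant_inference <- function(x, ...) {
  cat(sprintf(
    "<malignant_inference> %d spots; signature mode: %s; K = %s; malignant clusters: %s\n",
    length(x$F_malignant), x$mode, x$chosen_K,
    if (length(x$malignant_clusters)) paste(x$malignant_clusters, collapse = ",")
    else "none"))
  cat(sprintf("  mean F_malignant = %.3f\n", mean(x$F_malignant)))
  invisible(x)
}
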