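#' CNA signature of a cancer type from per-patient gene-level CNA
#'
#' The per-patient total CNA burden is the sum of absolute gene-level CNA
#' values; the lowest quartile of patients by burden (floor(n/4) patients)
#' is excluded before averaging, so that chromosomally quiet tumors do not
#' dilute the signature.
#'
#' @param cna_matrix gene x patient matrix of gene-level CNA values.
#' @param exclude_quartile drop the lowest-burden quartile first (default).
#' @return Named gene vector: the per-gene mean over retained patients.
#' @export
build_cna_signature <- function(cna_matrix, exclude_quartile = TRUE) {
  cna_matrix <- as.matrix(cna_matrix)
  n <- ncol(cna_matrix)
  if (exclude_quartile) {
    if (n < 4) stop("at least 4 patients are required to exclude a quartile")
    burden <- colSums(abs(cna_matrix))
    drop_n <- floor(n / 4)
    keep <- order(burden)[-seq_len(drop_n)]
    cna_matrix <- cna_matrix[, keep, drop = FALSE]
  }
  rowMeans(cna_matrix)
}

#' Expression signature: tumor-vs-normal log2 fold change
#'
#' Computed as the difference of group means in log2(TPM/10 + 1) space.
#' Cancer types lacking adequate normal samples get no expression signature.
#'
#' @param tumor gene x sample matrix of tumor TPM.
#' @param normal gene x sample matrix of normal TPM; same gene index.
#' @param min_normal minimum number of normal samples (default 10).
#' @return Named gene vector of log2 fold changes.
#' @export
build_expression_signature <- function(tumor, normal, min_normal = 10) {
  tumor <- as.matrix(tumor); normal <- as.matrix(normal)
  if (!identical(rownames(tumor), rownames(normal))) {
    stop("tumor and normal gene indices must match")
  }
  if (ncol(normal) < min_normal) {
    stop(sprintf(
      "no expression signature: lack of adequate normal samples (n < %d patients)",
      min_normal))
  }
  rowMeans(log_tpm(tumor)) - rowMeans(log_tpm(normal))
}

#' Assemble a signature dictionary from per-type signatures
#'
#' Aligns signatures on the union of their gene indices (a gene missing in a
#' type is NA there and ignored for that gene's pan-cancer mean) and derives
#' the pan-cancer expression signature as the per-gene mean over all
#' expression signatures.
#'
#' @param expr_signatures named list of expression signature gene vectors
#'   (at least one).
#' @param cna_signatures optional named list of CNA signature gene vectors.
#' @return A [signature_dictionary()].
#' @export
assemble_dictionary <- function(expr_signatures, cna_signatures = NULL) {
  if (length(expr_signatures) == 0) {
    stop("at least one expression signature is required")
  }
  bind_columns <- function(sigs) {
    genes <- Reduce(union, lapply(sigs, names))
    out <- matrix(NA_real_, length(genes), length(sigs),
                  dimnames = list(genes, names(sigs)))
    for (i in seq_along(sigs)) out[names(sigs[[i]]), i] <- sigs[[i]]
    out
  }
  expr <- bind_columns(expr_signatures)
  cna <- if (!is.null(cna_signatures)) bind_columns(cna_signatures) else NULL
  signature_dictionary(cna = cna, expr = expr)
}

#' Marker genes of a cell type by one-vs-rest differential expression
#'
#' Fits limma on log2(TPM/10 + 1) values contrasting the cell type against
#' all other cells pooled, ranks overexpressed genes by BH-adjusted p value,
#' takes the top `n_top`, and keeps those with log2 fold change above
#' `lfc_min` and adjusted p below `p_max`. Constant genes carry no evidence
#' and are assigned p = 1.
#'
#' @param sc a [single_cell_set()].
#' @param cell_type the type whose markers are sought (>= 3 cells).
#' @param n_top rank cutoff on adjusted p (default 500).
#' @param lfc_min log2 fold-change threshold (default 0.25).
#' @param p_max adjusted p threshold (default 0.01).
#' @return Character vector of marker genes.
#' @export
select_markers <- function(sc, cell_type, n_top = 500, lfc_min = 0.25,
                           p_max = 0.01) {
  if (!cell_type %in% sc$cell_type) stop("cell type absent: ", cell_type)
  in_type <- sc$cell_type == cell_type
  if (sum(in_type) < 3) stop("need >= 3 cells of type ", cell_type)
  if (all(in_type)) stop("need at least one other cell type")
  y <- log_tpm(sc$expression)
  design <- cbind(Intercept = 1, group = as.numeric(in_type))
  fit <- limma::eBayes(limma::lmFit(y, design))
  tab <- limma::topTable(fit, coef = "group", number = Inf, sort.by = "none")
  lfc <- tab$logFC
  padj <- tab$adj.P.Val
  constant <- apply(y, 1, function(v) max(v) == min(v))
  padj[constant | !is.finite(padj)] <- 1
  lfc[!is.finite(lfc)] <- 0
  over <- which(lfc > 0)
  over <- over[order(padj[over], -lfc[over])]
  over <- utils::head(over, n_top)
  keep <- over[lfc[over] > lfc_min & padj[over] < p_max]
  rownames(y)[keep]
}

#' Build a two-level hierarchical cell-type reference
#'
#' For each single-cell dataset, the reference profile of a cell type is the
#' mean expression of its cells in non-log TPM space (after restricting all
#' datasets to their shared genes and re-normalizing); the combined profile
#' averages the per-dataset profiles of datasets containing the type.
#' Combined markers are the genes selected in at least half (ceiling) of the
#' datasets containing the type. Major-lineage profiles and markers are
#' computed from the pooled cells of all their sublineages. Malignant cells
#' participate in the differential-expression background but get no
#' reference entry (the malignant profile is inferred from the ST data
#' itself in stage 1).
#'
#' @param sc_sets a [single_cell_set()] or list of them.
#' @param tree optional named character vector sublineage -> major lineage;
#'   defaults to the first set's hierarchy.
#' @param ... passed on to [select_markers()].
#' @return A [hier_reference()].
#' @export
build_hierarchical_reference <- function(sc_sets, tree = NULL, ...) {
  if (inherits(sc_sets, "single_cell_set")) sc_sets <- list(sc_sets)
  if (length(sc_sets) == 0) stop("at least one single-cell set is required")
  if (is.null(tree)) tree <- sc_sets[[1]]$hierarchy
  tree <- tree[unname(tree) != "Malignant"]

  genes <- Reduce(intersect, lapply(sc_sets, function(s) rownames(s$expression)))
  if (length(genes) == 0) stop("datasets share no genes")
  sc_sets <- lapply(sc_sets, function(s) {
    expr <- scale_columns(s$expression[genes, , drop = FALSE])
    single_cell_set(expr, s$cell_type, s$hierarchy, patient = s$patient,
                    meta = s$meta)
  })

  majors <- unique(unname(tree))
  # every entity (sublineage leaf + major lineage) -> the cells composing it
  entities <- union(names(tree), majors)
  cells_of <- function(s, entity) {
    leaves <- if (entity %in% majors) names(tree)[tree == entity] else entity
    leaves <- union(leaves, entity)
    which(s$cell_type %in% leaves)
  }

  profiles <- list(); markers <- list()
  for (e in entities) {
    prof_list <- list(); mark_list <- list()
    for (s in sc_sets) {
      idx <- cells_of(s, e)
      if (length(idx) == 0) next
      prof_list[[length(prof_list) + 1]] <-
        rowMeans(s$expression[, idx, drop = FALSE])
      if (length(idx) >= 3 && length(idx) < ncol(s$expression)) {
        relabeled <- s
        relabeled$cell_type <- ifelse(seq_along(s$cell_type) %in% idx,
                                      e, s$cell_type)
        relabeled$hierarchy <- c(s$hierarchy, stats::setNames("..tmp", e))
        mark_list[[length(mark_list) + 1]] <- select_markers(relabeled, e, ...)
      }
    }
    if (length(prof_list) == 0) {
      warning("cell type absent from all datasets, omitted: ", e)
      next
    }
    profiles[[e]] <- Reduce(`+`, prof_list) / length(prof_list)
    if (length(mark_list)) {
      need <- ceiling(length(mark_list) / 2)
      counts <- table(unlist(mark_list))
      markers[[e]] <- names(counts)[counts >= need]
    } else {
      markers[[e]] <- character(0)
    }
  }
  present <- names(profiles)
  tree <- tree[names(tree) %in% present & unname(tree) %in% present]
  hier_reference(do.call(cbind, profiles), markers[present], tree)
}
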