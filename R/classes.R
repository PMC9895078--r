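#' Spatial expression matrix
#'
#' Container for a gene-by-spot expression matrix in TPM/CPM space, with
#' optional spot coordinates. Each spot column holds the mixed transcriptome
#' of all cells captured at that location.
#'
#' @param expr numeric gene x spot matrix, non-negative and finite, with gene
#'   symbols as rownames and spot ids as colnames.
#' @param coords optional data.frame with columns `x` and `y` and one row per
#'   spot (rownames = spot ids), in whatever units the platform supplies.
#' @return An object of class `spatial_expr` with elements `expr`, `coords`
#'   and `spot_ids`.
#' @export
spatial_expr <- function(expr, coords = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("spot", seq_len(ncol(expr)))
  if (any(!is.finite(expr)) || any(expr < 0)) {
    stop("expression values must be non-negative and finite")
  }
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    if (!all(c("x", "y") %in% colnames(coords))) {
      stop("coords must have columns 'x' and 'y'")
    }
    if (nrow(coords) != ncol(expr)) {
      stop(sprintf("coords rows (%d) do not match spots (%d)",
                   nrow(coords), ncol(expr)))
    }
    rownames(coords) <- colnames(expr)
  }
  structure(list(expr = expr, coords = coords, spot_ids = colnames(expr)),
            class = "spatial_expr")
}

#' @export
print.spatial_expr <- function(x, ...) {
  cat(sprintf("<spatial_expr> %d genes x %d spots%s\n",
              nrow(x$expr), ncol(x$expr),
              if (is.null(x$coords)) " (no coordinates)" else ""))
  invisible(x)
}

#' Single-cell profile set
#'
#' A gene-by-cell expression matrix with per-cell cell-type and patient
#' labels, plus a two-level lineage tree mapping each cell type (sublineage)
#' to its major lineage. A cell type whose major lineage is `"Malignant"` is
#' treated as malignant throughout the package.
#'
#' @param expression numeric gene x cell matrix, non-negative finite,
#'   non-log TPM-like.
#' @param cell_type character vector, one label per cell; every label must
#'   appear in `names(hierarchy)`.
#' @param hierarchy named character vector mapping each cell type to its
#'   major lineage (a lineage without sublineages maps to itself).
#' @param patient optional character vector of per-cell patient labels.
#' @param meta optional list of generator ground truth (templates, planted
#'   markers, CNA profile) carried along for validation.
#' @return An object of class `single_cell_set`.
#' @export
single_cell_set <- function(expression, cell_type, hierarchy,
                            patient = NULL, meta = list()) {
  expression <- as.matrix(expression)
  if (any(!is.finite(expression)) || any(expression < 0)) {
    stop("expression values must be non-negative and finite")
  }
  cell_type <- as.character(cell_type)
  if (length(cell_type) != ncol(expression)) {
    stop("one cell_type label per cell is required")
  }
  if (!all(cell_type %in% names(hierarchy))) {
    missing <- setdiff(unique(cell_type), names(hierarchy))
    stop("cell types absent from hierarchy: ", paste(missing, collapse = ", "))
  }
  if (is.null(patient)) patient <- rep("P1", ncol(expression))
  structure(list(expression = expression, cell_type = cell_type,
                 patient = as.character(patient), hierarchy = hierarchy,
                 meta = meta),
            class = "single_cell_set")
}

#' @export
print.single_cell_set <- function(x, ...) {
  cat(sprintf("<single_cell_set> %d genes x %d cells, %d cell types\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$cell_type))))
  invisible(x)
}

# Cell types of a set whose major lineage is "Malignant".
malignant_cell_types <- function(sc) {
  names(sc$hierarchy)[sc$hierarchy == "Malignant"]
}

#' Cancer-type signature dictionary
#'
#' Per-cancer-type copy-number-alteration (CNA) and tumor-vs-normal
#' expression signatures, plus a pan-cancer expression signature used when a
#' cancer type is not covered.
#'
#' @param cna gene x cancer-type matrix of average gene-level CNA values
#'   (may be NULL when only expression signatures exist).
#' @param expr gene x cancer-type matrix of tumor-vs-normal log2 fold
#'   changes.
#' @param pan_cancer optional gene vector; defaults to the per-gene mean of
#'   the columns of `expr` (genes missing in a type ignored for that gene).
#' @return An object of class `signature_dictionary`.
#' @export
signature_dictionary <- function(cna = NULL, expr, pan_cancer = NULL) {
  expr <- as.matrix(expr)
  if (any(is.infinite(expr))) stop("expression signatures must be finite")
  if (!is.null(cna)) {
    cna <- as.matrix(cna)
    if (any(is.infinite(cna))) stop("CNA signatures must be finite")
  }
  if (is.null(pan_cancer)) pan_cancer <- rowMeans(expr, na.rm = TRUE)
  structure(list(cna = cna, expr = expr, pan_cancer = pan_cancer),
            class = "signature_dictionary")
}

#' @export
print.signature_dictionary <- function(x, ...) {
  cat(sprintf("<signature_dictionary> %d genes; CNA types: %s; expression types: %s\n",
              nrow(x$expr),
              if (is.null(x$cna)) "none" else paste(colnames(x$cna), collapse = ", "),
              paste(colnames(x$expr), collapse = ", ")))
  invisible(x)
}

#' Hierarchical cell-type reference
#'
#' Mean expression profiles (non-log TPM) and marker gene sets for the major
#' lineages and sublineages of the tumor microenvironment, arranged as a
#' two-level tree.
#'
#' @param profiles gene x cell-type matrix (majors and sublineages), non-log
#'   TPM space, non-negative.
#' @param markers named list mapping each cell type to its marker gene set.
#' @param tree named character vector mapping sublineage -> major lineage;
#'   lineages without sublineages map to themselves.
#' @return An object of class `hier_reference`.
#' @export
hier_reference <- function(profiles, markers, tree) {
  profiles <- as.matrix(profiles)
  if (any(!is.finite(profiles)) || any(profiles < 0)) {
    stop("reference profiles must be non-negative and finite")
  }
  bad <- setdiff(unlist(markers), rownames(profiles))
  if (length(bad)) {
    stop("marker genes absent from profile gene index: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  majors <- unique(unname(tree))
  orphan <- setdiff(majors, c(names(tree), colnames(profiles)))
  if (length(orphan)) stop("major lineages without entries: ",
                           paste(orphan, collapse = ", "))
  structure(list(profiles = profiles, markers = markers, tree = tree),
            class = "hier_reference")
}

#' @export
print.hier_reference <- function(x, ...) {
  majors <- unique(unname(x$tree))
  cat(sprintf("<hier_reference> %d genes; %d major lineages, %d leaf types\n",
              nrow(x$profiles), length(majors), length(x$tree)))
  invisible(x)
}

# Major lineages of a reference (excluding any malignant entry).
reference_majors <- function(reference) {
  setdiff(unique(unname(reference$tree)), "Malignant")
}

# Sublineage families: majors with >1 child or a child named differently.
reference_families <- function(reference) {
  fam <- split(names(reference$tree), unname(reference$tree))
  fam <- fam[!vapply(fam, function(ch) length(ch) == 1 && ch == names(fam)[1],
                     logical(1))]
  fam[vapply(names(fam), function(m) {
    ch <- fam[[m]]
    length(ch) > 1 || !identical(ch, m)
  }, logical(1))]
}

#' Directed ligand-receptor network
#'
#' A set of unique directed ligand -> receptor gene pairs, filtered to the
#' genes detectable on the platform.
#'
#' @param edges data.frame with character columns `ligand` and `receptor`.
#' @param gene_universe optional character vector of detectable genes; edges
#'   touching genes outside it are dropped.
#' @return An object of class `lr_network`.
#' @export
lr_network <- function(edges, gene_universe = NULL) {
  edges <- as.data.frame(edges)[, c("ligand", "receptor")]
  edges$ligand <- as.character(edges$ligand)
  edges$receptor <- as.character(edges$receptor)
  if (!is.null(gene_universe)) {
    keep <- edges$ligand %in% gene_universe & edges$receptor %in% gene_universe
    edges <- edges[keep, , drop = FALSE]
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  structure(list(edges = edges, gene_universe = gene_universe),
            class = "lr_network")
}

#' @export
print.lr_network <- function(x, ...) {
  cat(sprintf("<lr_network> %d directed ligand->receptor pairs\n", nrow(x$edges)))
  invisible(x)
}
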