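#' Read a spatial expression matrix
#'
#' Two dialects are supported: `"dense_tsv"` (genes as rows, spots as
#' columns, rownames in the first column) and `"mtx"` (a directory holding
#' `matrix.mtx`, `features.tsv`, `barcodes.tsv` in 10x triplet style;
#' the second column of the features file is used as the gene symbol when
#' present). Duplicate gene symbols are collapsed by summation. An optional
#' coordinates TSV (columns `spot_id`, `x`, `y`) attaches spot positions;
#' without it the object loads uncoordinated and spatial operations refuse
#' later.
#'
#' @param path file (dense TSV) or directory (MTX triplet).
#' @param dialect `"dense_tsv"` or `"mtx"`.
#' @param coords_path optional coordinates TSV.
#' @return A [spatial_expr()] of raw values (no normalization applied).
#' @export
read_spatial_matrix <- function(path, dialect = c("dense_tsv", "mtx"),
                                coords_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "dense_tsv") {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    expr <- as.matrix(df)
  } else {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    feats <- utils::read.delim(file.path(path, "features.tsv"),
                               header = FALSE, stringsAsFactors = FALSE)
    bars <- utils::read.delim(file.path(path, "barcodes.tsv"),
                              header = FALSE, stringsAsFactors = FALSE)
    if (nrow(feats) != nrow(m)) {
      stop(sprintf("features file has %d rows but matrix has %d",
                   nrow(feats), nrow(m)))
    }
    if (nrow(bars) != ncol(m)) {
      stop(sprintf("barcodes file has %d rows but matrix has %d columns",
                   nrow(bars), ncol(m)))
    }
    symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
    expr <- as.matrix(m)
    rownames(expr) <- symbols
    colnames(expr) <- bars[[1]]
  }
  if (anyDuplicated(rownames(expr))) {
    expr <- rowsum(expr, group = rownames(expr))
  }
  coords <- NULL
  if (!is.null(coords_path)) {
    cdf <- utils::read.delim(coords_path, stringsAsFactors = FALSE)
    if (!all(c("spot_id", "x", "y") %in% colnames(cdf))) {
      stop("coordinates file needs columns spot_id, x, y")
    }
    missing <- setdiff(colnames(expr), cdf$spot_id)
    if (length(missing)) stop("coordinates missing for ", length(missing), " spots")
    cdf <- cdf[match(colnames(expr), cdf$spot_id), ]
    coords <- data.frame(x = cdf$x, y = cdf$y)
  }
  spatial_expr(expr, coords)
}

#' Write a spatial expression matrix
#'
#' @param st a [spatial_expr()].
#' @param path output file (dense TSV) or directory (MTX triplet).
#' @param dialect `"dense_tsv"` or `"mtx"`.
#' @return `path`, invisibly. Coordinates, if present, are written next to
#'   the matrix as `<path>.coords.tsv` (dense) or `coords.tsv` (mtx).
#' @export
write_spatial_matrix <- function(st, path, dialect = c("dense_tsv", "mtx")) {
  dialect <- match.arg(dialect)
  if (dialect == "dense_tsv") {
    df <- data.frame(gene = rownames(st$expr), st$expr, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    coords_file <- paste0(path, ".coords.tsv")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(st$expr, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(rownames(st$expr), rownames(st$expr)),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(colnames(st$expr)),
                       file.path(path, "barcodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    coords_file <- file.path(path, "coords.tsv")
  }
  if (!is.null(st$coords)) {
    utils::write.table(data.frame(spot_id = st$spot_ids, st$coords),
                       coords_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Normalize spot columns to TPM
#'
#' Every spot column is scaled to sum to one million (TPM, equivalent to
#' CPM for 10x counts). All-zero spots are left at zero and listed in the
#' `zero_spots` attribute. Idempotent.
#'
#' @param st a [spatial_expr()] of non-negative counts or expression.
#' @return A normalized [spatial_expr()].
#' @export
normalize_tpm <- function(st) {
  if (any(st$expr < 0)) stop("negative entries cannot be normalized to TPM")
  cs <- colSums(st$expr)
  out <- spatial_expr(scale_columns(st$expr), st$coords)
  attr(out, "zero_spots") <- colnames(st$expr)[cs == 0]
  out
}

#' Evaluate predicted cell fractions against ground truth
#'
#' For each cell type shared between prediction and truth, Pearson r and
#' RMSE across spots; optionally, AUC of a fraction as the ranking score for
#' binary region annotations; and a shuffled-identity random control in
#' which the spot labels of the predictions are permuted before correlating.
#'
#' @param predicted spot x cell-type fraction matrix.
#' @param truth spot x cell-type matrix of true fractions (same spot set).
#' @param regions optional spot x region logical/0-1 matrix of annotations.
#' @param region_types named character vector mapping region -> the cell
#'   type whose fraction scores it (default: region name itself).
#' @param shuffle_seed seed for the shuffled-identity control (NULL skips).
#' @return An object of class `evaluation_report`: `per_type` data.frame
#'   (pearson_r, rmse, degenerate flag), `auc` data.frame, `shuffled`
#'   data.frame of control correlations.
#' @export
evaluate_predictions <- function(predicted, truth, regions = NULL,
                                 region_types = NULL, shuffle_seed = NULL) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  spots <- intersect(rownames(predicted), rownames(truth))
  if (length(spots) == 0) stop("prediction and truth share no spots")
  predicted <- predicted[spots, , drop = FALSE]
  truth <- truth[spots, , drop = FALSE]
  types <- intersect(colnames(predicted), colnames(truth))
  if (length(types) == 0) stop("prediction and truth share no cell types")

  one_r <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(c(0, TRUE))
    c(stats::cor(a, b), FALSE)
  }
  per_type <- do.call(rbind, lapply(types, function(tp) {
    rr <- one_r(predicted[, tp], truth[, tp])
    data.frame(cell_type = tp, pearson_r = rr[1],
               rmse = sqrt(mean((predicted[, tp] - truth[, tp])^2)),
               degenerate = as.logical(rr[2]))
  }))

  auc <- NULL
  if (!is.null(regions)) {
    regions <- as.matrix(regions)[spots, , drop = FALSE]
    if (is.null(region_types)) {
      region_types <- stats::setNames(colnames(regions), colnames(regions))
    }
    auc <- do.call(rbind, lapply(colnames(regions), function(rg) {
      tp <- region_types[[rg]]
      if (!tp %in% colnames(predicted)) return(NULL)
      lab <- as.logical(regions[, rg])
      if (all(lab) || !any(lab)) return(NULL)
      a <- as.numeric(pROC::auc(pROC::roc(response = lab,
                                          predictor = predicted[, tp],
                                          levels = c(FALSE, TRUE),
                                          direction = "<", quiet = TRUE)))
      data.frame(region = rg, cell_type = tp, auc = a)
    }))
  }

  shuffled <- NULL
  if (!is.null(shuffle_seed)) {
    perm <- withr::with_seed(shuffle_seed, sample(length(spots)))
    shuffled <- do.call(rbind, lapply(types, function(tp) {
      rr <- one_r(predicted[perm, tp], truth[, tp])
      data.frame(cell_type = tp, pearson_r = rr[1])
    }))
  }
  structure(list(per_type = per_type, auc = auc, shuffled = shuffled),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$per_type, row.names = FALSE)
  if (!is.null(x$auc)) print(x$auc, row.names = FALSE)
  if (!is.null(x$shuffled)) {
    cat(sprintf("  shuffled-control median r = %.3f\n",
                stats::median(x$shuffled$pearson_r)))
  }
  invisible(x)
}

#' Write / read a signature dictionary as TSV
#'
#' Genes are rows; one column per cancer type; the pan-cancer expression
#' signature occupies the reserved column name `Pan.Cancer` in the
#' expression file. CNA and expression dialects are separate files.
#'
#' @param dictionary a [signature_dictionary()].
#' @param expr_path,cna_path output TSV paths (cna optional).
#' @return Paths, invisibly.
#' @export
write_dictionary <- function(dictionary, expr_path, cna_path = NULL) {
  expr <- cbind(dictionary$expr, Pan.Cancer = dictionary$pan_cancer)
  utils::write.table(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cna_path) && !is.null(dictionary$cna)) {
    utils::write.table(data.frame(gene = rownames(dictionary$cna),
                                  dictionary$cna, check.names = FALSE),
                       cna_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(expr_path, cna_path))
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(expr_path, cna_path = NULL) {
  ex <- utils::read.delim(expr_path, row.names = 1, check.names = FALSE)
  pan <- NULL
  if ("Pan.Cancer" %in% colnames(ex)) {
    pan <- stats::setNames(ex[["Pan.Cancer"]], rownames(ex))
    ex <- ex[, setdiff(colnames(ex), "Pan.Cancer"), drop = FALSE]
  }
  cna <- if (!is.null(cna_path)) {
    as.matrix(utils::read.delim(cna_path, row.names = 1, check.names = FALSE))
  } else NULL
  signature_dictionary(cna = cna, expr = as.matrix(ex), pan_cancer = pan)
}

#' Write / read a hierarchical reference
#'
#' Profiles as a gene x cell-type TSV, markers as a two-column TSV
#' (cell_type, gene), and the lineage tree as YAML (sublineage: major).
#'
#' @param reference a [hier_reference()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(gene = rownames(reference$profiles),
                                reference$profiles, check.names = FALSE),
                     file.path(dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mk <- do.call(rbind, lapply(names(reference$markers), function(tp) {
    if (length(reference$markers[[tp]]) == 0) return(NULL)
    data.frame(cell_type = tp, gene = reference$markers[[tp]])
  }))
  utils::write.table(mk, file.path(dir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(as.list(reference$tree), file.path(dir, "tree.yaml"))
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  prof <- as.matrix(utils::read.delim(file.path(dir, "profiles.tsv"),
                                      row.names = 1, check.names = FALSE))
  mk <- utils::read.delim(file.path(dir, "markers.tsv"),
                          stringsAsFactors = FALSE)
  markers <- split(mk$gene, mk$cell_type)
  for (tp in setdiff(colnames(prof), names(markers))) {
    markers[[tp]] <- character(0)
  }
  tree <- unlist(yaml::read_yaml(file.path(dir, "tree.yaml")))
  hier_reference(prof, markers, tree)
}

#' Write ground-truth or predicted fractions as long-format TSV
#'
#' @param fractions spot x cell-type matrix.
#' @param path output TSV (columns spot, cell_type, fraction, stratum).
#' @param stratum optional per-spot stratum labels.
#' @return `path`, invisibly.
#' @export
write_fractions <- function(fractions, path, stratum = NULL) {
  long <- data.frame(
    spot = rep(rownames(fractions), times = ncol(fractions)),
    cell_type = rep(colnames(fractions), each = nrow(fractions)),
    fraction = as.vector(fractions))
  if (!is.null(stratum)) long$stratum <- rep(stratum, times = ncol(fractions))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
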