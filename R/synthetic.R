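#' Generate a synthetic single-cell profile set with planted markers
#'
#' Builds a gene-by-cell matrix in non-log TPM space where each cell type has
#' a contiguous block of marker genes expressed at elevated level over a
#' shared log-normal baseline, and cells are noisy log-normal replicates of
#' their type template. Any cell type whose major lineage is `"Malignant"`
#' additionally carries a copy-number-like dosage gradient imposed on
#' contiguous blocks of the non-marker gene range (emulating chromosome-arm
#' gains/losses), which the matching synthetic dictionary uses as its CNA
#' signature; keeping the gradient off the marker blocks keeps the two
#' planted signals orthogonal.
#'
#' The planted truth (templates, marker sets, CNA dosage profile) is stored
#' in the `meta` field so downstream recovery can be validated.
#'
#' @param n_genes number of genes; must be at least
#'   `length(cell_types) * markers_per_type`.
#' @param cell_types character vector of cell-type names. Defaults to six
#'   tumor-microenvironment types including `"Malignant"`.
#' @param markers_per_type number of planted marker genes per cell type.
#' @param n_cells_per_type cells simulated per type.
#' @param noise_level standard deviation of per-cell log-normal noise
#'   (0 = every cell equals its template exactly).
#' @param seed integer seed; the same seed reproduces the set bit-for-bit.
#' @param hierarchy named character vector mapping cell type -> major
#'   lineage. Defaults to each type being its own major lineage (with
#'   `"Malignant"` mapping to `"Malignant"`).
#' @param marker_fc fold elevation of marker genes over baseline.
#' @param sublineage_markers_per_type extra marker genes distinguishing each
#'   sublineage within a multi-child family (the family shares its major
#'   lineage's marker block, so sibling templates are highly correlated, as
#'   real sublineages are).
#' @param sublineage_fc fold elevation of sublineage-specific markers
#'   (defaults to half of `marker_fc`, floored at 2).
#' @param cna_blocks number of contiguous gene blocks of the non-marker gene
#'   range receiving a CNA dosage (values drawn from -1, -0.5, 0, 0.5, 1).
#' @param cna_effect expression effect multiplier: malignant templates are
#'   scaled by `2^(cna_effect * dosage)` per gene.
#' @param n_patients cells are assigned round-robin to this many patients.
#' @param template_seed optional separate seed for the template-level
#'   randomness (baseline expression, CNA dosage). Two calls sharing a
#'   `template_seed` but differing in `seed` emulate independent datasets of
#'   the same underlying cell biology, e.g. for inter-dataset validation
#'   where the deconvolution reference comes from different cells than the
#'   simulated spots.
#' @return A [single_cell_set()].
#' @export
generate_synthetic_scrna <- function(n_genes = 1000,
                                     cell_types = c("Malignant", "CAF",
                                                    "Endothelial", "Bcell",
                                                    "Tcell", "Macrophage"),
                                     markers_per_type = 50,
                                     n_cells_per_type = 200,
                                     noise_level = 0.5,
                                     seed = 1,
                                     hierarchy = NULL,
                                     marker_fc = 10,
                                     sublineage_markers_per_type = 15,
                                     sublineage_fc = NULL,
                                     cna_blocks = 20,
                                     cna_effect = 1,
                                     n_patients = 3,
                                     template_seed = NULL) {
  k <- length(cell_types)
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (is.null(hierarchy)) {
    hierarchy <- stats::setNames(cell_types, cell_types)
  }
  if (!all(cell_types %in% names(hierarchy))) {
    stop("hierarchy must cover every cell type")
  }
  if (is.null(sublineage_fc)) sublineage_fc <- max(2, marker_fc / 2)
  groups <- split(cell_types, unname(hierarchy[cell_types]))
  n_fam_members <- sum(lengths(groups)[lengths(groups) > 1])
  need <- length(groups) * markers_per_type +
    n_fam_members * sublineage_markers_per_type
  if (n_genes < need) {
    stop("marker budget exceeds gene count: need at least ", need, " genes")
  }

  withr::with_seed(template_seed %||% seed, {
    genes <- paste0("g", seq_len(n_genes))
    baseline <- stats::rlnorm(n_genes, meanlog = log(5), sdlog = 1)
    names(baseline) <- genes

    markers <- stats::setNames(vector("list", k), cell_types)
    templates <- matrix(rep(baseline, k), nrow = n_genes,
                        dimnames = list(genes, cell_types))
    # One shared marker block per major lineage; members of a multi-child
    # family add a small block of their own, so sibling templates are highly
    # correlated (as real sublineages are).
    cursor <- 0
    take <- function(n) {
      idx <- cursor + seq_len(n)
      cursor <<- cursor + n
      idx
    }
    for (g in names(groups)) {
      members <- groups[[g]]
      shared <- take(markers_per_type)
      for (m in members) {
        templates[shared, m] <- baseline[shared] * marker_fc
        markers[[m]] <- genes[shared]
      }
      if (length(members) > 1) {
        for (m in members) {
          own <- take(sublineage_markers_per_type)
          templates[own, m] <- baseline[own] * sublineage_fc
          markers[[m]] <- c(markers[[m]], genes[own])
        }
      }
    }

    # CNA-like dosage gradient over contiguous blocks of the non-marker gene
    # range, shared by all malignant types (their common genomic background).
    # Keeping the gradient off the planted marker blocks keeps the two
    # planted signals orthogonal, so ground-truth attribution stays clean.
    cna_profile <- rep(0, n_genes)
    names(cna_profile) <- genes
    mal_types <- names(hierarchy)[hierarchy == "Malignant"]
    mal_types <- intersect(mal_types, cell_types)
    if (length(mal_types)) {
      if (cursor >= n_genes) {
        warning("no non-marker genes left for the CNA gradient; ",
                "malignant templates carry no dosage effect")
      } else {
        free <- seq(cursor + 1, n_genes)
        nb <- min(cna_blocks, length(free))
        block <- sort(rep(seq_len(nb), length.out = length(free)))
        dosage <- sample(c(-1, -0.5, 0, 0.5, 1), nb, replace = TRUE)
        cna_profile[free] <- dosage[block]
        for (m in mal_types) {
          templates[, m] <- templates[, m] * 2^(cna_effect * cna_profile)
        }
      }
    }
    templates <- scale_columns(templates)
    NULL
  })

  withr::with_seed(seed, {
    n_cells <- k * n_cells_per_type
    expr <- matrix(0, n_genes, n_cells, dimnames = list(genes, NULL))
    cell_type <- rep(cell_types, each = n_cells_per_type)
    for (i in seq_len(k)) {
      cols <- ((i - 1) * n_cells_per_type + 1):(i * n_cells_per_type)
      base <- templates[, i]
      if (noise_level == 0) {
        expr[, cols] <- base
      } else {
        noise <- matrix(stats::rnorm(n_genes * length(cols), 0, noise_level),
                        n_genes, length(cols))
        expr[, cols] <- base * exp(noise)
      }
    }
    expr <- scale_columns(expr)
    colnames(expr) <- paste0("cell", seq_len(n_cells))
    patient <- paste0("P", (seq_len(n_cells) - 1) %% n_patients + 1)

    single_cell_set(expr, cell_type, hierarchy, patient = patient,
                    meta = list(templates = templates, markers = markers,
                                cna_profile = cna_profile,
                                baseline = baseline, marker_fc = marker_fc,
                                noise_level = noise_level))
  })
}

#' Simulation design for synthetic spot mixtures
#'
#' Describes how simulated spots are composed: the number of spots in each
#' malignant-fraction stratum (0%, 50%, 100% of cells malignant), the ranges
#' of nonmalignant cell-type counts and total cells per spot, and the
#' symmetric Dirichlet concentration used to draw type weights. A cell-type
#' pair may optionally be coupled: selecting one tends to pull in the other,
#' and the two then share a niche of varying intensity (a Beta(2, 2) share
#' of the nonmalignant budget, split equally, the rest going to at least one
#' filler type) — planting both a colocalization signal and a positive
#' amount correlation recoverable from the spot mixtures.
#'
#' @param n_spots_per_stratum named numeric vector over strata `"0"`, `"50"`,
#'   `"100"`; the default 500/200/500 yields 1200 spots.
#' @param n_types_range integer interval (lo, hi) for the number of
#'   nonmalignant cell types per spot.
#' @param n_cells_range integer interval (lo, hi) for total cells per spot.
#' @param dirichlet_alpha symmetric Dirichlet concentration for type weights.
#' @param coupled_pair optional length-2 character vector of nonmalignant
#'   types to co-occur.
#' @param coupling_prob probability that the partner type is added when
#'   exactly one of the coupled pair was drawn.
#' @param seed integer seed consumed by [simulate_st()].
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_spots_per_stratum = c("0" = 500, "50" = 200,
                                                      "100" = 500),
                              n_types_range = c(1L, 3L),
                              n_cells_range = c(3L, 10L),
                              dirichlet_alpha = 1,
                              coupled_pair = NULL,
                              coupling_prob = 0.9,
                              seed = 1) {
  if (!all(names(n_spots_per_stratum) %in% c("0", "50", "100"))) {
    stop("strata must be named '0', '50', '100'")
  }
  if (n_types_range[1] < 1 || n_types_range[2] < n_types_range[1]) {
    stop("n_types_range must be a nonempty interval with positive lower bound")
  }
  if (n_cells_range[1] < 1 || n_cells_range[2] < n_cells_range[1]) {
    stop("n_cells_range must be a nonempty interval with positive lower bound")
  }
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be positive")
  structure(list(n_spots_per_stratum = n_spots_per_stratum,
                 n_types_range = as.integer(n_types_range),
                 n_cells_range = as.integer(n_cells_range),
                 dirichlet_alpha = dirichlet_alpha,
                 coupled_pair = coupled_pair,
                 coupling_prob = coupling_prob,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate spatial transcriptomics spots from single-cell profiles
#'
#' For each spot, draws a number of nonmalignant cell types, weights from a
#' symmetric Dirichlet, and a total cell count; allocates cells to types by
#' largest-remainder rounding of the weights; samples that many cells from
#' the single-cell set; and averages their profiles as the spot signal. In
#' the 50% stratum, half of the spot's cells (rounding half up) are
#' malignant; in the 100% stratum all are. When several malignant types
#' (states) exist, each malignant spot draws its malignant cells from a
#' single randomly chosen state. Spots are laid out row-major on a square
#' lattice, ordered 0% then 50% then 100% stratum, so the malignant region
#' is spatially contiguous.
#'
#' @param sc a [single_cell_set()].
#' @param design a [simulation_design()]; its `seed` drives all randomness.
#' @return A list with elements `st` (a [spatial_expr()]), `truth` (a list
#'   with `fractions`: spot x cell-type matrix of realized cell-count
#'   proportions, `stratum`: per-spot label, `cells`: per-spot selected cell
#'   indices).
#' @export
simulate_st <- function(sc, design = simulation_design()) {
  if (ncol(sc$expression) == 0) stop("empty single-cell set")
  types <- unique(sc$cell_type)
  mal_types <- intersect(malignant_cell_types(sc), types)
  nonmal_types <- setdiff(types, mal_types)
  strata <- design$n_spots_per_stratum
  if (any(strata[names(strata) != "0"] > 0) && length(mal_types) == 0) {
    stop("a malignant stratum was requested but the set has no malignant cells")
  }
  if (length(nonmal_types) == 0 && any(strata[names(strata) != "100"] > 0)) {
    stop("a nonmalignant stratum was requested but the set has no nonmalignant cells")
  }
  cells_by_type <- split(seq_along(sc$cell_type), sc$cell_type)

  n_total <- sum(strata)
  stratum_label <- rep(names(strata), times = strata)
  fractions <- matrix(0, n_total, length(types),
                      dimnames = list(paste0("spot", seq_len(n_total)), types))
  expr <- matrix(0, nrow(sc$expression), n_total,
                 dimnames = list(rownames(sc$expression), rownames(fractions)))
  picked <- vector("list", n_total)

  draw_cells <- function(type, n) {
    pool <- cells_by_type[[type]]
    if (is.null(pool)) stop("no cells of type ", type)
    pool[sample.int(length(pool), n, replace = n > length(pool))]
  }
  rint <- function(lo, hi) if (lo == hi) lo else sample(seq(lo, hi), 1)

  withr::with_seed(design$seed, {
    for (s in seq_len(n_total)) {
      strat <- stratum_label[s]
      n_cells <- rint(design$n_cells_range[1], design$n_cells_range[2])
      n_mal <- switch(strat,
                      "0" = 0L,
                      "50" = as.integer(ceiling(n_cells / 2)),
                      "100" = n_cells)
      counts <- stats::setNames(integer(length(types)), types)
      if (n_mal > 0) {
        state <- if (length(mal_types) > 1) sample(mal_types, 1) else mal_types
        counts[state] <- n_mal
      }
      n_non <- n_cells - n_mal
      if (n_non > 0) {
        kt <- rint(design$n_types_range[1], design$n_types_range[2])
        kt <- min(kt, length(nonmal_types))
        chosen <- sample(nonmal_types, kt)
        pr <- design$coupled_pair
        if (!is.null(pr) && sum(pr %in% chosen) == 1 &&
            stats::runif(1) < design$coupling_prob) {
          chosen <- union(chosen, pr)
        }
        if (!is.null(pr) && all(pr %in% chosen)) {
          # The coupled types share a niche of varying intensity, split
          # equally; the remainder goes to filler types (at least one, so
          # the niche share is never pinned at the whole spot and its
          # variation survives into the fractions).
          filler <- setdiff(chosen, pr)
          if (length(filler) == 0) {
            pool <- setdiff(nonmal_types, pr)
            if (length(pool)) {
              filler <- sample(pool, 1)
              chosen <- c(chosen, filler)
            }
          }
          q <- if (length(filler)) stats::rbeta(1, 2, 2) else 1
          w <- numeric(length(chosen))
          w[match(pr, chosen)] <- q / 2
          if (length(filler)) {
            w[match(filler, chosen)] <-
              (1 - q) * rdirichlet1(rep(design$dirichlet_alpha, length(filler)))
          }
        } else {
          w <- rdirichlet1(rep(design$dirichlet_alpha, length(chosen)))
        }
        counts[chosen] <- counts[chosen] + largest_remainder(w, n_non)
      }
      idx <- unlist(lapply(types[counts > 0], function(tp)
        draw_cells(tp, counts[[tp]])), use.names = FALSE)
      expr[, s] <- rowMeans(sc$expression[, idx, drop = FALSE])
      fractions[s, ] <- counts / n_cells
      picked[[s]] <- idx
    }
  })

  ncolumns <- ceiling(sqrt(n_total))
  coords <- data.frame(x = (seq_len(n_total) - 1) %% ncolumns,
                       y = (seq_len(n_total) - 1) %/% ncolumns)
  st <- spatial_expr(expr, coords)
  list(st = st,
       truth = list(fractions = fractions,
                    stratum = stats::setNames(stratum_label, rownames(fractions)),
                    cells = picked))
}

#' Build a synthetic signature dictionary matching a generated set
#'
#' The CNA signature is the dosage gradient planted by
#' [generate_synthetic_scrna()]; the expression signature is the log2 fold
#' change of the mean malignant profile over the pooled nonmalignant mean
#' (genes with a zero mean in either group get 0). The pan-cancer signature
#' is the average over the expression signatures provided (here, one type).
#'
#' @param sc a [single_cell_set()] carrying a planted CNA gradient.
#' @param cancer_type_label column name for the synthetic cancer type.
#' @return A [signature_dictionary()].
#' @export
generate_synthetic_dictionary <- function(sc, cancer_type_label = "SYN") {
  mal <- sc$cell_type %in% malignant_cell_types(sc)
  if (!any(mal)) stop("single-cell set has no malignant type")
  if (is.null(sc$meta$cna_profile)) {
    stop("single-cell set carries no planted CNA gradient")
  }
  m_mean <- rowMeans(sc$expression[, mal, drop = FALSE])
  n_mean <- rowMeans(sc$expression[, !mal, drop = FALSE])
  lfc <- log2(m_mean / n_mean)
  lfc[!is.finite(lfc)] <- 0
  genes <- rownames(sc$expression)
  cna <- matrix(sc$meta$cna_profile[genes], ncol = 1,
                dimnames = list(genes, cancer_type_label))
  expr <- matrix(lfc, ncol = 1, dimnames = list(genes, cancer_type_label))
  signature_dictionary(cna = cna, expr = expr)
}

#' Downsample the genes detected in each spot
#'
#' Emulates shallow capture: per spot, a random subset of the expressed
#' genes of the requested size is retained (all of them if fewer), the rest
#' are zeroed, and the column is rescaled back to TPM.
#'
#' @param st a [spatial_expr()].
#' @param genes_per_spot number of expressed genes to keep per spot.
#' @param seed integer seed.
#' @return A [spatial_expr()].
#' @export
downsample_genes <- function(st, genes_per_spot, seed = 1) {
  if (genes_per_spot < 1) stop("genes_per_spot must be >= 1")
  expr <- st$expr
  withr::with_seed(seed, {
    for (s in seq_len(ncol(expr))) {
      nz <- which(expr[, s] > 0)
      if (length(nz) > genes_per_spot) {
        drop <- nz[-sample.int(length(nz), genes_per_spot)]
        expr[drop, s] <- 0
      }
    }
  })
  spatial_expr(scale_columns(expr), st$coords)
}

#' Add an unknown cell type overlapping a chosen share of reference markers
#'
#' Stress-test utility: appends cells of a new type (major lineage
#' `"Unknown"`) whose template elevates a controlled fraction of the given
#' marker genes, the remainder of its elevated genes falling outside the
#' marker space. Low overlap emulates an unknown type the marker-space
#' deconvolution can route to the unidentifiable component; high overlap
#' emulates one that contaminates known-type estimates.
#'
#' @param sc a [single_cell_set()] from [generate_synthetic_scrna()].
#' @param reference_markers character vector of marker genes (typically the
#'   union of reference marker sets).
#' @param overlap_fraction fraction of the new type's elevated genes drawn
#'   from `reference_markers`.
#' @param n_cells number of unknown cells to append.
#' @param n_elevated number of elevated genes in the unknown template.
#' @param seed integer seed.
#' @return A [single_cell_set()] including the `"Unknown"` type.
#' @export
add_unknown_type <- function(sc, reference_markers, overlap_fraction,
                             n_cells = 200, n_elevated = 50, seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]")
  }
  baseline <- sc$meta$baseline
  if (is.null(baseline)) stop("set lacks generator metadata")
  genes <- rownames(sc$expression)
  reference_markers <- intersect(reference_markers, genes)
  withr::with_seed(seed, {
    n_in <- round(overlap_fraction * n_elevated)
    n_out <- n_elevated - n_in
    inside <- sample(reference_markers, min(n_in, length(reference_markers)))
    outside_pool <- setdiff(genes, reference_markers)
    outside <- sample(outside_pool, min(n_out, length(outside_pool)))
    template <- baseline[genes]
    template[c(inside, outside)] <- template[c(inside, outside)] * sc$meta$marker_fc
    template <- template / sum(template) * 1e6
    noise_level <- sc$meta$noise_level %||% 0
    new <- if (noise_level == 0) {
      matrix(rep(template, n_cells), nrow = length(genes))
    } else {
      template * exp(matrix(stats::rnorm(length(genes) * n_cells, 0, noise_level),
                            length(genes), n_cells))
    }
    new <- scale_columns(new)
    rownames(new) <- genes
    colnames(new) <- paste0("ucell", seq_len(n_cells))
    single_cell_set(cbind(sc$expression, new),
                    c(sc$cell_type, rep("Unknown", n_cells)),
                    c(sc$hierarchy, Unknown = "Unknown"),
                    patient = c(sc$patient, rep("PU", n_cells)),
                    meta = sc$meta)
  })
}
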