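#' Configuration for a synthetic single-cell reference
#'
#' Describes a labeled single-cell reference sharing its gene universe with the
#' bulk simulator. Per cell type, a set of disjoint marker genes is planted at
#' \code{marker_enrichment_fold} times the shared baseline rate, so that
#' planted markers satisfy the detection-fraction floor (0.5\%) and the 1.5x
#' specificity margin in expectation; all other gene/type combinations share
#' the Poisson baseline.
#'
#' @param cell_types named integer vector of cells per type.
#' @param n_genes size of the gene universe (ignored when \code{gene_ids} given).
#' @param gene_ids optional explicit gene identifiers (e.g. those of a
#'   simulated bulk cohort, to share the universe).
#' @param markers_per_type number of planted markers per cell type.
#' @param marker_genes optional named list (cell type -> gene ids) overriding
#'   the random marker selection; sets must be disjoint. Used to co-plant bulk
#'   trajectory-program genes as markers of their cell type.
#' @param marker_enrichment_fold expression fold of a marker in its own type
#'   relative to baseline; must exceed 1.5 so planted markers satisfy the
#'   specificity rule in expectation.
#' @param detection_baseline baseline per-cell detection probability in [0,1)
#'   for non-marker expression. The default (0.25) is typical of moderately
#'   expressed genes in liver single-nucleus references and keeps the Poisson
#'   standard error of a per-type mean several-fold below the 1.5x
#'   specificity margin at a few hundred cells per type, so baseline genes
#'   are stably "unspecific".
#' @param seed integer seed.
#' @return an object of class \code{sc_sim_config}.
#' @export
sc_sim_config <- function(cell_types = c(hepatocyte = 200L, cholangiocyte = 200L,
                                         fibroblast = 200L, macrophage = 200L,
                                         tcell = 200L),
                          n_genes = 2000L,
                          gene_ids = NULL,
                          markers_per_type = 10L,
                          marker_genes = NULL,
                          marker_enrichment_fold = 10,
                          detection_baseline = 0.25,
                          seed = 1L) {
  if (is.null(names(cell_types)) || any(cell_types < 1))
    stop_fib("cell_types must be a named vector of positive cell counts")
  if (marker_enrichment_fold <= 1.5)
    stop_fib("marker_enrichment_fold must exceed the 1.5x specificity margin")
  if (detection_baseline < 0 || detection_baseline >= 1)
    stop_fib("detection_baseline must lie in [0, 1)")
  if (!is.null(gene_ids)) {
    if (anyDuplicated(gene_ids)) stop_fib("duplicate gene_ids")
    n_genes <- length(gene_ids)
  }
  if (!is.null(marker_genes)) {
    if (!all(names(marker_genes) %in% names(cell_types)))
      stop_fib("marker_genes names must be cell types")
    all_m <- unlist(marker_genes, use.names = FALSE)
    if (anyDuplicated(all_m))
      stop_fib("marker sets must be disjoint; duplicated: ",
               all_m[duplicated(all_m)][1])
  }
  structure(list(cell_types = cell_types, n_genes = as.integer(n_genes),
                 gene_ids = gene_ids, markers_per_type = as.integer(markers_per_type),
                 marker_genes = marker_genes,
                 marker_enrichment_fold = marker_enrichment_fold,
                 detection_baseline = detection_baseline, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Construct a labeled single-cell reference
#'
#' Light container for a sparse genes x cells expression matrix plus per-cell
#' cell-type labels, as used by the cell-type mapping functions.
#'
#' @param counts a genes x cells matrix (dense or \code{Matrix} sparse),
#'   non-negative, with gene rownames.
#' @param cell_type character or factor of length \code{ncol(counts)}.
#' @return an object of class \code{sc_ref}.
#' @export
sc_reference <- function(counts, cell_type) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts))) stop_fib("counts must carry gene rownames")
  if (length(cell_type) != ncol(counts))
    stop_fib("cell_type must label every cell (one per column)")
  if (anyNA(cell_type)) stop_fib("every cell must be labeled")
  if (any(counts@x < 0)) stop_fib("expression must be non-negative")
  cell_type <- factor(as.character(cell_type))
  if (nlevels(cell_type) < 1L) stop_fib("cell type list must be non-empty")
  structure(list(counts = counts, cell_type = cell_type), class = "sc_ref")
}

#' @export
print.sc_ref <- function(x, ...) {
  cat("Single-cell reference:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", nlevels(x$cell_type), "cell types\n")
  print(table(x$cell_type))
  invisible(x)
}

#' Simulate a single-cell reference with planted markers
#'
#' Counts are Poisson around type-specific rates: baseline rate
#' \eqn{\lambda_0 = -\log(1 - d)} (so the expected detection fraction of a
#' non-marker gene is \code{detection_baseline} \eqn{d}), markers at
#' \eqn{\lambda_0 \times} \code{marker_enrichment_fold} within their own type.
#'
#' @param config an \code{\link{sc_sim_config}}.
#' @return list with \code{ref} (an \code{\link{sc_reference}}) and
#'   \code{truth} (data frame gene, cell_type with planted specificity label,
#'   \code{"unspecific"} for non-markers).
#' @export
simulate_sc_reference <- function(config) {
  if (!inherits(config, "sc_sim_config"))
    stop_fib("config must be built with sc_sim_config()")
  with_seed(config$seed, {
    genes <- config$gene_ids %||% sprintf("g%05d", seq_len(config$n_genes))
    ng <- length(genes)
    types <- names(config$cell_types)
    marker_genes <- config$marker_genes %||% list()
    if (!all(unlist(marker_genes) %in% genes))
      stop_fib("marker_genes contain identifiers outside the gene universe")
    # types without an explicit marker set get a random disjoint one
    pool <- sample(setdiff(genes, unlist(marker_genes)))
    for (t in setdiff(types, names(marker_genes))) {
      marker_genes[[t]] <- pool[seq_len(config$markers_per_type)]
      pool <- pool[-seq_len(config$markers_per_type)]
    }

    # baseline rate giving expected detection fraction = detection_baseline;
    # markers keep a floor at the 0.5% eligibility rate so a zero baseline
    # still yields detectable markers (and zero non-marker fractions)
    lam0 <- -log(1 - config$detection_baseline)
    lam_marker <- config$marker_enrichment_fold * max(lam0, -log(1 - 0.005))
    cell_type <- factor(rep(types, times = config$cell_types), levels = types)
    n_cells <- length(cell_type)
    blocks <- lapply(types, function(t) {
      nc <- config$cell_types[[t]]
      lam <- rep(lam0, ng)
      names(lam) <- genes
      lam[marker_genes[[t]] %||% character(0)] <- lam_marker
      m <- matrix(rpois(ng * nc, lambda = rep(lam, nc)), nrow = ng, ncol = nc)
      rownames(m) <- genes
      m
    })
    counts <- methods::as(Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE),
                          "CsparseMatrix")
    colnames(counts) <- sprintf("c%05d", seq_len(n_cells))

    truth <- data.frame(gene = genes, cell_type = "unspecific",
                        stringsAsFactors = FALSE)
    for (t in types) truth$cell_type[truth$gene %in% marker_genes[[t]]] <- t

    list(ref = sc_reference(counts, cell_type), truth = truth)
  })
}
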