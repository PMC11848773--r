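# Cell-type mapping against a labeled single-cell reference: detection
# fractions, enrichment log fold changes, the 1.5x specificity rule, and
# cell-type scoring along PCA-defined fibrosis trajectories.

type_indicator <- function(ref) {
  # cells x types 0/1 sparse indicator
  ct <- ref$cell_type
  Matrix::sparseMatrix(i = seq_along(ct), j = as.integer(ct), x = 1,
                       dims = c(length(ct), nlevels(ct)),
                       dimnames = list(colnames(ref$counts), levels(ct)))
}

#' Per-type detection fractions
#'
#' Fraction of cells of each type with nonzero expression of each gene; a
#' gene is eligible for specificity assignment in a type when its fraction
#' reaches the 0.5\% floor.
#'
#' @param ref an \code{\link{sc_reference}}.
#' @return genes x types matrix of fractions in [0,1].
#' @export
detection_fractions <- function(ref) {
  stopifnot(inherits(ref, "sc_ref"))
  n_per_type <- table(ref$cell_type)
  if (any(n_per_type == 0L))
    stop_fib("cell type with zero cells: ",
             names(n_per_type)[n_per_type == 0][1])
  ind <- type_indicator(ref)
  detected <- ref$counts
  detected@x <- as.numeric(detected@x > 0)   # robust to stored zeros
  f <- as.matrix(detected %*% ind)
  sweep(f, 2L, as.numeric(n_per_type), `/`)
}

#' Per-type mean expression
#'
#' @param ref an \code{\link{sc_reference}}.
#' @return genes x types matrix of mean raw expression.
#' @export
mean_expression <- function(ref) {
  stopifnot(inherits(ref, "sc_ref"))
  ind <- type_indicator(ref)
  m <- as.matrix(ref$counts %*% ind)
  sweep(m, 2L, as.numeric(table(ref$cell_type)), `/`)
}

#' Enrichment log fold change per cell type
#'
#' For each gene and type, \eqn{\log((m_t + \epsilon)/(m_{\neg t} + \epsilon))}
#' where \eqn{m_{\neg t}} is the mean over all cells not of type t (natural
#' log). \eqn{\epsilon} is a small constant relative to the gene's global mean
#' guarding against zeros.
#'
#' @param ref an \code{\link{sc_reference}}.
#' @param genes optional subset of gene identifiers.
#' @param eps_rel relative epsilon (default 1e-9 of the global mean, floored
#'   at 1e-12 for all-zero genes).
#' @return genes x types matrix of log fold changes.
#' @export
enrichment_logfc <- function(ref, genes = NULL, eps_rel = 1e-9) {
  stopifnot(inherits(ref, "sc_ref"))
  m <- mean_expression(ref)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) stop_fib("gene(s) not in reference: ", miss[1])
    m <- m[genes, , drop = FALSE]
  }
  n_t <- as.numeric(table(ref$cell_type))
  n_tot <- sum(n_t)
  tot <- m %*% n_t                      # per-gene total expression
  glob <- drop(tot) / n_tot
  eps <- pmax(glob * eps_rel, 1e-12)
  other <- sweep(-sweep(m, 2L, n_t, `*`), 1L, drop(tot), `+`)  # total minus type
  other <- sweep(other, 2L, n_tot - n_t, `/`)
  log((m + eps) / (other + eps))
}

#' Assign cell-type specificity to genes
#'
#' Implements the reference-based specificity rule: per gene, cell types with
#' detection fraction below \code{detection_min} (default 0.5\%) are dropped
#' ("undetected" when none remain); among the eligible types, the gene is
#' assigned to the type with the highest mean expression if and only if that
#' mean is at least \code{specificity_fold} (default 1.5, i.e. 50\% higher)
#' times the next-highest eligible mean — boundary inclusive; otherwise it is
#' labeled "unspecific". A single eligible type counts as specific.
#'
#' @param ref an \code{\link{sc_reference}}.
#' @param genes optional subset of gene identifiers (default: all genes in
#'   the reference).
#' @param detection_min detection-fraction floor (inclusive).
#' @param specificity_fold required mean-expression margin (inclusive).
#' @return data frame of class \code{specificity_calls}: gene, label (a cell
#'   type, "unspecific" or "undetected"), top_type, top_mean, second_mean,
#'   n_eligible.
#' @export
assign_specificity <- function(ref, genes = NULL, detection_min = 0.005,
                               specificity_fold = 1.5) {
  stopifnot(inherits(ref, "sc_ref"))
  f <- detection_fractions(ref)
  m <- mean_expression(ref)
  if (is.null(genes)) genes <- rownames(m)
  miss <- setdiff(genes, rownames(m))
  if (length(miss))
    stop_fib("gene(s) not in reference: ", paste(head(miss, 3), collapse = ", "))
  types <- colnames(m)
  out <- lapply(genes, function(g) {
    elig <- f[g, ] >= detection_min
    if (!any(elig))
      return(data.frame(gene = g, label = "undetected", top_type = NA_character_,
                        top_mean = NA_real_, second_mean = NA_real_,
                        n_eligible = 0L, stringsAsFactors = FALSE))
    me <- sort(m[g, ][elig], decreasing = TRUE)
    top <- names(me)[1]
    second <- if (length(me) > 1L) me[2] else NA_real_
    specific <- length(me) == 1L ||
      (me[1] >= specificity_fold * second && me[1] > 0)
    data.frame(gene = g, label = if (specific) top else "unspecific",
               top_type = top, top_mean = unname(me[1]),
               second_mean = unname(second), n_eligible = sum(elig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("specificity_calls", "data.frame")
  out
}

#' Long-format dot-plot table
#'
#' One row per gene x cell type with detection fraction, enrichment logFC,
#' eligibility under the detection floor, and the assignment flag — enough to
#' regenerate a dot plot of the specificity mapping.
#'
#' @param ref an \code{\link{sc_reference}}.
#' @param genes optional subset of genes.
#' @param detection_min,specificity_fold see \code{\link{assign_specificity}}.
#' @return data frame: gene, cell_type, fraction, mean_expr, logfc, eligible,
#'   assigned, label.
#' @export
dotplot_table <- function(ref, genes = NULL, detection_min = 0.005,
                          specificity_fold = 1.5) {
  calls <- assign_specificity(ref, genes, detection_min, specificity_fold)
  f <- detection_fractions(ref)
  m <- mean_expression(ref)
  lfc <- enrichment_logfc(ref)
  types <- colnames(f)
  long <- expand.grid(gene = calls$gene, cell_type = types,
                      stringsAsFactors = FALSE)
  ij <- cbind(match(long$gene, rownames(f)), match(long$cell_type, types))
  long$fraction <- f[ij]
  long$mean_expr <- m[ij]
  long$logfc <- lfc[ij]
  long$eligible <- long$fraction >= detection_min
  lab <- setNames(calls$label, calls$gene)
  long$label <- unname(lab[long$gene])
  long$assigned <- long$label == long$cell_type
  long[order(long$gene, long$cell_type), , drop = FALSE]
}

#' Normalize a single-cell reference for trajectory projection
#'
#' Library-size normalization (counts per \code{scale_factor}), \code{log1p},
#' then per-gene standardization to zero mean and unit variance.
#' Zero-variance genes are set to all-zero and flagged; zero-count cells are
#' dropped with a warning.
#'
#' @param ref an \code{\link{sc_reference}}.
#' @param scale_factor library-size target (default 1e4).
#' @param library_size,log_transform toggles for the first two steps (both
#'   \code{TRUE} by default; the standardization step always runs).
#' @return dense cells x genes matrix with attributes
#'   \code{constant_genes} (character) and \code{cell_type} (per retained
#'   cell).
#' @export
normalize_sc_for_projection <- function(ref, scale_factor = 1e4,
                                        library_size = TRUE,
                                        log_transform = TRUE) {
  stopifnot(inherits(ref, "sc_ref"))
  x <- ref$counts                       # genes x cells
  ct <- ref$cell_type
  totals <- Matrix::colSums(x)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-count cell(s) dropped")
    keep <- totals > 0
    x <- x[, keep, drop = FALSE]
    ct <- droplevels(ct[keep])
    totals <- totals[keep]
  }
  z <- t(as.matrix(x))                  # cells x genes
  if (library_size) z <- z / totals * scale_factor
  if (log_transform) z <- log1p(z)
  mu <- colMeans(z)
  sdv <- apply(z, 2L, sd)
  const <- sdv == 0 | !is.finite(sdv)
  z <- sweep(z, 2L, mu, `-`)
  z[, !const] <- sweep(z[, !const, drop = FALSE], 2L, sdv[!const], `/`)
  z[, const] <- 0
  attr(z, "constant_genes") <- colnames(z)[const]
  attr(z, "cell_type") <- ct
  z
}

weighted_quantile <- function(x, w, q = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  x[which(cw >= q)[1]]
}

# Scott's rule bandwidth for a weighted sample (effective n = 1/sum(w^2)).
bw_scott_weighted <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sigma <- sqrt(max(sum(w * (x - mu)^2), 1e-12))
  n_eff <- 1 / sum(w^2)
  1.06 * sigma * n_eff^(-1 / 5)
}

#' Cell-type scores along an oriented fibrosis-axis component
#'
#' Projects the fibrosis trajectory defined by an oriented bulk principal
#' component onto the single-cell reference. Two linked computations are
#' returned: (i) the gene-level view (default for densities) — each gene is
#' assigned a cell-type specificity label by the detection-floor / 1.5x rule
#' (\code{\link{assign_specificity}}) and, per cell type, a kernel density is
#' computed over the PC coefficients of the genes assigned to it
#' (\code{density_weights = "assigned"}); alternatively every gene enters
#' every type's density weighted by its detection-fraction share
#' \eqn{f_{t,g} / \sum_{t'} f_{t',g}} (\code{"share"}); and (ii) the
#' cell-level view — each cell's score \eqn{\sum_g w_g z_{c,g}} over the
#' normalized expression matrix. Genes absent from the reference are dropped
#' and counted.
#'
#' @param ref an \code{\link{sc_reference}}.
#' @param pca a \code{\link{pca_with_orientation}} result (bulk fibrosis axis).
#' @param component which component to project (default 1).
#' @param genes optional gene subset (e.g. a validated signature); default:
#'   all genes shared between the PC loadings and the reference.
#' @param normalized optional pre-computed
#'   \code{\link{normalize_sc_for_projection}} matrix (computed on demand).
#' @param grid_n density grid size.
#' @param bw kernel bandwidth; \code{"scott"} (weighted Scott's rule, the
#'   default) or a positive number.
#' @param density_weights \code{"assigned"} (default: per type, equal-weight
#'   KDE over the coefficients of the genes the specificity rule assigns to
#'   it) or \code{"share"} (all genes, detection-fraction-share weights).
#' @param detection_min,specificity_fold specificity-rule thresholds used for
#'   the \code{"assigned"} densities.
#' @return object of class \code{trajectory_score}: \code{component},
#'   \code{orientation_sign}, \code{ranking} (gene, weight, rank — descending
#'   weight), \code{densities} (cell_type, x, density; each integrates to 1),
#'   \code{type_summary} (cell_type, median_coef, median_cell_score),
#'   \code{cell_scores} (cell, cell_type, score), \code{n_genes_used},
#'   \code{n_genes_dropped}.
#' @export
trajectory_scores <- function(ref, pca, component = 1L, genes = NULL,
                              normalized = NULL, grid_n = 512L, bw = "scott",
                              density_weights = c("assigned", "share"),
                              detection_min = 0.005, specificity_fold = 1.5) {
  density_weights <- match.arg(density_weights)
  stopifnot(inherits(ref, "sc_ref"), inherits(pca, "fib_pca"))
  if (component > ncol(pca$loadings)) stop_fib("component not in PCA result")
  w_all <- pca$loadings[, component]
  genes <- genes %||% names(w_all)
  shared <- intersect(intersect(genes, names(w_all)), rownames(ref$counts))
  n_drop <- length(genes) - length(shared)
  if (!length(shared))
    stop_fib("no genes shared between the PC loadings and the reference")
  if (n_drop > 0)
    message(n_drop, " gene(s) absent from the reference dropped from projection")
  w <- w_all[shared]

  # cell-level projection
  if (is.null(normalized)) normalized <- normalize_sc_for_projection(ref)
  z <- normalized[, shared, drop = FALSE]
  cell_scores <- data.frame(cell = rownames(z),
                            cell_type = attr(normalized, "cell_type"),
                            score = drop(z %*% w), stringsAsFactors = FALSE)

  # gene-level coefficient densities per cell type
  f <- detection_fractions(ref)[shared, , drop = FALSE]
  types <- colnames(f)
  if (density_weights == "share") {
    share <- f / pmax(rowSums(f), .Machine$double.eps)
    share[rowSums(f) == 0, ] <- 0
    type_weights <- lapply(setNames(types, types), function(t) share[, t])
  } else {
    calls <- assign_specificity(ref, shared, detection_min, specificity_fold)
    type_weights <- lapply(setNames(types, types), function(t)
      as.numeric(calls$label == t))
  }
  xr <- range(w)
  pad <- diff(xr) * 0.25 + 1e-9
  grid_from <- xr[1] - pad; grid_to <- xr[2] + pad
  dens <- lapply(types, function(t) {
    wt <- type_weights[[t]]
    if (sum(wt > 0) < 2L) return(NULL)
    bwv <- if (identical(bw, "scott")) bw_scott_weighted(w, wt) else bw
    bwv <- max(bwv, diff(xr) * 1e-3, 1e-9)
    d <- density(w, weights = wt / sum(wt), bw = bwv, n = grid_n,
                 from = grid_from, to = grid_to)
    data.frame(cell_type = t, x = d$x, density = d$y,
               stringsAsFactors = FALSE)
  })
  densities <- do.call(rbind, dens)
  type_summary <- data.frame(
    cell_type = types,
    n_genes = vapply(types, function(t) sum(type_weights[[t]] > 0), integer(1)),
    median_coef = vapply(types, function(t) {
      if (sum(type_weights[[t]]) <= 0) NA_real_
      else weighted_quantile(w, type_weights[[t]])
    }, numeric(1)),
    median_cell_score = vapply(types, function(t)
      median(cell_scores$score[cell_scores$cell_type == t]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  ranking <- data.frame(gene = shared, weight = unname(w),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$weight), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL

  structure(list(component = component,
                 orientation_sign = pca$orientation_sign[component],
                 ranking = ranking, densities = densities,
                 type_summary = type_summary, cell_scores = cell_scores,
                 n_genes_used = length(shared), n_genes_dropped = n_drop),
            class = "trajectory_score")
}

#' @export
print.trajectory_score <- function(x, ...) {
  cat("Trajectory scores along component", x$component,
      "(sign", x$orientation_sign, "):", x$n_genes_used, "genes used,",
      x$n_genes_dropped, "dropped\n")
  print(x$type_summary)
  invisible(x)
}

#' Plot cell-type densities along the fibrosis axis
#'
#' @param x a \code{\link{trajectory_scores}} result.
#' @param ... forwarded to \code{matplot}.
#' @export
plot.trajectory_score <- function(x, ...) {
  d <- x$densities
  types <- unique(d$cell_type)
  xs <- unique(d$x)
  ym <- vapply(types, function(t) d$density[d$cell_type == t],
               numeric(length(xs)))
  graphics::matplot(xs, ym, type = "l", lty = 1, lwd = 2,
                    xlab = "oriented PC gene weight (fibrosis axis)",
                    ylab = "density", ...)
  graphics::abline(v = 0, col = "grey", lty = 2)
  graphics::legend("topright", legend = types, col = seq_along(types),
                   lty = 1, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
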