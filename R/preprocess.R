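#' Filter genes by count support
#'
#' Default reading of the ">= 10 counts" filter: retain genes whose summed
#' count across samples reaches \code{min_total} (standard practice for bulk
#' count matrices). \code{mode = "each"} is a strict alternative requiring the
#' threshold in every sample.
#'
#' @param counts genes x samples integer matrix.
#' @param min_total count threshold (default 10).
#' @param mode \code{"total"} (sum across samples, default) or \code{"each"}
#'   (every sample individually).
#' @return the filtered count matrix; gene order preserved.
#' @export
filter_low_counts <- function(counts, min_total = 10, mode = c("total", "each")) {
  mode <- match.arg(mode)
  check_count_matrix(counts)
  keep <- if (mode == "total") rowSums(counts) >= min_total
          else apply(counts, 1L, min) >= min_total
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample \eqn{j},
#' \eqn{s_j = \mathrm{median}_g\, y_{gj} / (\prod_k y_{gk})^{1/m}} taken over
#' genes with a positive geometric mean (equivalently, genes expressed in all
#' samples).
#'
#' @param counts genes x samples count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  loggeo <- rowMeans(log(counts))        # -Inf where any zero
  use <- is.finite(loggeo)
  if (!any(use))
    stop_fib("no gene is expressed in every sample; filter the count matrix ",
             "(filter_low_counts) or provide deeper data")
  sf <- apply(log(counts[use, , drop = FALSE]) - loggeo[use], 2L,
              function(lr) exp(median(lr)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop_fib("size factor estimation failed (non-positive factor)")
  sf
}

#' Normalized log2 transform
#'
#' \eqn{x_{gj} = \log_2(y_{gj}/s_j + 1)}: a monotone variance-taming transform
#' of normalized counts for PCA and visualisation (a pragmatic substitute for
#' heavier regularized-log transforms; see the methods vignette).
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample size factors (from \code{\link{size_factors}}).
#' @return real matrix of the same shape.
#' @export
log_transform <- function(counts, factors) {
  check_count_matrix(counts)
  if (length(factors) != ncol(counts))
    stop_fib("need one size factor per sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop_fib("size factors must be positive and finite")
  log2(sweep(counts, 2L, factors, `/`) + 1)
}

#' PCA with fibrosis-axis sign orientation
#'
#' Principal component analysis of samples (genes centered, optionally
#' scaled), followed by an orientation step: each component whose scores
#' correlate negatively (Spearman) with the fibrosis stage is flipped, so that
#' positive scores always point towards higher fibrosis. Zero-variance or
#' undefined correlations leave the sign at +1.
#'
#' @param x genes x samples real matrix (e.g. from \code{\link{log_transform}}).
#' @param meta sample metadata (used for its \code{stage} column); may be
#'   \code{NULL} if \code{stage} is given.
#' @param n_components number of components to keep.
#' @param stage optional explicit per-sample fibrosis stage vector.
#' @param scale_genes scale genes to unit variance before decomposition
#'   (default \code{FALSE}; constant genes are dropped from scaling).
#' @return object of class \code{fib_pca}: \code{scores} (samples x k),
#'   \code{loadings} (genes x k, orthonormal columns),
#'   \code{explained_variance} (fraction per component, non-increasing),
#'   \code{orientation_sign} (+1/-1 per component), \code{stage}.
#' @export
pca_with_orientation <- function(x, meta = NULL, n_components = 2L,
                                 stage = NULL, scale_genes = FALSE) {
  if (ncol(x) < 2L) stop_fib("PCA needs at least 2 samples")
  if (is.null(stage)) {
    if (is.null(meta)) stop_fib("provide meta or stage")
    meta <- align_counts_meta(x, meta)
    stage <- meta$stage
  }
  if (length(stage) != ncol(x)) stop_fib("need one stage per sample")
  kmax <- min(ncol(x) - 1L, nrow(x))
  if (n_components > kmax)
    stop_fib("n_components (", n_components, ") exceeds min(dims) = ", kmax)
  xs <- t(x)
  if (scale_genes) {
    sdv <- apply(xs, 2L, sd)
    xs[, sdv > 0] <- scale(xs[, sdv > 0, drop = FALSE])
    xs[, sdv == 0] <- scale(xs[, sdv == 0, drop = FALSE], scale = FALSE)
    p <- prcomp(xs, center = TRUE, scale. = FALSE)
  } else {
    p <- prcomp(xs, center = TRUE, scale. = FALSE)
  }
  k <- seq_len(n_components)
  scores <- p$x[, k, drop = FALSE]
  loadings <- p$rotation[, k, drop = FALSE]
  signs <- vapply(k, function(i) {
    s <- scores[, i]
    if (sd(s) == 0 || sd(stage) == 0) return(1)
    rho <- suppressWarnings(cor(s, stage, method = "spearman"))
    if (is.na(rho) || rho >= 0) 1 else -1
  }, numeric(1))
  scores <- sweep(scores, 2L, signs, `*`)
  loadings <- sweep(loadings, 2L, signs, `*`)
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[k], orientation_sign = signs,
                 center = p$center, stage = stage),
            class = "fib_pca")
}

#' @export
print.fib_pca <- function(x, ...) {
  cat("Oriented PCA:", nrow(x$loadings), "genes,", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  cat("  orientation signs:", paste(x$orientation_sign, collapse = ", "), "\n")
  invisible(x)
}
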