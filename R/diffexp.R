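# Negative-binomial Wald differential expression, DESeq2-style:
# median-of-ratios offsets, per-gene Cox-Reid dispersion ML, parametric
# mean-dispersion trend, MAP shrinkage, Wald test on the category coefficient.

# One IRLS fit of the NB log-link GLM at fixed dispersion, with a weak ridge
# for stability when a group has all-zero counts.
nb_irls <- function(y, X, off, alpha, ridge = 1e-6, maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  rI <- diag(ridge, p)
  beta <- tryCatch(
    drop(solve(crossprod(X) + rI, crossprod(X, log(y + 0.5) - off))),
    error = function(e) rep(0, p))
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + off, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    beta_new <- tryCatch(
      drop(solve(crossprod(X, w * X) + rI, crossprod(X, w * z))),
      error = function(e) beta)
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done) break
  }
  eta <- pmin(pmax(drop(X %*% beta) + off, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  list(beta = beta, mu = mu, XtWX = crossprod(X, w * X) + rI)
}

# Cox-Reid adjusted NB log-likelihood in alpha, at fixed fitted means.
cr_loglik <- function(alpha, y, mu, X) {
  w <- mu / (1 + alpha * mu)
  ll <- sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  adj <- 0.5 * as.numeric(determinant(crossprod(X, w * X),
                                      logarithm = TRUE)$modulus)
  ll - adj
}

# Parametric dispersion trend alpha(mu) = a0/mu + a1, fitted by iterated
# gamma-weighted least squares over well-behaved genes.
fit_dispersion_trend <- function(mean_norm, alpha_gw,
                                 alpha_range = c(1e-8, 10)) {
  use <- alpha_gw > alpha_range[1] * 10 & alpha_gw < alpha_range[2] * 0.9 &
    mean_norm > 0.5
  if (sum(use) < 10L) {
    a <- c(0, max(median(alpha_gw), alpha_range[1]))
  } else {
    x <- 1 / mean_norm[use]
    yv <- alpha_gw[use]
    a <- c(0, median(yv))
    Xm <- cbind(x, 1)
    for (it in 1:20) {
      fitv <- pmax(a[1] * x + a[2], 1e-8)
      w <- 1 / fitv^2                          # gamma-family variance weights
      a_new <- tryCatch(
        pmax(drop(solve(crossprod(Xm, w * Xm), crossprod(Xm, w * yv))),
             c(0, 1e-8)),
        error = function(e) a)
      if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
      a <- a_new
    }
  }
  list(coef = c(asymptote = a[2], extra = a[1]),
       fun = function(mu) pmax(a[1] / pmax(mu, 1e-8) + a[2], 1e-8))
}

#' Fit per-gene negative-binomial GLMs for differential expression
#'
#' For each gene, fits \eqn{y_j \sim NB(\mu_j, \alpha_g)} with
#' \eqn{\log \mu_j = \log s_j + x_j^T \beta} where the design contains an
#' intercept, the covariates (default: sex) and the fibrosis category
#' (early = reference). Dispersions are estimated per gene by Cox-Reid
#' adjusted maximum likelihood, a parametric mean-dispersion trend
#' \eqn{\alpha(\mu) = a_1/\mu + a_0} is fitted across genes, and gene-wise
#' estimates are shrunk towards the trend by maximum a posteriori estimation
#' with a log-normal prior. Fold changes are reported unshrunk, in log2.
#'
#' @param counts filtered genes x samples count matrix (no all-zero genes).
#' @param meta sample metadata (see \code{\link{read_meta}}); must contain the
#'   covariate columns and \code{fibrosis_category} (or stage + scheme).
#' @param disease optional disease label to subset samples.
#' @param covariates character vector of metadata columns to adjust for
#'   (default \code{"sex"}); use \code{character(0)} for none.
#' @param size_factors optional per-sample factors; computed by the
#'   median-of-ratios method when missing.
#' @param dispersion optional fixed dispersion (scalar or per-gene) to skip
#'   estimation.
#' @param shrink_dispersion shrink gene-wise dispersions towards the trend
#'   (default \code{TRUE}).
#' @param ridge weak L2 penalty on coefficients for numerical stability.
#' @return an object of class \code{nb_fit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{results}, \code{plot}.
#' @seealso \code{\link{results.nb_fit}}, \code{\link{wald_test}},
#'   \code{\link{call_degs}}
#' @export
nb_fit <- function(counts, meta, disease = NULL, covariates = "sex",
                   size_factors = NULL, dispersion = NULL,
                   shrink_dispersion = TRUE, ridge = 1e-6) {
  check_count_matrix(counts)
  meta <- check_sample_meta(meta)
  meta <- align_counts_meta(counts, meta)
  if (!is.null(disease)) {
    keep <- meta$disease %in% disease
    if (!any(keep)) stop_fib("no samples for disease ", disease)
    counts <- counts[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (any(table(meta$fibrosis_category) < 2L))
    stop_fib("need at least 2 samples in each fibrosis category")
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop_fib("all-zero gene(s) present (e.g. ", rownames(counts)[zero][1],
             "); run filter_low_counts() first")

  miss <- setdiff(covariates, names(meta))
  if (length(miss)) stop_fib("covariate(s) not in metadata: ",
                             paste(miss, collapse = ", "))
  fml <- stats::reformulate(c(covariates, "fibrosis_category"))
  X <- model.matrix(fml, data = meta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_fib("design matrix is rank deficient; collinear column(s): ",
             paste(dropped, collapse = ", "))
  }
  coef_name <- "fibrosis_categoryadvanced"

  sf <- size_factors %||% size_factors(counts)
  off <- log(sf)
  ng <- nrow(counts)
  m <- ncol(counts)
  p <- ncol(X)
  norm <- sweep(counts, 2L, sf, `/`)
  base_mean <- rowMeans(norm)

  # moment starting values for the dispersion
  v <- apply(norm, 1L, var)
  alpha0 <- pmin(pmax((v - base_mean) / base_mean^2, 1e-8), 10)

  fixed_alpha <- NULL
  if (!is.null(dispersion)) {
    fixed_alpha <- rep_len(dispersion, ng)
    if (any(fixed_alpha <= 0)) stop_fib("dispersion must be > 0")
  }

  la_lo <- log(1e-8); la_hi <- log(10)
  alpha_gw <- numeric(ng)
  mu_list <- vector("list", ng)
  ys <- lapply(seq_len(ng), function(i) counts[i, ])
  for (i in seq_len(ng)) {
    a_start <- if (is.null(fixed_alpha)) alpha0[i] else fixed_alpha[i]
    fit0 <- nb_irls(ys[[i]], X, off, a_start, ridge)
    mu_list[[i]] <- fit0$mu
    if (is.null(fixed_alpha)) {
      opt <- optimize(function(la) cr_loglik(exp(la), ys[[i]], fit0$mu, X),
                      c(la_lo, la_hi), maximum = TRUE, tol = 1e-4)
      alpha_gw[i] <- exp(opt$maximum)
    } else {
      alpha_gw[i] <- fixed_alpha[i]
    }
  }

  if (is.null(fixed_alpha)) {
    trend <- fit_dispersion_trend(base_mean, alpha_gw)
    alpha_tr <- trend$fun(base_mean)
    if (shrink_dispersion) {
      lr <- log(alpha_gw) - log(alpha_tr)
      prior_var <- max(mad(lr)^2 - trigamma((m - p) / 2), 0.25)
      prior_sd <- sqrt(prior_var)
      alpha_map <- vapply(seq_len(ng), function(i) {
        opt <- optimize(function(la)
          cr_loglik(exp(la), ys[[i]], mu_list[[i]], X) +
            dnorm(la, log(alpha_tr[i]), prior_sd, log = TRUE),
          c(la_lo, la_hi), maximum = TRUE, tol = 1e-4)
        exp(opt$maximum)
      }, numeric(1))
    } else {
      alpha_map <- alpha_gw
      prior_sd <- NA_real_
    }
  } else {
    trend <- NULL
    alpha_tr <- fixed_alpha
    alpha_map <- fixed_alpha
    prior_sd <- NA_real_
  }

  beta <- matrix(NA_real_, ng, p, dimnames = list(rownames(counts), colnames(X)))
  se <- beta
  for (i in seq_len(ng)) {
    fit <- nb_irls(ys[[i]], X, off, alpha_map[i], ridge)
    beta[i, ] <- fit$beta
    se[i, ] <- sqrt(diag(tryCatch(solve(fit$XtWX),
                                  error = function(e) matrix(NA_real_, p, p))))
  }
  l2 <- 1 / log(2)                     # natural-log coefficients -> log2

  structure(list(
    coefficients = beta * l2, se = se * l2, coef_name = coef_name,
    base_mean = base_mean,
    dispersion = data.frame(gene = rownames(counts), gene_wise = alpha_gw,
                            trend = alpha_tr, final = alpha_map),
    dispersion_prior_sd = prior_sd, trend_coef = trend$coef %||% NULL,
    design = X, formula = fml, size_factors = sf, meta = meta,
    n_samples = m, call = match.call()),
    class = "nb_fit")
}

#' Wald test on the fibrosis-category coefficient
#'
#' \eqn{z = \log_2FC / se}, two-sided p from the standard normal. Genes with
#' an undefined standard error get \code{NA} and are excluded from the
#' multiple-testing denominator downstream.
#'
#' @param fit an \code{\link{nb_fit}} object.
#' @return data frame: gene, log2FC, se, stat, p.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "nb_fit"))
  lfc <- fit$coefficients[, fit$coef_name]
  s <- fit$se[, fit$coef_name]
  stat <- ifelse(is.na(s) | s == 0, NA_real_, lfc / s)
  p <- 2 * pnorm(-abs(stat))
  data.frame(gene = rownames(fit$coefficients), log2FC = lfc, se = s,
             stat = stat, p = p, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment; \code{NA} entries are tolerated and excluded from
#' the number of tests.
#'
#' @param p numeric vector of p values in [0,1] (NA allowed).
#' @return adjusted p values, same length and order, NA preserved.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_fib("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Differential expression results table
#'
#' Assembles the per-gene Wald results with BH-adjusted p values and the DEG
#' flag \code{padj <= alpha & |log2FC| >= lfc_min} (both thresholds inclusive,
#' matching the conventional "p-adj <= 0.05, |log2FC| >= 1" rule).
#'
#' @param object an \code{\link{nb_fit}}.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_min absolute log2FC threshold (default 1).
#' @param ... unused.
#' @return data frame: gene, base_mean, log2FC, se, stat, p, padj, is_deg.
#' @export
results.nb_fit <- function(object, alpha = 0.05, lfc_min = 1, ...) {
  w <- wald_test(object)
  w$base_mean <- object$base_mean
  w$padj <- bh_adjust(w$p)
  w$is_deg <- !is.na(w$padj) & w$padj <= alpha & abs(w$log2FC) >= lfc_min
  w[, c("gene", "base_mean", "log2FC", "se", "stat", "p", "padj", "is_deg")]
}

#' @export
results <- function(object, ...) UseMethod("results")

#' Call differentially expressed genes
#'
#' @param res a results data frame (from \code{\link{results.nb_fit}}) or an
#'   \code{\link{nb_fit}} object.
#' @param alpha,lfc_min thresholds (inclusive).
#' @return data frame of DEGs: gene, log2FC, direction ("up"/"down").
#' @export
call_degs <- function(res, alpha = 0.05, lfc_min = 1) {
  if (inherits(res, "nb_fit")) res <- results(res, alpha, lfc_min)
  keep <- !is.na(res$padj) & res$padj <= alpha & abs(res$log2FC) >= lfc_min
  out <- res[keep, c("gene", "log2FC")]
  out$direction <- ifelse(out$log2FC >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' @export
coef.nb_fit <- function(object, ...) object$coefficients

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial Wald fit:", nrow(x$coefficients), "genes,",
      x$n_samples, "samples\n")
  cat("  design:", deparse(x$formula), "\n")
  cat("  contrast:", x$coef_name, "(early = reference)\n")
  cat("  dispersion: median gene-wise ",
      signif(median(x$dispersion$gene_wise), 3), ", median final ",
      signif(median(x$dispersion$final), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.nb_fit <- function(object, alpha = 0.05, lfc_min = 1, ...) {
  res <- results(object, alpha, lfc_min)
  n_up <- sum(res$is_deg & res$log2FC > 0)
  n_dn <- sum(res$is_deg & res$log2FC < 0)
  cat("out of", nrow(res), "genes:\n")
  cat("  DEGs (padj <=", alpha, ", |log2FC| >=", lfc_min, "):",
      n_up + n_dn, "(", n_up, "up,", n_dn, "down )\n")
  cat("  NA p values:", sum(is.na(res$p)), "\n")
  invisible(res)
}

#' Dispersion-estimate diagnostic plot
#'
#' Gene-wise, trend and final (shrunk) dispersion estimates against the mean
#' of normalized counts, on log-log axes.
#'
#' @param x an \code{\link{nb_fit}}.
#' @param ... forwarded to \code{plot}.
#' @export
plot.nb_fit <- function(x, ...) {
  d <- x$dispersion
  ord <- order(x$base_mean)
  graphics::plot(x$base_mean, d$gene_wise, log = "xy", pch = 16, cex = 0.4,
                 col = "grey50", xlab = "mean of normalized counts",
                 ylab = "dispersion", ...)
  graphics::points(x$base_mean, d$final, pch = 16, cex = 0.4, col = "dodgerblue")
  graphics::lines(x$base_mean[ord], d$trend[ord], col = "red", lwd = 2)
  graphics::legend("topright", legend = c("gene-wise", "final", "trend"),
                   col = c("grey50", "dodgerblue", "red"), pch = c(16, 16, NA),
                   lty = c(NA, NA, 1), bty = "n")
  invisible(x)
}
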