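#' Simulate a qPCR plate with known fold changes
#'
#' Generates a long-format Ct table (case and control samples, target genes
#' plus one housekeeping gene) such that the expected recovered
#' \eqn{2^{-\Delta\Delta Ct}} fold change equals \code{true_fold_changes}.
#' Housekeeping Ct values sit around \code{hk_ct}; each target gene has a
#' random baseline \eqn{\Delta Ct} in \code{dct_range}; cases are shifted by
#' \eqn{-\log_2(\mathrm{FC})}; Gaussian noise of sd \code{ct_noise_sd} is
#' added on the Ct scale.
#'
#' @param n_case,n_control group sizes (>= 1).
#' @param true_fold_changes named positive numeric vector, one per target gene.
#' @param ct_noise_sd Ct noise standard deviation (cycles).
#' @param housekeeping housekeeping gene name.
#' @param hk_ct mean housekeeping Ct (cycles).
#' @param dct_range interval for per-gene baseline delta-Ct.
#' @param seed integer seed.
#' @return data frame with columns sample, group, gene, ct, is_housekeeping.
#' @export
simulate_qpcr_plate <- function(n_case, n_control, true_fold_changes,
                                ct_noise_sd = 0.3, housekeeping = "HPRT",
                                hk_ct = 20, dct_range = c(2, 8), seed = 1L) {
  if (n_case < 1L || n_control < 1L)
    stop_fib("need at least one case and one control sample")
  if (is.null(names(true_fold_changes)) || any(true_fold_changes <= 0))
    stop_fib("true_fold_changes must be a named vector of positive fold changes")
  if (housekeeping %in% names(true_fold_changes))
    stop_fib("the housekeeping gene cannot also be a target")
  with_seed(seed, {
    samples <- c(sprintf("case_%02d", seq_len(n_case)),
                 sprintf("ctrl_%02d", seq_len(n_control)))
    group <- rep(c("case", "control"), c(n_case, n_control))
    genes <- names(true_fold_changes)
    base_dct <- runif(length(genes), dct_range[1], dct_range[2])
    names(base_dct) <- genes

    hk <- hk_ct + rnorm(length(samples), 0, ct_noise_sd)
    rows <- data.frame(sample = samples, group = group, gene = housekeeping,
                       ct = hk, is_housekeeping = TRUE,
                       stringsAsFactors = FALSE)
    for (g in genes) {
      shift <- ifelse(group == "case", -log2(true_fold_changes[[g]]), 0)
      ct <- hk + base_dct[[g]] + shift + rnorm(length(samples), 0, ct_noise_sd)
      rows <- rbind(rows, data.frame(sample = samples, group = group, gene = g,
                                     ct = ct, is_housekeeping = FALSE,
                                     stringsAsFactors = FALSE))
    }
    rownames(rows) <- NULL
    rows
  })
}
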