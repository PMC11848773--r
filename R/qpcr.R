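# Delta-delta-Ct relative quantification against a housekeeping gene and
# nonparametric case/control comparison.

check_ct_table <- function(ct_table) {
  req <- c("sample", "group", "gene", "ct", "is_housekeeping")
  miss <- setdiff(req, names(ct_table))
  if (length(miss)) stop_fib("Ct table lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (any(!is.finite(ct_table$ct))) stop_fib("Ct values must be finite")
  if (!all(ct_table$group %in% c("case", "control")))
    stop_fib("group must be 'case' or 'control'")
  ct_table
}

#' Housekeeping-normalized delta Ct
#'
#' Technical replicates are averaged on the Ct scale per sample and gene;
#' then \eqn{\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{housekeeping}} per
#' sample.
#'
#' @param ct_table data frame: sample, group, gene, ct, is_housekeeping (one
#'   housekeeping gene per sample required).
#' @return data frame: sample, group, gene, delta_ct.
#' @export
delta_ct <- function(ct_table) {
  ct_table <- check_ct_table(ct_table)
  avg <- aggregate(ct ~ sample + group + gene + is_housekeeping,
                   data = ct_table, FUN = mean)
  hk <- avg[avg$is_housekeeping, ]
  no_hk <- setdiff(unique(avg$sample), hk$sample)
  if (length(no_hk))
    stop_fib("sample(s) missing a housekeeping Ct: ",
             paste(head(no_hk, 3), collapse = ", "))
  if (anyDuplicated(hk$sample))
    stop_fib("more than one housekeeping gene per sample is not supported")
  tg <- avg[!avg$is_housekeeping, ]
  tg$delta_ct <- tg$ct - hk$ct[match(tg$sample, hk$sample)]
  out <- tg[order(tg$gene, tg$group, tg$sample),
            c("sample", "group", "gene", "delta_ct")]
  rownames(out) <- NULL
  out
}

#' Fold change from delta-delta-Ct
#'
#' \eqn{FC = 2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = \Delta Ct - \mathrm{ref}(\Delta Ct_\mathrm{control})}.
#'
#' @param dct_case numeric vector of sample delta-Ct values.
#' @param dct_control_ref scalar reference (mean of control delta Ct).
#' @return positive fold changes, same length as \code{dct_case}.
#' @export
fold_change <- function(dct_case, dct_control_ref) {
  2^(-(dct_case - dct_control_ref))
}

#' Per-sample fold changes for every gene of a Ct table
#'
#' Computes \eqn{\Delta Ct}, then per gene the control reference (arithmetic
#' mean of control \eqn{\Delta Ct} by default, median optionally) and
#' \eqn{2^{-\Delta\Delta Ct}} for every sample, case and control alike.
#'
#' @param ct_table see \code{\link{delta_ct}}.
#' @param reference \code{"mean"} (default) or \code{"median"} of control
#'   delta Ct.
#' @return data frame: sample, group, gene, delta_ct, delta_delta_ct,
#'   fold_change.
#' @export
qpcr_fold_changes <- function(ct_table, reference = c("mean", "median")) {
  reference <- match.arg(reference)
  d <- delta_ct(ct_table)
  reffun <- if (reference == "mean") mean else median
  out <- do.call(rbind, lapply(split(d, d$gene), function(g) {
    ctrl <- g$delta_ct[g$group == "control"]
    if (!length(ctrl)) stop_fib("gene ", g$gene[1], " has no control samples")
    g$delta_delta_ct <- g$delta_ct - reffun(ctrl)
    g$fold_change <- 2^(-g$delta_delta_ct)
    g
  }))
  rownames(out) <- NULL
  out
}

#' Unpaired two-sided rank-sum comparison
#'
#' Wilcoxon rank-sum (Mann-Whitney) test: exact p for small samples
#' (both groups <= 12, no ties), normal approximation with tie correction
#' otherwise.
#'
#' @param values_case,values_control numeric vectors (>= 1 value each).
#' @return list: \code{statistic} (rank-sum W), \code{p} (two-sided),
#'   \code{exact} (logical).
#' @export
compare_groups <- function(values_case, values_control) {
  if (!length(values_case) || !length(values_control))
    stop_fib("both groups need at least one value")
  if (length(unique(c(values_case, values_control))) == 1L)
    return(list(statistic = length(values_case) * length(values_control) / 2,
                p = 1, exact = FALSE))
  ties <- anyDuplicated(c(values_case, values_control)) > 0
  use_exact <- !ties && length(values_case) <= 12 && length(values_control) <= 12
  wt <- suppressWarnings(
    wilcox.test(values_case, values_control, exact = use_exact,
                correct = !use_exact, alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1     # degenerate tie structure
  list(statistic = unname(wt$statistic), p = min(p, 1), exact = use_exact)
}

#' qPCR validation report
#'
#' Per gene: per-sample fold changes plus the case-vs-control rank-sum test on
#' the delta-Ct values (equivalent, up to sign, to testing the fold changes).
#'
#' @param ct_table see \code{\link{delta_ct}}.
#' @param reference control reference for the delta-delta-Ct, see
#'   \code{\link{qpcr_fold_changes}}.
#' @return list: \code{fold_changes} (per-sample table), \code{tests} (per
#'   gene: median fold change of cases, W statistic, p).
#' @export
qpcr_report <- function(ct_table, reference = "mean") {
  fc <- qpcr_fold_changes(ct_table, reference)
  tests <- do.call(rbind, lapply(split(fc, fc$gene), function(g) {
    cmp <- compare_groups(g$delta_ct[g$group == "case"],
                          g$delta_ct[g$group == "control"])
    data.frame(gene = g$gene[1],
               median_fc_case = median(g$fold_change[g$group == "case"]),
               statistic = cmp$statistic, p = cmp$p, exact = cmp$exact,
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(fold_changes = fc, tests = tests)
}
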