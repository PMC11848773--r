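# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up: padj_i = min over {j : p_j >= p_i}
# of m * p_j / rank_j, capped at 1. O(m^2), independent of p.adjust.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided rank-sum p by full enumeration of group assignments
# (no ties assumed). Two-sided p = 2 * min(tail probs), capped at 1.
wilcox_brute_force <- function(x, y) {
  v <- c(x, y)
  stopifnot(!anyDuplicated(v))
  n1 <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  combos <- utils::combn(length(v), n1)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force Venn region decomposition by direct membership testing.
venn_brute_force <- function(sets) {
  labels <- names(sets)
  universe <- unique(unlist(sets))
  combos <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (cb in combos) {
    members <- Filter(function(g) {
      ins <- vapply(labels, function(l) g %in% sets[[l]], logical(1))
      setequal(labels[ins], cb)
    }, universe)
    out[[paste(cb, collapse = "&")]] <- as.character(members)
  }
  out
}

# A tiny deterministic labeled reference built by hand: genes x cells dense
# counts with explicit per-type structure (for boundary-case tests).
tiny_ref <- function(counts, types) {
  fibrosig::sc_reference(Matrix::Matrix(counts, sparse = TRUE), types)
}

# Small bulk cohort for fast unit tests.
small_bulk <- function(seed = 1, n_genes = 300, ...) {
  cfg <- fibrosig::bulk_sim_config(
    n_genes = n_genes,
    diseases = list(PSC = c(1, 4, 3, 2, 2)),
    program_sizes = c(PSC = 30),
    shared_program_sizes = c(pairwise = 0, triple = 0),
    n_sex_genes = 10, seed = seed, ...)
  fibrosig::simulate_bulk_cohort(cfg)
}
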