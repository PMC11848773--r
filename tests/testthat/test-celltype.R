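test_that("detection fractions implement the 0.5% eligibility boundary", {
  # 1000 cells of type A: 5/1000 = 0.005 is eligible, 4/1000 is not
  counts <- matrix(0, nrow = 3, ncol = 1100,
                   dimnames = list(c("all", "five", "four"), NULL))
  counts["all", ] <- 1
  counts["five", 1:5] <- 1
  counts["four", 1:4] <- 1
  ref <- tiny_ref(counts, rep(c("A", "B"), c(1000, 100)))
  f <- detection_fractions(ref)
  expect_equal(f["all", "A"], 1)
  expect_equal(f["five", "A"], 0.005)
  expect_equal(f["four", "A"], 0.004)
  calls <- assign_specificity(ref, c("five", "four"))
  expect_identical(calls$n_eligible[calls$gene == "five"] >= 1, TRUE)
})

test_that("enrichment logFC has the expected sign structure", {
  counts <- matrix(2, nrow = 2, ncol = 40,
                   dimnames = list(c("flat", "aonly"), NULL))
  counts["aonly", ] <- c(rep(6, 20), rep(0, 20))
  ref <- tiny_ref(counts, rep(c("A", "B"), each = 20))
  lfc <- enrichment_logfc(ref)
  expect_equal(unname(lfc["flat", ]), c(0, 0), tolerance = 1e-6)
  expect_gt(lfc["aonly", "A"], 1)
  expect_lt(lfc["aonly", "B"], -1)
})

test_that("planted 10x markers show the planted enrichment", {
  sim <- simulate_sc_reference(sc_sim_config(
    cell_types = c(A = 300, B = 300, C = 300), n_genes = 300,
    markers_per_type = 8, marker_enrichment_fold = 10, seed = 19))
  lfc <- enrichment_logfc(sim$ref)
  mk <- sim$truth$gene[sim$truth$cell_type == "A"]
  # marker in A vs others: mean ratio 10x baseline vs baseline => log(10)
  obs <- lfc[mk, "A"]
  expect_true(all(abs(obs - log(10)) < 0.5))
})

test_that("the 1.5x specificity rule resolves boundaries inclusively", {
  mk <- function(mA, mB) {
    counts <- matrix(0, nrow = 1, ncol = 20, dimnames = list("g", NULL))
    counts[1, ] <- c(rep(mA, 10), rep(mB, 10))
    tiny_ref(counts, rep(c("A", "B"), each = 10))
  }
  expect_identical(assign_specificity(mk(3, 2))$label, "A")     # 3 = 1.5 x 2
  expect_identical(assign_specificity(mk(2.9, 2))$label, "unspecific")
  # single eligible type counts as specific
  expect_identical(assign_specificity(mk(1, 0))$label, "A")
  # nothing detected anywhere
  counts <- matrix(0, 1, 20, dimnames = list("g", NULL))
  ref0 <- tiny_ref(counts, rep(c("A", "B"), each = 10))
  expect_identical(assign_specificity(ref0)$label, "undetected")
})

test_that("specificity recovers planted markers and is invariant", {
  sim <- simulate_sc_reference(sc_sim_config(
    cell_types = c(A = 200, B = 200, C = 200, D = 200, E = 200),
    n_genes = 400, markers_per_type = 10, seed = 33))
  calls <- assign_specificity(sim$ref)
  tab <- merge(calls, sim$truth, by = "gene")
  planted <- tab$cell_type != "unspecific"
  called <- !tab$label %in% c("unspecific", "undetected")
  recall <- mean(tab$label[planted] == tab$cell_type[planted])
  precision <- mean(tab$cell_type[called] == tab$label[called])
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # permutation invariance over cells
  set.seed(1)
  perm <- sample(ncol(sim$ref$counts))
  ref_p <- sc_reference(sim$ref$counts[, perm], sim$ref$cell_type[perm])
  calls_p <- assign_specificity(ref_p)
  expect_identical(calls$label[order(calls$gene)],
                   calls_p$label[order(calls_p$gene)])
  # scale invariance: multiplying all cells by a constant changes nothing
  # (a power of two keeps floating-point boundary comparisons exact)
  ref_s <- sc_reference(sim$ref$counts * 8, sim$ref$cell_type)
  expect_identical(assign_specificity(ref_s)$label, calls$label)
})

test_that("projection normalization standardizes genes and flags constants", {
  sim <- simulate_sc_reference(sc_sim_config(
    cell_types = c(A = 60, B = 60), n_genes = 100, markers_per_type = 5,
    seed = 13))
  z <- normalize_sc_for_projection(sim$ref)
  mu <- colMeans(z); sdv <- apply(z, 2, sd)
  const <- attr(z, "constant_genes")
  live <- setdiff(colnames(z), const)
  expect_true(all(abs(mu[live]) < 1e-10))
  expect_true(all(abs(sdv[live] - 1) < 1e-10))
  expect_true(all(z[, const] == 0))
  # standardization alone is idempotent
  z2 <- z
  ref2 <- sc_reference(t(z2 - min(z2)), sim$ref$cell_type)  # shift >= 0
  zz <- normalize_sc_for_projection(ref2, library_size = FALSE,
                                    log_transform = FALSE)
  mu2 <- colMeans(zz); sd2 <- apply(zz, 2, sd)
  live2 <- setdiff(colnames(zz), attr(zz, "constant_genes"))
  expect_true(all(abs(mu2[live2]) < 1e-8))
  expect_true(all(abs(sd2[live2] - 1) < 1e-8))
})

fake_pca <- function(w, sign = 1) {
  structure(list(scores = NULL,
                 loadings = matrix(w, ncol = 1,
                                   dimnames = list(names(w), "PC1")),
                 explained_variance = 1, orientation_sign = sign),
            class = "fib_pca")
}

test_that("trajectory projection is linear and sign-coherent", {
  sim <- simulate_sc_reference(sc_sim_config(
    cell_types = c(A = 80, B = 80), n_genes = 120, markers_per_type = 6,
    seed = 3))
  genes <- rownames(sim$ref$counts)
  set.seed(5)
  w1 <- setNames(rnorm(length(genes)), genes)
  w2 <- setNames(rnorm(length(genes)), genes)
  nz <- normalize_sc_for_projection(sim$ref)
  s1 <- trajectory_scores(sim$ref, fake_pca(w1), normalized = nz)
  s2 <- trajectory_scores(sim$ref, fake_pca(w2), normalized = nz)
  s12 <- trajectory_scores(sim$ref, fake_pca(w1 + w2), normalized = nz)
  expect_equal(s12$cell_scores$score, s1$cell_scores$score + s2$cell_scores$score,
               tolerance = 1e-10)
  # flipping the component sign flips scores and mirrors the densities
  sf <- trajectory_scores(sim$ref, fake_pca(-w1, sign = -1), normalized = nz)
  expect_equal(sf$cell_scores$score, -s1$cell_scores$score, tolerance = 1e-10)
  expect_equal(sf$type_summary$median_cell_score,
               -s1$type_summary$median_cell_score, tolerance = 1e-10)
  # all-zero weights: all scores zero, flat ranking
  s0 <- trajectory_scores(sim$ref, fake_pca(0 * w1), normalized = nz)
  expect_true(all(s0$cell_scores$score == 0))
  expect_true(all(s0$ranking$weight == 0))
  # per-type densities integrate to 1
  for (t in unique(s1$densities$cell_type)) {
    d <- s1$densities[s1$densities$cell_type == t, ]
    expect_equal(sum(d$density) * diff(d$x[1:2]), 1, tolerance = 0.02)
  }
})

test_that("dot-plot table is complete, consistent and round-trips", {
  sim <- simulate_sc_reference(sc_sim_config(
    cell_types = c(A = 50, B = 50, C = 50, D = 50, E = 50),
    n_genes = 60, markers_per_type = 2, seed = 8))
  g <- rownames(sim$ref$counts)[1]
  tab <- dotplot_table(sim$ref, g)
  expect_identical(nrow(tab), 5L)
  expect_lte(sum(tab$assigned), 1L)
  expect_true(all(tab$fraction[tab$eligible] >= 0.005))
  tf <- tempfile(fileext = ".csv")
  write.csv(tab, tf, row.names = FALSE)
  rt <- read.csv(tf, stringsAsFactors = FALSE)
  expect_equal(rt$fraction, tab$fraction)
  expect_identical(rt$label, tab$label)
})
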