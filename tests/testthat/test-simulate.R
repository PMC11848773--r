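test_that("bulk cohort dimensions and metadata follow the configuration", {
  cfg <- bulk_sim_config(n_genes = 2000,
                         diseases = list(PSC = c(4, 4, 4, 2, 2)),
                         program_sizes = c(PSC = 50),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         seed = 5)
  sim <- simulate_bulk_cohort(cfg)
  expect_identical(dim(sim$counts), c(2000L, 16L))
  expect_identical(nrow(sim$meta), 16L)
  expect_identical(as.integer(table(sim$meta$fibrosis_category)),
                   c(12L, 4L))
  expect_true(all(sim$counts >= 0))
})

test_that("null effect size yields an empty planted DEG set", {
  cfg <- bulk_sim_config(n_genes = 200,
                         diseases = list(PSC = c(2, 2, 2, 1, 1)),
                         program_sizes = c(PSC = 20),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         effect_log2fc = 0, seed = 2)
  sim <- simulate_bulk_cohort(cfg)
  expect_identical(sum(sim$truth$planted_deg), 0L)
  expect_true(all(sim$truth$true_log2fc == 0))
})

test_that("planted fold change is recovered in sample means (NB mean oracle)", {
  # analytic NB mean: advanced/early ratio = 2^2 = 4 for planted genes
  cfg <- bulk_sim_config(n_genes = 500,
                         diseases = list(PSC = c(50, 0, 0, 0, 50)),
                         program_sizes = c(PSC = 60),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         effect_log2fc = 2, n_sex_genes = 0,
                         size_factor_range = c(1, 1), seed = 3)
  sim <- simulate_bulk_cohort(cfg)
  up <- sim$truth$planted_deg & sim$truth$direction == 1
  adv <- sim$meta$fibrosis_category == "advanced"
  ratio <- rowMeans(sim$counts[up, adv]) / rowMeans(sim$counts[up, !adv])
  expect_gt(median(ratio), 3.5)
  expect_lt(median(ratio), 4.5)
})

test_that("generation is bit-reproducible per seed and validates sizes", {
  cfg <- bulk_sim_config(n_genes = 100, diseases = list(PSC = c(1, 1, 1, 1, 1)),
                         program_sizes = c(PSC = 10),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         seed = 7)
  expect_identical(simulate_bulk_cohort(cfg), simulate_bulk_cohort(cfg))
  expect_error(bulk_sim_config(n_genes = 20,
                               diseases = list(PSC = c(1, 1, 1, 1, 1)),
                               program_sizes = c(PSC = 50),
                               shared_program_sizes = c(pairwise = 0, triple = 0)),
               "exceed")
})

test_that("counts follow the NB mean-variance relation", {
  cfg <- bulk_sim_config(n_genes = 300,
                         diseases = list(PSC = c(200, 0, 0, 0, 0)),
                         program_sizes = c(PSC = 0),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         n_sex_genes = 0, nb_dispersion = 0.1,
                         size_factor_range = c(1, 1), seed = 11)
  sim <- simulate_bulk_cohort(cfg)
  mu <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  ratio <- v / (mu + 0.1 * mu^2)
  expect_gt(median(ratio), 0.85)
  expect_lt(median(ratio), 1.15)
})

test_that("global depth scaling leaves truth and relative factors unchanged", {
  cfg <- bulk_sim_config(n_genes = 800, diseases = list(PSC = c(2, 2, 2, 1, 1)),
                         program_sizes = c(PSC = 15),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         size_factor_range = c(0.5, 2), seed = 13)
  cfg2 <- cfg; cfg2$size_factor_range <- c(1, 4)   # same factors, doubled
  a <- simulate_bulk_cohort(cfg)
  b <- simulate_bulk_cohort(cfg2)
  expect_identical(a$truth$true_log2fc, b$truth$true_log2fc)
  expect_equal(b$meta$true_size_factor, 2 * a$meta$true_size_factor)
  # median-of-ratios identifies factors up to a constant: the doubled cohort
  # yields the same relative estimates, matching the planted relative truth
  fa <- filter_low_counts(a$counts); fb <- filter_low_counts(b$counts)
  common <- intersect(rownames(fa), rownames(fb))
  sa <- size_factors(fa[common, ]); sb <- size_factors(fb[common, ])
  expect_gt(cor(sa, sb), 0.999)
  expect_gt(cor(sa, a$meta$true_size_factor), 0.99)
})

test_that("sc reference plants the configured marker structure", {
  sim <- simulate_sc_reference(sc_sim_config(
    cell_types = c(A = 200, B = 200, C = 200, D = 200, E = 200),
    n_genes = 600, markers_per_type = 10, seed = 4))
  expect_identical(sum(sim$truth$cell_type != "unspecific"), 50L)
  expect_identical(dim(sim$ref$counts), c(600L, 1000L))

  # zero baseline, markers only in A: all non-A detection fractions are 0
  sim0 <- simulate_sc_reference(sc_sim_config(
    cell_types = c(A = 50, B = 50), n_genes = 40, markers_per_type = 0,
    marker_genes = list(A = sprintf("g%05d", 1:5)),
    detection_baseline = 0, seed = 9))
  f <- detection_fractions(sim0$ref)
  expect_true(all(f[, "B"] == 0))
  expect_true(all(f[sprintf("g%05d", 1:5), "A"] > 0))
  expect_error(sc_sim_config(cell_types = c(A = 10, B = 10),
                             marker_genes = list(A = "g1", B = "g1")),
               "disjoint")
})

test_that("qPCR plate embeds the requested fold changes", {
  # noise-free: recovered fold change is exact
  plate <- simulate_qpcr_plate(4, 4, c(G1 = 4, G2 = 1), ct_noise_sd = 0,
                               seed = 2)
  fc <- qpcr_fold_changes(plate)
  expect_equal(unique(fc$fold_change[fc$gene == "G1" & fc$group == "case"]), 4)
  dct <- delta_ct(plate)
  g2 <- dct[dct$gene == "G2", ]
  expect_equal(g2$delta_ct[g2$group == "case"],
               rep(mean(g2$delta_ct[g2$group == "control"]), 4))

  # noisy recovery: median recovered fold within Monte-Carlo bounds
  med <- vapply(1:100, function(s) {
    p <- simulate_qpcr_plate(6, 6, c(G = 4), ct_noise_sd = 0.3, seed = s)
    f <- qpcr_fold_changes(p)
    median(f$fold_change[f$group == "case"])
  }, numeric(1))
  expect_true(all(med > 2.5 & med < 6.5))
  expect_error(simulate_qpcr_plate(3, 3, c(G = -1)), "positive")
})
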