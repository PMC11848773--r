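test_that("BH adjustment matches closed forms and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.5)), c(0.015, 0.06, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
  }
  # NA values excluded from the denominator
  p <- c(0.01, NA, 0.02, 0.03)
  expect_equal(bh_adjust(p), c(0.03, NA, 0.03, 0.03))
})

test_that("Wald statistics follow the normal closed forms", {
  fit <- structure(list(
    coefficients = matrix(c(0, 0, 0, 0, 1.959964, 5),
                          nrow = 3,
                          dimnames = list(paste0("g", 1:3),
                                          c("(Intercept)", "fibrosis_categoryadvanced"))),
    se = matrix(c(1, 1, 1, 1, 1, 0), nrow = 3,
                dimnames = list(paste0("g", 1:3),
                                c("(Intercept)", "fibrosis_categoryadvanced"))),
    coef_name = "fibrosis_categoryadvanced"), class = "nb_fit")
  w <- wald_test(fit)
  expect_equal(w$p[1], 1)
  expect_equal(w$p[2], 0.05, tolerance = 1e-6)
  expect_true(is.na(w$p[3]))             # se = 0 -> NA, excluded from BH m
})

test_that("DEG calling applies inclusive thresholds with directions", {
  res <- data.frame(gene = c("a", "b", "c"),
                    log2FC = c(1.0, 3.0, -1.2),
                    padj = c(0.05, 0.051, 0.01))
  out <- call_degs(res)
  expect_identical(out$gene, c("a", "c"))
  expect_identical(out$direction, c("up", "down"))
})

test_that("NB fit recovers null and planted effects", {
  cfg <- bulk_sim_config(n_genes = 400,
                         diseases = list(PSC = c(25, 0, 0, 0, 25)),
                         program_sizes = c(PSC = 40),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         effect_log2fc = 2, n_sex_genes = 0,
                         nb_dispersion = 0.05, seed = 8)
  sim <- simulate_bulk_cohort(cfg)
  f <- filter_low_counts(sim$counts)
  fit <- nb_fit(f, sim$meta)
  res <- results(fit)
  truth <- sim$truth[match(res$gene, sim$truth$gene), ]
  est_err <- res$log2FC - truth$true_log2fc
  # planted log2FC = +/-2 at n = 25/25: median estimate within 0.2 of truth
  expect_lt(abs(median(est_err[truth$planted_deg])), 0.2)
  # null genes: median |estimate| well under the 0.3 bound
  expect_lt(median(abs(res$log2FC[!truth$planted_deg])), 0.3)
})

test_that("design validation catches degenerate inputs", {
  sim <- small_bulk(seed = 17)
  f <- filter_low_counts(sim$counts)
  meta <- sim$meta
  # sex perfectly confounded with the fibrosis category
  meta$sex <- factor(ifelse(meta$fibrosis_category == "advanced",
                            "male", "female"), levels = c("female", "male"))
  expect_error(nb_fit(f, meta), "rank deficient")
  # all-zero genes must be filtered upstream
  withz <- rbind(f, gzero = 0L)
  expect_error(nb_fit(withz, sim$meta), "all-zero")
  # fewer than 2 samples per category
  sub <- sim$meta$sample[sim$meta$stage <= 3][1:8]
  expect_error(nb_fit(f[, sub], sim$meta[sim$meta$sample %in% sub, ]),
               "at least 2")
})

test_that("log2FC estimates agree with DESeq2 on a shared cohort", {
  cfg <- bulk_sim_config(n_genes = 250,
                         diseases = list(PSC = c(4, 2, 2, 4, 4)),
                         program_sizes = c(PSC = 25),
                         shared_program_sizes = c(pairwise = 0, triple = 0),
                         n_sex_genes = 5, seed = 23)
  sim <- simulate_bulk_cohort(cfg)
  f <- filter_low_counts(sim$counts)
  fit <- nb_fit(f, sim$meta)
  res <- results(fit)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      f, data.frame(sex = sim$meta$sex,
                    condition = sim$meta$fibrosis_category),
      ~ sex + condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds, contrast = c("condition", "advanced", "early"))
  })
  common <- intersect(res$gene, rownames(dres))
  a <- res$log2FC[match(common, res$gene)]
  b <- dres$log2FoldChange[match(common, rownames(dres))]
  expect_gt(cor(a, b), 0.98)
  expect_lt(median(abs(a - b)), 0.1)
  # DEG calls substantially concordant despite dispersion-detail differences
  da <- res$padj <= 0.05 & abs(res$log2FC) >= 1
  db <- !is.na(dres$padj) & dres$padj <= 0.05 & abs(dres$log2FoldChange) >= 1
  expect_gt(mean(da[match(common, res$gene)] ==
                   db[match(common, rownames(dres))]), 0.9)
})

test_that("offset invariance: scaling a sample and its factor is neutral", {
  sim <- small_bulk(seed = 29, n_genes = 150)
  f <- filter_low_counts(sim$counts)
  sf <- size_factors(f)
  fit1 <- nb_fit(f, sim$meta, size_factors = sf, dispersion = 0.05)
  f2 <- f; f2[, 3] <- f2[, 3] * 2L
  sf2 <- sf; sf2[3] <- sf2[3] * 2
  fit2 <- nb_fit(f2, sim$meta, size_factors = sf2, dispersion = 0.05)
  expect_equal(fit1$coefficients[, fit1$coef_name],
               fit2$coefficients[, fit2$coef_name], tolerance = 0.02)
})
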