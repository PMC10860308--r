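test_that("Bartlett statistic matches hand-evaluated cases", {
  # equal variances: statistic exactly 0
  b0 <- bartlett_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(b0$K2, 0, tolerance = 1e-12)
  expect_equal(b0$p, 1)
  expect_identical(b0$df, 1L)

  # variances 5/3 vs 20/3: K2 ~ 1.1476, p ~ 0.2841
  b1 <- bartlett_test(list(c(1, 2, 3, 4), c(2, 4, 6, 8)))
  expect_equal(b1$K2, 1.1475954, tolerance = 1e-3)
  expect_equal(b1$p, 0.2840531, tolerance = 1e-3)

  # zero-variance group: flagged, not thrown
  bz <- bartlett_test(list(c(1, 1, 1), c(1, 2, 3)))
  expect_false(bz$computable)
  expect_true(is.na(bz$p))

  expect_error(bartlett_test(list(1:3)), "2 groups")
  expect_error(bartlett_test(list(1, 1:3)), "2 observations")
})

test_that("Bartlett agrees with the independent oracle on random inputs", {
  set.seed(404)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) {
      rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    })
    mine <- bartlett_test(groups)
    ref <- oracle_bartlett(groups)
    expect_equal(mine$K2, ref$K2, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
    expect_equal(mine$df, ref$df)
  }
})

test_that("p-values fall as the variance ratio grows", {
  base <- scale(rnorm(20, sd = 1))[, 1]
  p <- vapply(c(1, 2, 4, 8), function(s) {
    bartlett_test(list(base, base * s))$p
  }, 0)
  expect_true(all(diff(p) < 0))
})

test_that("the Bonferroni threshold is alpha over the family size", {
  expect_equal(signif(bonferroni_threshold(0.05, 13684), 3), 3.65e-06)
  expect_equal(bonferroni_threshold(0.07, 1), 0.07)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(1.2, 10))
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("per-gene tests are invariant to shuffling eggs within levels", {
  sim <- simulate_clutches(sim_config(n_genes = 150, seed = 31))
  prep <- prepare_expression(sim$counts, sim$meta, 50L)
  vt1 <- per_gene_variance_tests(prep$tpm, prep$meta)
  # permute egg columns within each clutch (hence within each factor cell)
  set.seed(1)
  ord <- unlist(lapply(split(seq_len(nrow(prep$meta)), prep$meta$clutch),
                       sample), use.names = FALSE)
  vt2 <- per_gene_variance_tests(prep$tpm[, ord], prep$meta[ord, ])
  expect_equal(vt1$p_genotype, vt2$p_genotype, tolerance = 1e-12)
  expect_equal(vt1$p_stress, vt2$p_stress, tolerance = 1e-12)
  expect_equal(vt1$p_interaction, vt2$p_interaction, tolerance = 1e-12)
  expect_identical(colnames(vt1),
                   c("gene_id", "p_genotype", "p_interaction", "p_stress",
                     "sig_genotype", "sig_interaction", "sig_stress"))
})

test_that("a stress-driven variance shift is detected, a null is not", {
  # stress multiplies phi x9 for every gene in all genotypes
  sim <- simulate_clutches(sim_config(
    n_genes = 200, seed = 77, mu_log_mean = 5, mu_log_sd = 0.5,
    phi_log_mean = log(0.2), phi_log_sd = 0.3,
    inflation_factor = 9, inflated_fraction = 1,
    inflated_clutches = c("BBH", "ABH", "ABHB")))
  prep <- prepare_expression(sim$counts, sim$meta, 50L)
  vt <- per_gene_variance_tests(prep$tpm, prep$meta)
  # most genes reject the stress-homogeneity null at the Bonferroni bar
  expect_gt(mean(vt$sig_stress), 0.5)

  # constant-variance null: family-wise control leaves ~no flags
  sim0 <- simulate_clutches(sim_config(n_genes = 400, seed = 78,
                                       mu_log_mean = 5, mu_log_sd = 0.5))
  prep0 <- prepare_expression(sim0$counts, sim0$meta, 50L)
  vt0 <- per_gene_variance_tests(prep0$tpm, prep0$meta)
  expect_lte(sum(vt0$sig_stress), 1)
  expect_lte(sum(vt0$sig_genotype), 1)
})

test_that("global homogeneity test responds to a scaled level", {
  set.seed(5)
  em <- matrix(rlnorm(60 * 20, 3, 1), 60, 20,
               dimnames = list(paste0("g", 1:60), paste0("e", 1:20)))
  meta <- make_meta(colnames(em), rep(c("BBC", "BBH"), each = 10))
  # duplicate-group identity: same values in both levels -> K2 = 0
  em_dup <- cbind(em[, 1:10], em[, 1:10])
  colnames(em_dup) <- colnames(em)
  g0 <- global_homogeneity_test(em_dup, meta, "stress")
  expect_equal(g0$K2, 0, tolerance = 1e-10)
  # one level scaled x3 in spread
  em_alt <- em
  gm <- rowMeans(em[, 11:20])
  em_alt[, 11:20] <- gm + 3 * (em[, 11:20] - gm)
  expect_lt(global_homogeneity_test(em_alt, meta, "stress")$p, 0.05)
  expect_error(global_homogeneity_test(em, meta, "genotype"), "2 levels")
})

test_that("gene-by-environment interaction test flags cell-specific variance", {
  set.seed(9)
  G <- 40
  em <- matrix(rlnorm(G * 24, 3, 1), G, 24,
               dimnames = list(paste0("g", 1:G), paste0("e", 1:24)))
  meta <- make_meta(colnames(em), rep(c("BBC", "BBH"), each = 12))
  null_res <- gene_environment_interaction_test(em, meta)
  # interaction: half the genes get 5x the spread only under H
  em_int <- em
  idx <- 1:(G / 2)
  gm <- rowMeans(em[idx, 13:24])
  em_int[idx, 13:24] <- gm + 5 * (em[idx, 13:24] - gm)
  int_res <- gene_environment_interaction_test(em_int, meta)
  expect_lt(int_res$p, 0.001)
  expect_gt(int_res$K2, null_res$K2)
  expect_equal(int_res$df, G)
})
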