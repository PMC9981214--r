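test_that("the packaged syngeneic table matches its published structure", {
  tab <- syngeneic_table1()
  expect_identical(nrow(tab), 19L)
  expect_identical(tab$model_name[1], "Pan02")
  expect_true(all(tab$purity_pct > 0 & tab$purity_pct <= 100))
  # the table agrees with a from-first-principles rank correlation
  res <- purity_mutation_correlation(tab)
  expect_equal(res$rho, brute_spearman(tab$purity_pct, tab$n_somatic),
               tolerance = 1e-10)
})

test_that("purity-mutation correlation handles monotone toy tables", {
  up <- data.frame(purity_pct = 1:5, n_somatic = c(10, 20, 30, 40, 50))
  expect_equal(purity_mutation_correlation(up)$rho, 1, tolerance = 1e-12)
  down <- data.frame(purity_pct = 1:5, n_somatic = c(50, 40, 30, 20, 10))
  expect_equal(purity_mutation_correlation(down)$rho, -1, tolerance = 1e-12)
  expect_error(purity_mutation_correlation(up[1:2, ]))
})

test_that("within-model purity differences are smaller than between-model", {
  cohort <- gen_sample_table(n_models = 40, samples_per_model = 4,
                             between_sd = 0.12, within_sd = 0.05,
                             max_passage = 2, seed = 71)
  res <- within_between_differences(cohort)
  expect_gt(res$median_between, res$median_within)
  expect_lt(res$test$p.value, 0.01)
  # two identical samples: within-difference exactly 0
  two <- data.frame(model_id = "m1", passage = c(1, 1), purity = c(0.8, 0.8))
  expect_error(within_between_differences(two), "between")
  mixed <- rbind(two, data.frame(model_id = "m2", passage = 1, purity = 0.6))
  r2 <- within_between_differences(mixed)
  expect_identical(r2$within, 0)
  expect_equal(sort(r2$between), c(0.2, 0.2), tolerance = 1e-12)
})

test_that("early/late pairing recovers exact shifts and forbids reuse", {
  base <- data.frame(
    model_id = rep(sprintf("m%d", 1:10), each = 2),
    passage = rep(c(0, 5), 10),
    purity = rep(seq(0.5, 0.95, length.out = 10), each = 2)
  )
  base$purity[base$passage == 5] <- base$purity[base$passage == 5] + 0.01
  res <- early_late_pairing(base, seed = 1)
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  expect_equal(res$mean_diff, 0.01, tolerance = 1e-12)
  # a model whose samples share one passage still pairs two distinct samples
  same <- data.frame(model_id = "m1", passage = c(2, 2),
                     purity = c(0.7, 0.9))
  r1 <- early_late_pairing(same, seed = 3)
  expect_identical(sort(c(r1$pairs$early, r1$pairs$late)), c(0.7, 0.9))
  # independent purities: correlation near zero across seeds
  set.seed(72)
  rs <- vapply(1:30, function(s) {
    tab <- data.frame(model_id = rep(sprintf("m%d", 1:30), each = 2),
                      passage = rep(c(0, 5), 30),
                      purity = runif(60))
    early_late_pairing(tab, seed = s)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("balanced subsetting equalises per-cancer strain counts", {
  samples <- gen_sample_table(n_models = 80, samples_per_model = 3, seed = 73)
  bal <- balanced_strain_subset(samples, seed = 1)
  comp <- bal$composition
  for (ca in unique(comp$cancer)) {
    counts <- comp$Freq[comp$cancer == ca]
    expect_identical(counts[1], counts[2])
  }
  # total is twice the sum of per-cancer minima
  minima <- sapply(split(samples, samples$cancer_code), function(g)
    min(table(factor(g$strain, levels = unique(samples$strain)))))
  expect_identical(nrow(bal$subset), as.integer(2 * sum(minima)))
  # an already-balanced input is returned unchanged (modulo order)
  again <- balanced_strain_subset(bal$subset, seed = 9)
  expect_identical(nrow(again$subset), nrow(bal$subset))
  # min rule: 10 vs 4 retains 4 vs 4
  toy <- data.frame(cancer_code = "CR",
                    strain = rep(c("A", "B"), c(10, 4)),
                    purity = runif(14))
  expect_identical(nrow(balanced_strain_subset(toy)$subset), 8L)
})

test_that("strain comparison detects a constructed purity shift", {
  samples <- gen_sample_table(n_models = 200, samples_per_model = 3,
                              strain_shift = 0.07, within_sd = 0.03,
                              between_sd = 0.08, seed = 74)
  bal <- balanced_strain_subset(samples, seed = 2)
  res <- strain_comparison(bal$subset)
  shift <- res$pooled$medians[match("NOD_SCID", res$pooled$strains)] -
    res$pooled$medians[match("BALBC_NUDE", res$pooled$strains)]
  expect_gt(shift, 0.03)
  expect_lt(shift, 0.11)
  expect_lt(res$pooled$test$p.value, 0.01)
  # shared cancer-level means force positive cross-strain correlation
  expect_gt(res$median_correlation, 0)
  # identical distributions: zero median difference
  same <- data.frame(cancer_code = "CR", strain = rep(c("A", "B"), each = 5),
                     purity = rep(c(0.7, 0.75, 0.8, 0.85, 0.9), 2))
  r0 <- strain_comparison(same)
  expect_identical(diff(r0$pooled$medians), 0)
})

test_that("per-cancer summaries respect the minimum sample size", {
  samples <- data.frame(
    cancer_code = rep(c("CR", "GA"), c(19, 20)),
    purity = c(runif(19), rep(0.8, 20))
  )
  res <- cancer_purity_summary(samples, min_n = 20)
  expect_identical(res$table$cancer_code, "GA")
  expect_identical(res$n_excluded, 1L)
  expect_identical(res$table$median, 0.8)
  # mean of medians over two cancers
  two <- data.frame(cancer_code = rep(c("A", "B"), each = 20),
                    purity = rep(c(0.6, 0.9), each = 20))
  expect_identical(cancer_purity_summary(two)$mean_of_medians, 0.75)
})

test_that("statistics are invariant under sample reordering", {
  samples <- gen_sample_table(n_models = 30, samples_per_model = 4,
                              max_passage = 2, seed = 75)
  shuffled <- samples[sample(nrow(samples)), ]
  a <- within_between_differences(samples)
  b <- within_between_differences(shuffled)
  expect_equal(sort(a$within), sort(b$within), tolerance = 1e-12)
  expect_equal(a$test$p.value, b$test$p.value, tolerance = 1e-12)
  s1 <- cancer_purity_summary(samples, min_n = 5)
  s2 <- cancer_purity_summary(shuffled, min_n = 5)
  expect_equal(s1$table, s2$table, tolerance = 1e-12)
})

test_that("rank statistics agree with exact enumeration on small inputs", {
  set.seed(76)
  for (i in 1:20) {
    n1 <- sample(3:4, 1); n2 <- sample(3:4, 1)
    x <- sample(100, n1); y <- sample(100, n2)  # tie-free
    wt <- mann_whitney_oracle_check(x, y)
    expect_equal(wt$statistic, brute_u_stat(x, y), tolerance = 1e-12)
    expect_equal(wt$p_value, brute_u_pvalue(x, y), tolerance = 1e-9)
  }
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- runif(n); y <- runif(n)
    expect_equal(cor(x, y, method = "spearman"), brute_spearman(x, y),
                 tolerance = 1e-10)
    # with ties, average ranks still agree
    xt <- sample(3, n, replace = TRUE); yt <- sample(3, n, replace = TRUE)
    if (stats::sd(xt) > 0 && stats::sd(yt) > 0) {
      expect_equal(cor(xt, yt, method = "spearman"), brute_spearman(xt, yt),
                   tolerance = 1e-10)
    }
  }
})
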