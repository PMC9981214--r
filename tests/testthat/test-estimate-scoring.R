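test_that("hybrid expression adds mouse ortholog expression to human genes", {
  h <- matrix(c(5, 7), 2, 1, dimnames = list(c("hs_G1", "hs_G2"), "s1"))
  m <- matrix(c(3, 4), 2, 1, dimnames = list(c("mm_g1a", "mm_g1b"), "s1"))
  map <- data.frame(human_id = c("hs_G1", "hs_G1"),
                    mouse_id = c("mm_g1a", "mm_g1b"))
  hy <- hybridize_expression(h, m, map)
  expect_identical(hy["hs_G1", "s1"], 12)   # 5 + 3 + 4
  expect_identical(hy["hs_G2", "s1"], 7)    # unmapped: passes through
  # mouse all-zero: hybrid equals the human matrix
  m0 <- m * 0
  expect_identical(hybridize_expression(h, m0, map), h)
  # sample mismatch is an error
  m2 <- m; colnames(m2) <- "other"
  expect_error(hybridize_expression(h, m2, map), "sample")
})

test_that("enrichment score matches the brute-force running-sum oracle", {
  set.seed(61)
  for (i in 1:50) {
    expr <- setNames(runif(10, 0, 100), paste0("g", 1:10))
    gene_set <- sample(names(expr), 3)
    expect_equal(ssgsea_score(expr, gene_set),
                 brute_ssgsea(expr, gene_set),
                 tolerance = 1e-9)
  }
})

test_that("enrichment score is rank based and direction sensitive", {
  set.seed(62)
  expr <- setNames(runif(200, 1, 100), paste0("g", 1:200))
  gene_set <- sample(names(expr), 15)
  # invariant under monotone transforms of expression
  expect_equal(ssgsea_score(expr, gene_set), ssgsea_score(log(expr), gene_set),
               tolerance = 1e-12)
  expect_equal(ssgsea_score(expr, gene_set), ssgsea_score(expr^3, gene_set),
               tolerance = 1e-12)
  # set at the top of the profile scores strictly above set at the bottom
  top <- names(sort(expr, decreasing = TRUE))[1:15]
  bottom <- names(sort(expr))[1:15]
  expect_gt(ssgsea_score(expr, top), ssgsea_score(expr, bottom))
  # degenerate contracts
  expect_error(ssgsea_score(expr, names(expr)), "out-of-set")
  expect_error(ssgsea_score(expr, "absent_gene"), "no gene-set member")
})

test_that("combined score is exactly stromal plus immune", {
  sig <- default_signature(n_stromal = 15, n_immune = 15,
                           n_stromal_unmapped = 2, n_multi = 1)
  cohort <- gen_expression_cohort(sim_config(seed = 63, n_samples = 6,
                                             n_genes = 200), sig)
  for (v in c("human", "mouse", "hybrid")) {
    sc <- estimate_scores(sig, v, human = cohort$human, mouse = cohort$mouse)
    expect_equal(sc$estimate, sc$stromal + sc$immune, tolerance = 1e-12)
    expect_identical(attr(sc, "version"), v)
  }
  expect_error(estimate_scores(sig, "human", mouse = cohort$mouse), "human")
  expect_error(estimate_scores(sig, "mouse", human = cohort$human), "mouse")
})

test_that("hybrid score equals human score when mouse expression is zero", {
  sig <- default_signature(n_stromal = 12, n_immune = 12,
                           n_stromal_unmapped = 0, n_multi = 0)
  cohort <- gen_expression_cohort(sim_config(seed = 64, n_samples = 4,
                                             n_genes = 150), sig)
  mouse0 <- cohort$mouse * 0
  h <- estimate_scores(sig, "human", human = cohort$human)
  hy <- estimate_scores(sig, "hybrid", human = cohort$human, mouse = mouse0)
  expect_equal(hy$estimate, h$estimate, tolerance = 1e-12)
})

test_that("human-version scores floor out on a stroma-free sample", {
  sig <- default_signature(n_stromal = 20, n_immune = 20)
  cohort <- gen_expression_cohort(sim_config(seed = 65, n_samples = 12,
                                             n_genes = 500, noise_sd = 0),
                                  sig, purity = c(rep(1, 6), rep(0.5, 6)),
                                  stroma_split_sd = 0)
  sc <- estimate_scores(sig, "human", human = cohort$human)
  expect_lt(max(sc$estimate[1:6]), min(sc$estimate[7:12]))
})

test_that("loess calibration reproduces a noise-free monotone curve", {
  ref <- gen_score_purity_reference(sim_config(seed = 66, n_samples = 60),
                                    noise_sd = 0)
  curve <- fit_score_purity_curve(ref$pairs)
  pred <- predict(curve, ref$pairs$score)
  expect_lt(max(abs(pred - ref$truth_fun(ref$pairs$score))), 0.02)
  # predicted purity non-increasing in score over a dense grid
  dense <- seq(min(ref$pairs$score), max(ref$pairs$score), length.out = 400)
  expect_true(all(diff(predict(curve, dense)) <= 1e-8))
})

test_that("out-of-range scores use the linear extension and are clamped", {
  # linear reference: the boundary slope is known, so the extension is too
  pairs <- data.frame(score = seq(0, 1000, length.out = 40))
  pairs$purity <- 0.9 - 0.0008 * pairs$score
  curve <- fit_score_purity_curve(pairs)
  expect_equal(predict(curve, -100), 0.98, tolerance = 0.01)
  expect_equal(predict(curve, 1100), 0.02, tolerance = 0.01)
  # far outside, predictions clamp to [0, 1]
  expect_identical(predict(curve, -1e6), 1)
  expect_identical(predict(curve, 1e6), 0)
  # cosine reference: boundary values are already 1 and 0, clamp holds
  ref <- gen_score_purity_reference(sim_config(seed = 67, n_samples = 50),
                                    noise_sd = 0)
  c2 <- fit_score_purity_curve(ref$pairs)
  out <- predict(c2, c(min(ref$pairs$score) - 500, max(ref$pairs$score) + 500))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("calibration is invariant to the order of reference pairs", {
  ref <- gen_score_purity_reference(sim_config(seed = 68, n_samples = 40))
  shuffled <- ref$pairs[sample(nrow(ref$pairs)), ]
  c1 <- fit_score_purity_curve(ref$pairs)
  c2 <- fit_score_purity_curve(shuffled)
  s <- seq(min(ref$pairs$score), max(ref$pairs$score), length.out = 50)
  expect_equal(predict(c1, s), predict(c2, s), tolerance = 1e-10)
})

test_that("calibration rejects degenerate references", {
  few <- data.frame(score = 1:10, purity = runif(10))
  expect_error(fit_score_purity_curve(few), "at least 20")
  flat <- data.frame(score = rep(1, 25), purity = runif(25))
  expect_error(fit_score_purity_curve(flat), "all equal")
})

test_that("score-to-purity tags each version's denominator", {
  ref <- gen_score_purity_reference(sim_config(seed = 69, n_samples = 40))
  curve <- fit_score_purity_curve(ref$pairs)
  for (v in c("human", "mouse", "hybrid")) {
    out <- score_to_purity(curve, c(0, 1000), version = v)
    expect_true(all(out$purity >= 0 & out$purity <= 1))
    expect_match(out$interpretation[1], switch(v,
      human = "human cells", mouse = "mouse cells", hybrid = "all cells"))
  }
  # identical scores give identical purities; ordering reverses the scores
  out <- score_to_purity(curve, c(500, 500, 2000))
  expect_identical(out$purity[1], out$purity[2])
  expect_gte(out$purity[1], out$purity[3])
})
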