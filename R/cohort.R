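#' Packaged syngeneic model summary table
#'
#' Loads the packaged 19-model syngeneic summary (model name, median tumor
#' purity in percent across five tumors harvested at ~500 mm^3, somatic
#' mutation count, cancer type).
#'
#' @return Data frame with columns `model_name`, `purity_pct`, `n_somatic`,
#'   `cancer`.
#' @examples
#' tab <- syngeneic_table1()
#' purity_mutation_correlation(tab)
#' @export
syngeneic_table1 <- function() {
  path <- system.file("extdata", "syngeneic_table1.tsv", package = "xenopurity")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Spearman correlation between purity and somatic mutation count
#'
#' Rank correlation (average-rank tie handling) between tumor purity and
#' the number of somatic mutations across syngeneic models, with a
#' t-approximation p-value. Used to ask whether more immunogenic (highly
#' mutated) models grow purer or less pure tumors.
#'
#' @param table Data frame with `purity_pct` and `n_somatic` columns; at
#'   least 3 rows.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
purity_mutation_correlation <- function(table) {
  stopifnot(nrow(table) >= 3,
            all(c("purity_pct", "n_somatic") %in% names(table)))
  ct <- suppressWarnings(
    cor.test(table$purity_pct, table$n_somatic, method = "spearman",
             exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(table))
}

#' Within-model vs between-model purity differences
#'
#' For all pairs of samples sharing a passage number, computes absolute
#' purity differences separately for pairs from the same model (within) and
#' pairs from different models (between), with medians and a two-sided
#' Mann-Whitney U test of the two difference distributions. A between
#' median well above the within median indicates that purity is an
#' intrinsic, model-specific property rather than passage noise.
#'
#' @param samples Data frame with `model_id`, `passage`, `purity` columns.
#' @return A list with `within`, `between` (numeric difference vectors),
#'   `median_within`, `median_between`, and `test` (the `htest`).
#' @export
within_between_differences <- function(samples) {
  stopifnot(all(c("model_id", "passage", "purity") %in% names(samples)))
  within <- numeric(0)
  between <- numeric(0)
  for (p in unique(samples$passage)) {
    grp <- samples[samples$passage == p, , drop = FALSE]
    n <- nrow(grp)
    if (n < 2) next
    idx <- utils::combn(n, 2)
    d <- abs(grp$purity[idx[1, ]] - grp$purity[idx[2, ]])
    same <- grp$model_id[idx[1, ]] == grp$model_id[idx[2, ]]
    within <- c(within, d[same])
    between <- c(between, d[!same])
  }
  if (length(within) == 0) {
    stop("no within-model identical-passage pairs available")
  }
  if (length(between) == 0) {
    stop("no between-model identical-passage pairs available")
  }
  list(
    within = within,
    between = between,
    median_within = median(within),
    median_between = median(between),
    test = mann_whitney(between, within)
  )
}

# Two-sided Mann-Whitney U; exact when both groups are small and tie-free.
mann_whitney <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20 && !any(duplicated(c(x, y)))
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
}

#' Pair an early and a late passage sample per model
#'
#' For every model with at least two samples, selects one sample at the
#' earliest available passage and one at the latest (seeded random choice
#' among ties; the same sample is never used twice, so models whose samples
#' all share one passage still contribute a within-passage pair), then
#' summarises early-late concordance: Pearson correlation, mean paired
#' difference (late minus early), and a paired t test.
#'
#' @param samples Data frame with `model_id`, `passage`, `purity` columns.
#' @param seed Integer seed for tie-breaking.
#' @return A list with `pairs` (data frame `model_id`, `early`, `late`),
#'   `pearson_r`, `mean_diff`, `sd_diff`, and `test` (paired t test, or
#'   `NULL` when fewer than 2 pairs).
#' @export
early_late_pairing <- function(samples, seed = 1L) {
  stopifnot(all(c("model_id", "passage", "purity") %in% names(samples)))
  set.seed(as.integer(seed))
  models <- split(samples, samples$model_id)
  rows <- lapply(models, function(g) {
    if (nrow(g) < 2) return(NULL)
    early_idx <- sample(rep(which(g$passage == min(g$passage)), 2))[1]
    late_cand <- setdiff(which(g$passage == max(g$passage)), early_idx)
    if (length(late_cand) == 0) late_cand <- setdiff(seq_len(nrow(g)), early_idx)
    late_idx <- sample(rep(late_cand, 2))[1]
    data.frame(model_id = g$model_id[1],
               early = g$purity[early_idx], late = g$purity[late_idx])
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("no model has two or more samples")
  }
  diffs <- pairs$late - pairs$early
  list(
    pairs = pairs,
    pearson_r = if (nrow(pairs) >= 3) cor(pairs$early, pairs$late) else NA_real_,
    mean_diff = mean(diffs),
    sd_diff = stats::sd(diffs),
    test = if (nrow(pairs) >= 2 && stats::sd(diffs) > 0) {
      t.test(pairs$late, pairs$early, paired = TRUE)
    } else NULL
  )
}

#' Balanced per-cancer per-strain subset
#'
#' Builds a strain-comparison set in which every cancer contributes the
#' same number of samples to both host strains, by seeded downsampling
#' (without replacement) of the larger strain to the smaller count within
#' each cancer; cancers present in only one strain are dropped.
#'
#' @param samples Data frame with `cancer_code`, `strain`, and `purity`
#'   columns (plus any others, carried through).
#' @param seed Integer seed for downsampling.
#' @return A list with `subset` (the balanced data frame) and
#'   `composition` (per-cancer per-strain counts).
#' @export
balanced_strain_subset <- function(samples, seed = 1L) {
  stopifnot(all(c("cancer_code", "strain") %in% names(samples)))
  strains <- unique(samples$strain)
  if (length(strains) != 2) stop("exactly two strains required")
  set.seed(as.integer(seed))
  keep <- integer(0)
  for (ca in unique(samples$cancer_code)) {
    i1 <- which(samples$cancer_code == ca & samples$strain == strains[1])
    i2 <- which(samples$cancer_code == ca & samples$strain == strains[2])
    n <- min(length(i1), length(i2))
    if (n == 0) next
    keep <- c(keep,
              if (length(i1) > n) sample(i1, n) else i1,
              if (length(i2) > n) sample(i2, n) else i2)
  }
  if (length(keep) == 0) stop("no cancer present in both strains")
  subset <- samples[sort(keep), , drop = FALSE]
  composition <- as.data.frame(table(cancer = subset$cancer_code,
                                     strain = subset$strain))
  list(subset = subset, composition = composition)
}

#' Compare tumor purity between host strains
#'
#' On a balanced subset, compares purity between the two strains pooled
#' (median per strain, two-sided Mann-Whitney U) and within each cancer,
#' and reports the cross-strain Pearson correlation of per-cancer medians
#' (high correlation means cancer specificity of purity is preserved in
#' both strains).
#'
#' @param subset Balanced sample data frame (`cancer_code`, `strain`,
#'   `purity`), e.g. `balanced_strain_subset(...)$subset`.
#' @return A list with `pooled` (per-strain medians + test), `per_cancer`
#'   (data frame of per-cancer medians and p-values), and
#'   `median_correlation` (Pearson r of per-cancer medians, `NA` with < 3
#'   cancers).
#' @export
strain_comparison <- function(subset) {
  stopifnot(all(c("cancer_code", "strain", "purity") %in% names(subset)))
  strains <- sort(unique(subset$strain))
  if (length(strains) != 2) stop("exactly two strains required")
  x <- subset$purity[subset$strain == strains[1]]
  y <- subset$purity[subset$strain == strains[2]]
  pooled <- list(strains = strains, medians = c(median(x), median(y)),
                 test = mann_whitney(x, y))
  rows <- lapply(sort(unique(subset$cancer_code)), function(ca) {
    cx <- subset$purity[subset$cancer_code == ca & subset$strain == strains[1]]
    cy <- subset$purity[subset$cancer_code == ca & subset$strain == strains[2]]
    data.frame(cancer_code = ca, n = length(cx) + length(cy),
               median_1 = median(cx), median_2 = median(cy),
               p_value = if (length(cx) > 0 && length(cy) > 0)
                 mann_whitney(cx, cy)$p.value else NA_real_)
  })
  per_cancer <- do.call(rbind, rows)
  r <- if (nrow(per_cancer) >= 3) {
    cor(per_cancer$median_1, per_cancer$median_2)
  } else NA_real_
  list(pooled = pooled, per_cancer = per_cancer, median_correlation = r)
}

#' Per-cancer purity summary
#'
#' Median and quartiles of tumor purity per cancer, restricted to cancers
#' with at least `min_n` samples (small groups give unstable medians), plus
#' the mean of the per-cancer medians as a cohort-level purity summary.
#'
#' @param samples Data frame with `cancer_code` and `purity` columns.
#' @param min_n Minimum samples per cancer (default 20).
#' @return A list with `table` (data frame `cancer_code`, `n`, `q1`,
#'   `median`, `q3`), `mean_of_medians`, and `n_excluded` cancers.
#' @export
cancer_purity_summary <- function(samples, min_n = 20) {
  stopifnot(all(c("cancer_code", "purity") %in% names(samples)))
  counts <- table(samples$cancer_code)
  use <- names(counts)[counts >= min_n]
  rows <- lapply(sort(use), function(ca) {
    p <- samples$purity[samples$cancer_code == ca]
    q <- quantile(p, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cancer_code = ca, n = length(p),
               q1 = q[1], median = q[2], q3 = q[3])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cancer_code = character(0), n = integer(0),
               q1 = numeric(0), median = numeric(0), q3 = numeric(0))
  list(
    table = tab,
    mean_of_medians = if (nrow(tab)) mean(tab$median) else NA_real_,
    n_excluded = sum(counts < min_n)
  )
}

#' Simulate a PDX-style sample table for cohort statistics
#'
#' Draws per-model mean purities around cancer-level means, then per-sample
#' purities around the model mean, across passages and host strains --
#' the two-variance structure (model-to-model spread larger than
#' within-model spread) that makes purity an intrinsic model property.
#'
#' @param n_models Number of PDX models.
#' @param samples_per_model Samples per model.
#' @param cancers Character vector of cancer codes to draw from.
#' @param strains Two strain labels.
#' @param strain_shift Purity added to samples hosted in the first strain.
#' @param between_sd Sd of model-level mean purities around the cancer
#'   mean.
#' @param within_sd Sd of sample purities around their model mean.
#' @param max_passage Passages are drawn uniformly from 0..`max_passage`.
#' @param seed Integer seed.
#' @return Data frame with `model_id`, `cancer_code`, `strain`, `passage`,
#'   `purity`.
#' @export
gen_sample_table <- function(n_models = 60, samples_per_model = 4,
                             cancers = c("CR", "GA", "KI", "PA", "LU"),
                             strains = c("NOD_SCID", "BALBC_NUDE"),
                             strain_shift = 0,
                             between_sd = 0.12, within_sd = 0.05,
                             max_passage = 10, seed = 1L) {
  set.seed(as.integer(seed))
  cancer_mean <- setNames(runif(length(cancers), 0.6, 0.9), cancers)
  rows <- lapply(seq_len(n_models), function(i) {
    ca <- sample(cancers, 1)
    st <- sample(strains, 1)
    mu <- cancer_mean[[ca]] + rnorm(1, 0, between_sd) +
      if (st == strains[1]) strain_shift else 0
    p <- pmin(pmax(rnorm(samples_per_model, mu, within_sd), 0), 1)
    data.frame(
      model_id = sprintf("PDX%03d", i),
      cancer_code = ca,
      strain = st,
      passage = sample(0:max_passage, samples_per_model, replace = TRUE),
      purity = p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
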