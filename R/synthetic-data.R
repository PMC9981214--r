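#' Simulate read depths at cell-line-specific SNP sites in a syngeneic tumor
#'
#' Emulates the sequencing evidence a syngeneic tumor provides about its own
#' purity. The host mouse is homozygous `HH` at every simulated site while
#' the implanted cell line is either homozygous `TT` (with probability
#' `1 - het_fraction`) or heterozygous `HT` with tumor-allele fraction
#' `het_t1`. In a tumor that is a `theta : (1 - theta)` mixture of cancer and
#' host cells, a sequenced read carries the `T` allele with probability
#' `theta` at homozygous sites and `theta * T1` at heterozygous sites; reads
#' are drawn binomially at a per-site depth simulated from a negative
#' binomial (mean `depth_mean`, size `depth_dispersion`), truncated at 1.
#'
#' @param cfg A [sim_config()].
#' @return A list with `sites` (data frame with columns `site_id`,
#'   `genotype_class` (`"HOM"`/`"HET"`), `H1`, `T1`, `n_H`, `n_T`) and
#'   `theta_true`.
#' @examples
#' sim <- gen_syngeneic_sites(sim_config(seed = 7, theta_true = 0.85))
#' est <- estimate_purity(preprocess_sites(sim$sites))
#' est$theta_hat
#' @export
gen_syngeneic_sites <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_sites
  het <- runif(n) < cfg$het_fraction
  depth <- pmax(1L, rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion))
  p_t <- ifelse(het, cfg$theta_true * cfg$het_t1, cfg$theta_true)
  n_t <- rbinom(n, depth, p_t)
  sites <- data.frame(
    site_id = sprintf("site%05d", seq_len(n)),
    genotype_class = ifelse(het, "HET", "HOM"),
    H1 = ifelse(het, 1 - cfg$het_t1, NA_real_),
    T1 = ifelse(het, cfg$het_t1, NA_real_),
    n_H = as.integer(depth - n_t),
    n_T = as.integer(n_t),
    stringsAsFactors = FALSE
  )
  list(sites = sites, theta_true = cfg$theta_true)
}

#' Simulate per-segment species read counts for the deep amplicon assay
#'
#' Each of `cfg$n_segments` homologous human/mouse amplicon segments is
#' sequenced to `cfg$segment_depth` reads; every read is assigned to human
#' with probability given by the true human-cell fraction, optionally
#' distorted by a per-segment amplification-bias multiplier on the human
#' template (log-normal with standard deviation `bias_sd` on the log scale).
#'
#' @param cfg A [sim_config()].
#' @param human_fraction True human-cell fraction in `[0, 1]`.
#' @param bias_sd Standard deviation of the per-segment log amplification
#'   bias; 0 (default) disables bias.
#' @return A list with `segments` (data frame: `segment_id`, `reads_human`,
#'   `reads_mouse`) and `human_fraction_true`.
#' @examples
#' sim <- gen_segment_counts(sim_config(seed = 3), human_fraction = 0.9)
#' assay_purity(sim$segments)$purity
#' @export
gen_segment_counts <- function(cfg, human_fraction = 0.9, bias_sd = 0) {
  validate_sim_config(cfg)
  stopifnot(human_fraction >= 0, human_fraction <= 1, bias_sd >= 0)
  set.seed(derive_seed(cfg$seed, 2L))
  n <- cfg$n_segments
  b <- if (bias_sd > 0) exp(rnorm(n, 0, bias_sd)) else rep(1, n)
  f_eff <- b * human_fraction / (b * human_fraction + (1 - human_fraction))
  f_eff[!is.finite(f_eff)] <- human_fraction  # f = 0 or 1 edge
  hum <- rbinom(n, cfg$segment_depth, f_eff)
  segments <- data.frame(
    segment_id = sprintf("seg%03d", seq_len(n)),
    reads_human = as.integer(hum),
    reads_mouse = as.integer(cfg$segment_depth - hum),
    stringsAsFactors = FALSE
  )
  list(segments = segments, human_fraction_true = human_fraction)
}

#' Simulate a species-tagged expression cohort with known purity
#'
#' Builds paired human and mouse expression matrices (TPM-like, linear
#' scale) for a PDX-style cohort. For a sample of purity `p`, designated
#' human cancer-marker genes scale with `p`; the stromal/immune signature
#' signal scales with `1 - p` and is split between a residual human stromal
#' compartment (fraction `human_stroma_frac`, jittered per sample with
#' standard deviation `stroma_split_sd`) and the mouse compartment carrying
#' the rest, so human signature genes track `(1-p) * rho` and their mouse
#' orthologs `(1-p) * (1-rho)`. Background genes are purity independent. All
#' values receive multiplicative log-normal noise with sd `cfg$noise_sd`.
#'
#' The split between compartments is what makes the hybrid (human + mouse
#' ortholog) score a better purity readout than either single-species score:
#' the hybrid sum recovers `1 - p` exactly while each compartment alone is
#' corrupted by the random split.
#'
#' @param cfg A [sim_config()].
#' @param signature A signature list as returned by [default_signature()].
#' @param purity Optional vector of true purities (length `cfg$n_samples`);
#'   defaults to `Uniform(0.5, 1)` draws.
#' @param human_stroma_frac Mean fraction of stromal/immune signal residing
#'   in human cells (residual human stroma).
#' @param stroma_split_sd Per-sample jitter (sd) on that fraction.
#' @return A list with `human` and `mouse` expression matrices (genes x
#'   samples), `purity_true`, and `stroma_split` (per-sample human share of
#'   the stromal signal).
#' @export
gen_expression_cohort <- function(cfg, signature = default_signature(),
                                  purity = NULL,
                                  human_stroma_frac = 0.3,
                                  stroma_split_sd = 0.1) {
  validate_sim_config(cfg)
  stopifnot(length(signature$stromal) > 0, length(signature$immune) > 0)
  set.seed(derive_seed(cfg$seed, 3L))
  ns <- cfg$n_samples
  if (is.null(purity)) purity <- runif(ns, 0.5, 1)
  stopifnot(length(purity) == ns, all(purity >= 0 & purity <= 1))

  sig_h <- unique(c(signature$stromal, signature$immune))
  map <- signature$ortholog_map
  sig_m <- unique(map$mouse_id)
  n_cancer <- max(10L, cfg$n_genes %/% 10L)
  cancer_genes <- sprintf("hs_CAN%04d", seq_len(n_cancer))
  bg_h <- sprintf("hs_BG%05d", seq_len(cfg$n_genes))
  bg_m <- sprintf("mm_Bg%05d", seq_len(cfg$n_genes))

  rho <- human_stroma_frac +
    (if (stroma_split_sd > 0) rnorm(ns, 0, stroma_split_sd) else rep(0, ns))
  rho <- pmin(pmax(rho, 0), 1)

  floor_tpm <- 1        # basal transcription level for signal genes
  base_sig <- 200       # full-signal expression scale for signature genes
  base_can <- 200

  lnoise <- function(n) {
    if (cfg$noise_sd > 0) rlnorm(n, 0, cfg$noise_sd) else rep(1, n)
  }
  samples <- sprintf("S%03d", seq_len(ns))

  # human matrix: signature genes + cancer markers + background
  h_genes <- c(sig_h, cancer_genes, bg_h)
  base_bg_h <- rlnorm(length(bg_h), log(50), 1)
  human <- matrix(0, length(h_genes), ns, dimnames = list(h_genes, samples))
  for (j in seq_len(ns)) {
    sig_val <- floor_tpm + base_sig * (1 - purity[j]) * rho[j]
    can_val <- floor_tpm + base_can * purity[j]
    human[, j] <- c(
      rep(sig_val, length(sig_h)),
      rep(can_val, length(cancer_genes)),
      base_bg_h
    ) * lnoise(length(h_genes))
  }

  # mouse matrix: signature orthologs + background
  m_genes <- c(sig_m, bg_m)
  base_bg_m <- rlnorm(length(bg_m), log(50), 1)
  mouse <- matrix(0, length(m_genes), ns, dimnames = list(m_genes, samples))
  for (j in seq_len(ns)) {
    sig_val <- floor_tpm + base_sig * (1 - purity[j]) * (1 - rho[j])
    mouse[, j] <- c(rep(sig_val, length(sig_m)), base_bg_m) *
      lnoise(length(m_genes))
  }

  list(human = human, mouse = mouse, purity_true = purity, stroma_split = rho)
}

#' Simulate an annotated variant table with known germline/somatic labels
#'
#' Germline variants carry at least one germline-identifying feature:
#' population allele frequencies above 0.01 in all three databases,
#' cross-species conservation in two or more of 45 vertebrate genomes, or
#' presence in more than 20% of cohort models; their VAFs sit at the
#' heterozygous (0.5) or homozygous (1.0) germline expectation. Somatic
#' variants carry none of these features and are clonal monoallelic: their
#' alt depth is binomial with success probability
#' `0.5 * purity * mapping_bias`. With the default `mapping_bias = 1` the
#' somatic VAF distribution in a pure tumor is centered at 0.5; setting
#' `mapping_bias` to about 0.94 reproduces the ~0.47 center observed in real
#' data, where reference-biased read mapping slightly deflates alt counts.
#'
#' @param cfg A [sim_config()]; `n_sites` variants are drawn, with depths
#'   from the same negative-binomial coverage model as SNP sites (minimum
#'   depth 30 so the germline/somatic features stay separable).
#' @param germline_fraction Fraction of variants that are germline.
#' @param purity Sample purity scaling somatic VAFs.
#' @param mapping_bias Multiplier on the somatic alt-read probability.
#' @return A list with `variants` (a data frame with VariantRecord columns
#'   including the hidden `label`) and `purity_true`.
#' @export
gen_variant_table <- function(cfg, germline_fraction = 0.5, purity = 1,
                              mapping_bias = 1) {
  validate_sim_config(cfg)
  stopifnot(germline_fraction >= 0, germline_fraction <= 1,
            purity > 0, purity <= 1, mapping_bias > 0, mapping_bias <= 1)
  set.seed(derive_seed(cfg$seed, 4L))
  n <- cfg$n_sites
  germ <- runif(n) < germline_fraction
  depth <- pmax(30L, rnbinom(n, mu = max(cfg$depth_mean, 60), size = cfg$depth_dispersion))

  # which germline rule(s) mark each germline variant (at least one)
  rule <- ifelse(germ, sample.int(3L, n, replace = TRUE), 0L)
  af <- function(on) ifelse(on, runif(n, 0.02, 0.5), 0)
  pop <- rule == 1L
  af_dbsnp <- af(pop); af_gnomad <- af(pop); af_exac <- af(pop)
  vertebrate_hits <- ifelse(rule == 3L, sample(2:45, n, replace = TRUE),
                            sample(0:1, n, replace = TRUE))
  cohort_prevalence <- ifelse(rule == 2L, runif(n, 0.25, 0.9),
                              runif(n, 0, 0.15))

  het <- runif(n) < 0.7
  p_alt <- ifelse(germ, ifelse(het, 0.5, 1), 0.5 * purity * mapping_bias)
  alt <- rbinom(n, depth, p_alt)
  # keep somatic variants clear of the <10% VAF germline rule
  low <- !germ & alt < ceiling(0.15 * depth)
  alt[low] <- ceiling(0.15 * depth[low])

  variants <- data.frame(
    variant_id = sprintf("var%05d", seq_len(n)),
    chrom = "chr1",
    pos = seq_len(n) * 100L,
    ref = "A",
    alt = "G",
    consequence = sample(c("missense", "synonymous", "stop_gained"), n,
                         replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    alt_depth = as.integer(alt),
    total_depth = as.integer(depth),
    vaf = alt / depth,
    af_dbsnp = af_dbsnp,
    af_gnomad = af_gnomad,
    af_exac = af_exac,
    vertebrate_hits = as.integer(vertebrate_hits),
    cohort_prevalence = cohort_prevalence,
    label = ifelse(germ, "GERMLINE", "SOMATIC"),
    stringsAsFactors = FALSE
  )
  list(variants = variants, purity_true = purity)
}

#' Simulate (enrichment score, purity) reference pairs
#'
#' Generates calibration data of the kind used to map a stromal+immune
#' enrichment score to tumor purity: scores span a stated range and purity
#' follows a strictly decreasing smooth curve (a cosine-of-affine form
#' clamped to `[0, 1]`) plus optional Gaussian noise.
#'
#' @param cfg A [sim_config()]; `n_samples` pairs are generated (at least
#'   20 required to fit a curve downstream).
#' @param score_range Numeric length-2: span of the reference scores.
#' @param noise_sd Standard deviation of additive purity noise.
#' @return A list with `pairs` (data frame: `score`, `purity`),
#'   `truth_fun` (the generating function), and `score_range`.
#' @export
gen_score_purity_reference <- function(cfg, score_range = c(-2000, 4000),
                                       noise_sd = 0.02) {
  validate_sim_config(cfg)
  stopifnot(cfg$n_samples >= 20, diff(score_range) > 0, noise_sd >= 0)
  set.seed(derive_seed(cfg$seed, 5L))
  g <- score_purity_truth_fun(score_range)
  s <- sort(runif(cfg$n_samples, score_range[1], score_range[2]))
  p <- g(s) + (if (noise_sd > 0) rnorm(length(s), 0, noise_sd) else 0)
  pairs <- data.frame(score = s, purity = pmin(pmax(p, 0), 1))
  list(pairs = pairs, truth_fun = g, score_range = score_range)
}

# Strictly decreasing cosine-of-affine purity curve over the score range.
score_purity_truth_fun <- function(score_range) {
  lo <- score_range[1]; hi <- score_range[2]
  function(s) {
    z <- (pmin(pmax(s, lo), hi) - lo) / (hi - lo)
    0.5 * (1 + cos(pi * z))
  }
}
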