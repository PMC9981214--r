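#' Simulation configuration
#'
#' Bundles the parameters shared by the synthetic-data generators
#' (`gen_syngeneic_sites()`, `gen_segment_counts()`,
#' `gen_expression_cohort()`, `gen_variant_table()`,
#' `gen_score_purity_reference()`). The same configuration and seed always
#' reproduce the same data.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param theta_true True tumor purity (cancer-cell fraction) in `[0, 1]`
#'   used for syngeneic SNP-site simulation.
#' @param n_sites Number of SNP sites (or variants) to simulate.
#' @param depth_mean Mean sequencing depth per site (reads).
#' @param depth_dispersion Negative-binomial size parameter for per-site
#'   depth; larger values approach Poisson coverage, smaller values give the
#'   heavy-tailed depth variation typical of RNA-seq.
#' @param het_fraction Fraction of simulated cell-line SNP sites that are
#'   heterozygous (the rest are homozygous for the cell-line allele).
#' @param het_t1 Cell-line allele fraction `T1` of the tumor allele at
#'   heterozygous sites; the host allele has fraction `1 - het_t1`.
#' @param n_segments Number of homologous amplicon segments (the assay
#'   uses 108).
#' @param segment_depth Reads per amplicon segment (the assay averages
#'   over 3000x).
#' @param n_samples Number of samples for expression / reference-pair
#'   simulation.
#' @param n_genes Number of background (non-signature) genes per species in
#'   simulated expression matrices.
#' @param noise_sd Standard deviation of multiplicative log-normal
#'   expression noise, on the natural-log scale.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, theta_true = 0.8, n_sites = 200)
#' sim <- gen_syngeneic_sites(cfg)
#' head(sim$sites)
#' @export
sim_config <- function(seed = 1L,
                       theta_true = 0.8,
                       n_sites = 500L,
                       depth_mean = 50,
                       depth_dispersion = 10,
                       het_fraction = 0.5,
                       het_t1 = 0.5,
                       n_segments = 108L,
                       segment_depth = 3000L,
                       n_samples = 50L,
                       n_genes = 2000L,
                       noise_sd = 0.2) {
  cfg <- list(
    seed = as.integer(seed),
    theta_true = theta_true,
    n_sites = as.integer(n_sites),
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    het_fraction = het_fraction,
    het_t1 = het_t1,
    n_segments = as.integer(n_segments),
    segment_depth = as.integer(segment_depth),
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    noise_sd = noise_sd
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    is.finite(cfg$seed),
    length(cfg$theta_true) == 1, cfg$theta_true >= 0, cfg$theta_true <= 1,
    cfg$n_sites >= 1,
    cfg$depth_mean > 0,
    cfg$depth_dispersion > 0,
    cfg$het_fraction >= 0, cfg$het_fraction <= 1,
    cfg$het_t1 > 0, cfg$het_t1 < 1,
    cfg$n_segments >= 1,
    cfg$segment_depth >= 1,
    cfg$n_samples >= 1,
    cfg$n_genes >= 1,
    cfg$noise_sd >= 0
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a reproducible sub-seed so that generators called with the same
# config do not share (or reuse) random streams. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
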