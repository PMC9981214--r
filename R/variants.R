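#' Variant allele fraction
#'
#' @param alt_depth Alternative-allele read count(s).
#' @param total_depth Total read count(s); must be positive and at least
#'   `alt_depth`.
#' @return `alt_depth / total_depth`, vectorised.
#' @examples
#' compute_vaf(47, 100)
#' @export
compute_vaf <- function(alt_depth, total_depth) {
  if (any(total_depth <= 0)) stop("total_depth must be positive")
  if (any(alt_depth > total_depth)) stop("alt_depth exceeds total_depth")
  if (any(alt_depth < 0)) stop("alt_depth must be non-negative")
  alt_depth / total_depth
}

#' Classify variants as germline or somatic without a matched normal
#'
#' PDX tumors have no matched normal tissue, so germline variants are
#' recognised by independent evidence that a call pre-dates the tumor. A
#' variant is labelled `GERMLINE` if any rule fires:
#'
#' 1. **Population frequency**: allele frequencies in dbSNP, gnomAD and
#'    ExAC are all greater than `af_threshold` (0.01).
#' 2. **Cohort prevalence**: the variant is seen in more than
#'    `prevalence_threshold` (20%) of the tested models -- far too common
#'    to be independently acquired somatic events.
#' 3. **Conservation**: the variant allele is present in more than one of
#'    45 other vertebrate genomes.
#' 4. **Low VAF**: variant allele fraction below `vaf_min` (10%); such
#'    calls are treated as germline/noise rather than somatic (this removes
#'    subclonal and artefactual calls from the somatic set and can be
#'    disabled with `apply_low_vaf_rule = FALSE`).
#'
#' All remaining variants are `SOMATIC`. The rules combine by logical OR,
#' so their order is irrelevant.
#'
#' @param variants Data frame with columns `vaf`, `af_dbsnp`, `af_gnomad`,
#'   `af_exac`, `vertebrate_hits`, `cohort_prevalence` (missing annotation
#'   columns are tolerated; see `missing_af`).
#' @param af_threshold Population-frequency cutoff (strict `>`,
#'   default 0.01).
#' @param prevalence_threshold Cohort-prevalence cutoff (strict `>`,
#'   default 0.20).
#' @param vertebrate_min Conservation rule fires when `vertebrate_hits`
#'   is strictly greater than this (default 1, i.e. "more than one").
#' @param vaf_min Low-VAF germline cutoff (strict `<`, default 0.10).
#' @param apply_low_vaf_rule Disable rule 4 with `FALSE`.
#' @param missing_af How an absent (`NA`) population frequency interacts
#'   with rule 1: `"zero"` (default) treats it as 0 so the rule cannot fire
#'   on missing evidence; `"ignore"` drops missing databases from the
#'   all-of requirement (at least one observed frequency still required).
#' @return Character vector of `"GERMLINE"`/`"SOMATIC"`, one per row.
#' @examples
#' v <- data.frame(vaf = c(0.45, 0.45, 0.08),
#'                 af_dbsnp = c(0.02, 0, 0), af_gnomad = c(0.02, 0, 0),
#'                 af_exac = c(0.015, 0, 0),
#'                 vertebrate_hits = c(0, 0, 0),
#'                 cohort_prevalence = c(0, 0.05, 0))
#' classify_variants(v)
#' @export
classify_variants <- function(variants,
                              af_threshold = 0.01,
                              prevalence_threshold = 0.20,
                              vertebrate_min = 1L,
                              vaf_min = 0.10,
                              apply_low_vaf_rule = TRUE,
                              missing_af = c("zero", "ignore")) {
  missing_af <- match.arg(missing_af)
  n <- nrow(variants)
  col <- function(nm) {
    if (is.null(variants[[nm]])) rep(NA_real_, n) else variants[[nm]]
  }
  afs <- cbind(col("af_dbsnp"), col("af_gnomad"), col("af_exac"))
  if (missing_af == "zero") afs[is.na(afs)] <- 0
  above <- afs > af_threshold
  rule_pop <- if (missing_af == "zero") {
    rowSums(above) == ncol(afs)
  } else {
    rowSums(above, na.rm = TRUE) == rowSums(!is.na(afs)) &
      rowSums(!is.na(afs)) > 0
  }
  rule_prev <- col("cohort_prevalence") > prevalence_threshold
  rule_cons <- col("vertebrate_hits") > vertebrate_min
  rule_vaf <- if (apply_low_vaf_rule) variants$vaf < vaf_min else FALSE
  germ <- rule_pop | isTRUE_vec(rule_prev) | isTRUE_vec(rule_cons) | rule_vaf
  ifelse(germ, "GERMLINE", "SOMATIC")
}

# NA (missing annotation) never fires a rule
isTRUE_vec <- function(x) !is.na(x) & x

#' Median VAF of somatic missense mutations in one model
#'
#' Models with enough confidently somatic missense mutations are summarised
#' by their median VAF; in a pure tumor with clonal monoallelic mutations
#' this median sits near 0.5 (slightly below in real data because of
#' read-mapping bias), and it scales down with tumor purity. Models with
#' fewer than `min_missense` qualifying mutations are excluded (`NA`),
#' since a small mutation set gives an unstable median.
#'
#' @param variants Data frame of one model's variants with `consequence`
#'   and `vaf` columns; a `label` column is used if present, otherwise
#'   labels are computed by [classify_variants()].
#' @param min_missense Minimum somatic missense count (default 30).
#' @param ... Passed to [classify_variants()] when labels are computed.
#' @return A list with `median_vaf` (`NA` if excluded) and `n_missense`.
#' @export
model_median_vaf <- function(variants, min_missense = 30, ...) {
  label <- variants$label
  if (is.null(label)) label <- classify_variants(variants, ...)
  sel <- label == "SOMATIC" & variants$consequence == "missense"
  n <- sum(sel)
  list(
    median_vaf = if (n >= min_missense) median(variants$vaf[sel]) else NA_real_,
    n_missense = n
  )
}

#' Cohort prevalence of variants across models
#'
#' Computes, for every distinct variant key, the fraction of models in
#' which it was called -- the input to the cohort-prevalence germline rule,
#' which must be computed across the whole cohort before any per-model
#' classification.
#'
#' @param calls Data frame with columns `model_id` and a variant key column
#'   `variant_id` (one row per model x variant call).
#' @param n_models Total number of tested models (defaults to the number of
#'   distinct `model_id` values in `calls`).
#' @return Data frame of `variant_id`, `n_models_with`, `cohort_prevalence`.
#' @export
cohort_prevalence <- function(calls, n_models = NULL) {
  stopifnot(all(c("model_id", "variant_id") %in% names(calls)))
  if (is.null(n_models)) n_models <- length(unique(calls$model_id))
  stopifnot(n_models >= 1)
  u <- unique(calls[, c("model_id", "variant_id")])
  tab <- table(u$variant_id)
  data.frame(
    variant_id = names(tab),
    n_models_with = as.integer(tab),
    cohort_prevalence = as.integer(tab) / n_models,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
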