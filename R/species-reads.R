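#' Classify reads as human, mouse, ambiguous, or unmapped
#'
#' PDX sequencing reads are aligned to both the human and the mouse
#' reference; a read preferentially mapped to one genome (strictly better
#' alignment score, or mapped to that genome only) is assigned to that
#' species. Reads mapping equally well to both are ambiguous and are
#' discarded from downstream fraction estimates; reads mapping to neither
#' are unmapped. A score margin can require the winning score to exceed the
#' other by more than `margin` before a species is called.
#'
#' @param pairs Data frame with columns `read_id`, `score_human`,
#'   `score_mouse`; `NA` encodes "did not map to that genome".
#' @param margin Minimum score difference for a species call (default 0:
#'   any strict difference decides, equality is ambiguous).
#' @return The input with a `species` factor column
#'   (`HUMAN`/`MOUSE`/`AMBIGUOUS`/`UNMAPPED`).
#' @examples
#' reads <- data.frame(read_id = c("r1", "r2", "r3"),
#'                     score_human = c(60, 50, NA),
#'                     score_mouse = c(40, 50, 55))
#' classify_reads(reads)$species
#' @export
classify_reads <- function(pairs, margin = 0) {
  stopifnot(is.data.frame(pairs), margin >= 0)
  h <- pairs$score_human
  m <- pairs$score_mouse
  species <- rep("AMBIGUOUS", nrow(pairs))
  species[is.na(h) & is.na(m)] <- "UNMAPPED"
  species[!is.na(h) & is.na(m)] <- "HUMAN"
  species[is.na(h) & !is.na(m)] <- "MOUSE"
  both <- !is.na(h) & !is.na(m)
  species[both & (h - m) > margin] <- "HUMAN"
  species[both & (m - h) > margin] <- "MOUSE"
  pairs$species <- factor(species,
                          levels = c("HUMAN", "MOUSE", "AMBIGUOUS", "UNMAPPED"))
  pairs
}

#' Tumor purity as the human fraction of species-assigned reads
#'
#' The proportion of human reads among reads confidently assigned to either
#' species; ambiguous and unmapped reads are excluded. Note that this
#' estimates the human fraction of sequenced *material*, not of cells:
#' capture or expression bias toward one species (e.g. human-exome capture
#' in WES) inflates the estimate accordingly.
#'
#' @param pairs Data frame of read score pairs, or the output of
#'   [classify_reads()] (a `species` column is reused when present).
#' @param margin Passed to [classify_reads()] when classification is
#'   needed.
#' @return A list with `purity`, `n_human`, `n_mouse`, `n_ambiguous`,
#'   `n_unmapped`.
#' @export
read_fraction_purity <- function(pairs, margin = 0) {
  if (is.null(pairs$species)) pairs <- classify_reads(pairs, margin = margin)
  tab <- table(pairs$species)
  n_h <- tab[["HUMAN"]]; n_m <- tab[["MOUSE"]]
  if (n_h + n_m == 0) stop("no reads assigned to either species")
  list(
    purity = n_h / (n_h + n_m),
    n_human = n_h,
    n_mouse = n_m,
    n_ambiguous = tab[["AMBIGUOUS"]],
    n_unmapped = tab[["UNMAPPED"]]
  )
}

#' Simulate read score pairs from a species mixture
#'
#' Draws reads from a human/mouse mixture at a given human read fraction,
#' with optional capture-bias multiplier `bias` on the human sampling rate
#' and a configurable rate of ambiguous (equal-score) reads. Used to study
#' how library bias distorts read-fraction purity.
#'
#' @param n_reads Number of reads.
#' @param human_fraction True human cell-derived fraction of the template.
#' @param bias Multiplier on the human sampling rate (>1 means human
#'   material is over-captured).
#' @param ambiguous_rate Fraction of reads with equal scores.
#' @param seed Integer seed.
#' @return Data frame of `read_id`, `score_human`, `score_mouse`.
#' @export
gen_read_scores <- function(n_reads, human_fraction, bias = 1,
                            ambiguous_rate = 0.02, seed = 1L) {
  stopifnot(n_reads >= 1, human_fraction >= 0, human_fraction <= 1,
            bias > 0, ambiguous_rate >= 0, ambiguous_rate < 1)
  set.seed(as.integer(seed))
  p <- bias * human_fraction / (bias * human_fraction + (1 - human_fraction))
  is_h <- runif(n_reads) < p
  amb <- runif(n_reads) < ambiguous_rate
  base <- sample(40:60, n_reads, replace = TRUE)
  worse <- base - sample(5:20, n_reads, replace = TRUE)
  data.frame(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    score_human = ifelse(amb, base, ifelse(is_h, base, worse)),
    score_mouse = ifelse(amb, base, ifelse(is_h, worse, base)),
    stringsAsFactors = FALSE
  )
}
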