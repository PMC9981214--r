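#' Synthetic stromal/immune gene signature with human-mouse ortholog map
#'
#' Builds a signature object structurally matching the stromal and immune
#' signatures used for expression-based purity scoring: 141 human genes per
#' signature, of which 130 stromal and all 141 immune genes have mouse
#' orthologs (a handful of stromal genes have no one-to-one mouse
#' counterpart), and a few stromal genes map to two mouse orthologs to
#' exercise one-to-many aggregation. Gene identifiers are synthetic and
#' species-tagged (`hs_`/`mm_` prefixes); users with the real signatures
#' supply them in the same structure via [read_gmt()] and
#' [read_ortholog_map()].
#'
#' @param n_stromal,n_immune Signature sizes (defaults 141).
#' @param n_stromal_unmapped Stromal genes without a mouse ortholog
#'   (default 11).
#' @param n_multi Stromal genes with two mouse orthologs (default 5).
#' @return A list with `stromal`, `immune` (character vectors of human gene
#'   IDs) and `ortholog_map` (data frame `human_id`, `mouse_id`).
#' @export
default_signature <- function(n_stromal = 141L, n_immune = 141L,
                              n_stromal_unmapped = 11L, n_multi = 5L) {
  stopifnot(n_stromal >= 1, n_immune >= 1,
            n_stromal_unmapped >= 0, n_stromal_unmapped < n_stromal,
            n_multi >= 0, n_multi <= n_stromal - n_stromal_unmapped)
  stromal <- sprintf("hs_STRM%03d", seq_len(n_stromal))
  immune <- sprintf("hs_IMMN%03d", seq_len(n_immune))
  mapped_stromal <- stromal[seq_len(n_stromal - n_stromal_unmapped)]
  map <- rbind(
    data.frame(human_id = mapped_stromal,
               mouse_id = sub("hs_STRM", "mm_Strm", mapped_stromal)),
    data.frame(human_id = mapped_stromal[seq_len(n_multi)],
               mouse_id = sub("hs_STRM", "mm_StrmB", mapped_stromal[seq_len(n_multi)])),
    data.frame(human_id = immune,
               mouse_id = sub("hs_IMMN", "mm_Immn", immune))
  )
  list(stromal = stromal, immune = immune,
       ortholog_map = map[order(map$human_id), ])
}

#' Hybrid human+mouse expression for ortholog-linked genes
#'
#' For every gene in the human matrix, adds the expression of its mouse
#' ortholog(s) from the mouse matrix (summing over one-to-many orthologs);
#' genes without a mapped or measured mouse ortholog keep their human
#' value. The result is keyed on human gene identifiers and represents the
#' combined transcriptional output of both species' copies of the gene, so
#' that stromal/immune signal residing in mouse cells is not lost when a
#' PDX tumor is scored.
#'
#' @param human,mouse Expression matrices (genes x samples) with identical
#'   sample columns.
#' @param ortholog_map Data frame with `human_id`, `mouse_id` columns.
#' @return A matrix with the human matrix's dimensions and rownames.
#' @examples
#' h <- matrix(5, 1, 1, dimnames = list("hs_G1", "s1"))
#' m <- matrix(c(3, 4), 2, 1, dimnames = list(c("mm_g1a", "mm_g1b"), "s1"))
#' map <- data.frame(human_id = c("hs_G1", "hs_G1"),
#'                   mouse_id = c("mm_g1a", "mm_g1b"))
#' hybridize_expression(h, m, map)  # 5 + 3 + 4 = 12
#' @export
hybridize_expression <- function(human, mouse, ortholog_map) {
  stopifnot(is.matrix(human), is.matrix(mouse))
  if (!identical(colnames(human), colnames(mouse))) {
    stop("human and mouse matrices must share the same sample columns")
  }
  out <- human
  map <- ortholog_map[ortholog_map$human_id %in% rownames(human) &
                        ortholog_map$mouse_id %in% rownames(mouse), ,
                      drop = FALSE]
  if (nrow(map) == 0) return(out)
  for (hid in unique(map$human_id)) {
    mids <- map$mouse_id[map$human_id == hid]
    add <- if (length(mids) == 1) mouse[mids, ] else colSums(mouse[mids, , drop = FALSE])
    out[hid, ] <- out[hid, ] + add
  }
  out
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum enrichment of a gene set within one sample's
#' expression profile. Genes are ranked by expression (average ties),
#' traversed from the highest-expressed down, and the score is the sum over
#' all positions of the difference between the weighted in-set empirical
#' CDF -- in-set genes weighted by `rank^alpha` -- and the uniform
#' out-of-set empirical CDF. A set concentrated at the top of the profile
#' therefore scores high; the statistic depends on the expression values
#' only through their ranks.
#'
#' @param expr Named numeric vector: one sample's expression.
#' @param gene_set Character vector of gene identifiers.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return The enrichment score (unitless).
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(expr)), length(expr) > 1)
  in_set <- names(expr) %in% gene_set
  if (!any(in_set)) stop("no gene-set member present in the expression profile")
  if (all(in_set)) stop("gene set covers the whole profile; out-of-set ECDF undefined")
  r <- rank(expr, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  tag <- in_set[ord]
  w <- r[ord]^alpha
  ecdf_in <- cumsum(ifelse(tag, w, 0)) / sum(w[tag])
  ecdf_out <- cumsum(!tag) / sum(!tag)
  sum(ecdf_in - ecdf_out)
}

#' Stromal, immune, and combined enrichment scores per sample
#'
#' Scores every sample of an expression cohort with the stromal and immune
#' signatures; their sum is the combined (ESTIMATE-style) score used for
#' purity calibration. Three versions are supported, differing in which
#' species' expression carries the signal:
#'
#' * `"human"`: human matrix, human signature genes -- measures
#'   stromal/immune content within the *human* cells (residual human
#'   stroma).
#' * `"mouse"`: mouse matrix, mouse orthologs of the signature genes --
#'   measures content within the *mouse* cells; also the only applicable
#'   version for syngeneic tumors.
#' * `"hybrid"`: [hybridize_expression()] of both matrices, human
#'   signature IDs -- measures content among *all* cells and is the
#'   version whose score tracks overall tumor purity.
#'
#' @param signature Signature list ([default_signature()] structure).
#' @param version `"human"`, `"mouse"`, or `"hybrid"`.
#' @param human,mouse Expression matrices (genes x samples); `human` is
#'   required for the human and hybrid versions, `mouse` for the mouse and
#'   hybrid versions.
#' @param alpha Rank-weighting exponent passed to [ssgsea_score()].
#' @return Data frame with `sample`, `stromal`, `immune`, `estimate`
#'   (= stromal + immune) and a `version` attribute.
#' @export
estimate_scores <- function(signature, version = c("hybrid", "human", "mouse"),
                            human = NULL, mouse = NULL, alpha = 0.25) {
  version <- match.arg(version)
  if (version %in% c("human", "hybrid") && is.null(human)) {
    stop("version '", version, "' requires the human expression matrix")
  }
  if (version %in% c("mouse", "hybrid") && is.null(mouse)) {
    stop("version '", version, "' requires the mouse expression matrix")
  }
  map <- signature$ortholog_map
  to_mouse <- function(ids) unique(map$mouse_id[map$human_id %in% ids])
  if (version == "human") {
    mat <- human
    sets <- list(stromal = signature$stromal, immune = signature$immune)
  } else if (version == "mouse") {
    mat <- mouse
    sets <- list(stromal = to_mouse(signature$stromal),
                 immune = to_mouse(signature$immune))
  } else {
    mat <- hybridize_expression(human, mouse, map)
    sets <- list(stromal = signature$stromal, immune = signature$immune)
  }
  for (nm in names(sets)) {
    found <- mean(sets[[nm]] %in% rownames(mat))
    if (found == 0) stop("no ", nm, " signature genes found in the matrix")
    if (found < 0.5) {
      warning(sprintf("only %.0f%% of %s signature genes found in the matrix",
                      100 * found, nm))
    }
  }
  stromal <- apply(mat, 2, ssgsea_score, gene_set = sets$stromal, alpha = alpha)
  immune <- apply(mat, 2, ssgsea_score, gene_set = sets$immune, alpha = alpha)
  out <- data.frame(
    sample = colnames(mat),
    stromal = unname(stromal),
    immune = unname(immune),
    estimate = unname(stromal + immune),
    stringsAsFactors = FALSE
  )
  attr(out, "version") <- version
  out
}

#' Fit the score-to-purity calibration curve
#'
#' Fits a loess smooth of purity on combined enrichment score over a
#' reference set of (score, purity) pairs (in practice, patient tumors with
#' independently inferred purities). Predictions interpolate the smooth
#' inside the reference score range and extend linearly with the boundary
#' slope outside it, then clamp to `[0, 1]`.
#'
#' @param pairs Data frame with `score` and `purity` columns; at least 20
#'   pairs with non-constant scores.
#' @param span Loess span (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @return An object of class `score_purity_curve` usable with
#'   [score_to_purity()] and `predict()`.
#' @export
fit_score_purity_curve <- function(pairs, span = 0.75, degree = 2) {
  stopifnot(is.data.frame(pairs), all(c("score", "purity") %in% names(pairs)))
  pairs <- pairs[order(pairs$score), ]
  if (nrow(pairs) < 20) stop("at least 20 reference pairs required")
  rng <- range(pairs$score)
  if (diff(rng) == 0) stop("reference scores are all equal")
  fit <- loess(purity ~ score, data = pairs, span = span, degree = degree,
               control = loess.control(surface = "direct"))
  eps <- diff(rng) * 1e-3
  bval <- predict(fit, data.frame(score = c(rng[1], rng[1] + eps,
                                            rng[2] - eps, rng[2])))
  structure(
    list(fit = fit, range = rng, n = nrow(pairs), span = span, degree = degree,
         lo_value = bval[1], lo_slope = (bval[2] - bval[1]) / eps,
         hi_value = bval[4], hi_slope = (bval[4] - bval[3]) / eps),
    class = "score_purity_curve"
  )
}

#' @export
print.score_purity_curve <- function(x, ...) {
  cat(sprintf(
    "Score-to-purity loess calibration: %d pairs, span %.2f, degree %d,\n  score range [%.1f, %.1f]\n",
    x$n, x$span, x$degree, x$range[1], x$range[2]))
  invisible(x)
}

#' @param object A `score_purity_curve`.
#' @param newdata Numeric vector of scores (or data frame with a `score`
#'   column).
#' @param ... Unused.
#' @rdname fit_score_purity_curve
#' @export
predict.score_purity_curve <- function(object, newdata, ...) {
  s <- if (is.data.frame(newdata)) newdata$score else newdata
  p <- rep(NA_real_, length(s))
  inside <- s >= object$range[1] & s <= object$range[2]
  if (any(inside)) {
    p[inside] <- predict(object$fit, data.frame(score = s[inside]))
  }
  lo <- s < object$range[1]
  p[lo] <- object$lo_value + object$lo_slope * (s[lo] - object$range[1])
  hi <- s > object$range[2]
  p[hi] <- object$hi_value + object$hi_slope * (s[hi] - object$range[2])
  pmin(pmax(p, 0), 1)
}

#' Convert enrichment scores to tumor purities
#'
#' Applies a fitted calibration curve to per-sample scores and tags the
#' result with the denominator its purity refers to: the human version
#' measures the cancer-cell fraction among *human* cells, the mouse
#' version among *mouse* cells, and the hybrid version among *all* cells
#' of the tumor -- three biologically distinct quantities.
#'
#' @param curve A [fit_score_purity_curve()] object.
#' @param scores Numeric vector of combined scores, or an
#'   [estimate_scores()] data frame (its `estimate` column and `version`
#'   attribute are used).
#' @param version Overrides the version tag when `scores` is a bare vector.
#' @return Data frame with `sample` (when available), `score`, `purity`,
#'   and `interpretation`.
#' @export
score_to_purity <- function(curve, scores, version = NULL) {
  if (is.data.frame(scores)) {
    version <- version %||% attr(scores, "version")
    sample <- scores$sample
    s <- scores$estimate
  } else {
    sample <- NULL
    s <- scores
  }
  interp <- switch(version %||% "hybrid",
    human = "cancer-cell fraction among human cells",
    mouse = "cancer-cell fraction among mouse cells",
    hybrid = "cancer-cell fraction among all cells"
  )
  out <- data.frame(score = s, purity = predict(curve, s),
                    interpretation = interp, stringsAsFactors = FALSE)
  if (!is.null(sample)) out <- cbind(sample = sample, out)
  out
}
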