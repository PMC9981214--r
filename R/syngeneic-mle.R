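#' Log-likelihood of one SNP site at a given purity
#'
#' In a syngeneic tumor that is a `theta : (1 - theta)` mixture of cancer
#' cells and host cells, the host is homozygous `HH` at a cell-line-specific
#' SNP while the cell line is homozygous `TT` or heterozygous `HT` with
#' allele fractions `H1`, `T1` (`H1 + T1 = 1`). A sequencing read then shows
#' the tumor allele `T` with probability `theta` at a homozygous site and
#' `theta * T1` at a heterozygous site, so with read counts `n_H`, `n_T` the
#' per-site log-likelihood (dropping the theta-independent binomial
#' coefficient) is
#'
#' * `HOM`: `n_H * log(1 - theta) + n_T * log(theta)`
#' * `HET`: `n_H * log(1 - theta * T1) + n_T * log(theta * T1)`
#'
#' with the convention `0 * log(0) = 0` so that the boundary purities 0 and
#' 1 remain evaluable.
#'
#' @param site A one-row data frame (or list) with `genotype_class`
#'   (`"HOM"` or `"HET"`), `n_H`, `n_T`, and `T1` for heterozygous sites.
#' @param theta Purity in `[0, 1]`.
#' @return Log-likelihood in nats.
#' @examples
#' site_loglik(list(genotype_class = "HOM", n_H = 5, n_T = 5), theta = 0.5)
#' @export
site_loglik <- function(site, theta) {
  stopifnot(theta >= 0, theta <= 1)
  gc <- site$genotype_class
  if (!gc %in% c("HOM", "HET")) {
    stop("invalid genotype_class: ", gc, " (must be 'HOM' or 'HET')")
  }
  p_t <- if (gc == "HOM") theta else {
    t1 <- site$T1
    stopifnot(is.finite(t1), t1 > 0, t1 < 1)
    theta * t1
  }
  xlog(site$n_T, p_t) + xlog(site$n_H, 1 - p_t)
}

# x * log(p) with 0 * log(0) = 0; recycles x and p to a common length
xlog <- function(x, p) {
  n <- max(length(x), length(p))
  x <- rep_len(x, n)
  p <- rep_len(p, n)
  out <- numeric(n)
  nz <- x != 0
  out[nz] <- x[nz] * log(p[nz])
  out
}

#' Cohort log-likelihood over SNP sites
#'
#' Sums [site_loglik()] over all sites, vectorised over a grid of purity
#' values. Sites are aggregated by genotype class and `T1` so the cost is
#' independent of the number of sites once counts are pooled.
#'
#' @param sites Data frame of SNP sites (columns `genotype_class`, `n_H`,
#'   `n_T`, and `T1` for HET rows).
#' @param theta Numeric vector of purity values in `[0, 1]`.
#' @return Numeric vector of log-likelihoods, one per `theta`.
#' @export
cohort_loglik <- function(sites, theta) {
  if (is.null(nrow(sites)) || nrow(sites) == 0) stop("no SNP sites supplied")
  stopifnot(all(theta >= 0), all(theta <= 1))
  bad <- !sites$genotype_class %in% c("HOM", "HET")
  if (any(bad)) stop("invalid genotype_class in rows: ",
                     paste(utils::head(which(bad)), collapse = ", "))

  ll <- numeric(length(theta))
  hom <- sites$genotype_class == "HOM"
  if (any(hom)) {
    a <- sum(sites$n_H[hom]); b <- sum(sites$n_T[hom])
    ll <- ll + xlog(b, theta) + xlog(a, 1 - theta)
  }
  if (any(!hom)) {
    het <- sites[!hom, , drop = FALSE]
    if (any(!is.finite(het$T1)) || any(het$T1 <= 0) || any(het$T1 >= 1)) {
      stop("HET sites require T1 in (0, 1)")
    }
    for (t1 in unique(het$T1)) {
      grp <- het$T1 == t1
      a <- sum(het$n_H[grp]); b <- sum(het$n_T[grp])
      ll <- ll + xlog(b, theta * t1) + xlog(a, 1 - theta * t1)
    }
  }
  ll
}

#' Depth-filter and depth-cap SNP sites
#'
#' Removes sites with total read depth below `depth_min` (low-depth sites
#' are false-positive prone), then caps the influence of very deep sites:
#' any retained site whose depth exceeds `cap_multiplier` times the median
#' retained depth is either rescaled to the cap -- preserving its allele
#' fraction `n_T / (n_H + n_T)` with half-up integer rounding -- or dropped,
#' depending on `cap_mode`. RNA-seq depths can differ by orders of magnitude
#' between sites, and without the cap a handful of very deep sites would
#' dominate the likelihood.
#'
#' @param sites Data frame of SNP sites.
#' @param depth_min Minimum total depth; sites below it are removed
#'   (default 20).
#' @param cap_multiplier Cap = `cap_multiplier` x median retained depth
#'   (default 5).
#' @param cap_mode `"rescale"` (default) shrinks over-cap sites to the cap;
#'   `"drop"` removes them.
#' @return The filtered (and possibly rescaled) site data frame, input
#'   order preserved, with attributes `n_removed` and `n_capped`.
#' @examples
#' sites <- data.frame(genotype_class = "HOM",
#'                     n_H = c(10, 10, 10, 1800), n_T = c(30, 30, 30, 200))
#' # median depth 40, cap 200: the deep site is rescaled to n_H=180, n_T=20
#' preprocess_sites(sites, depth_min = 20, cap_multiplier = 5)
#' @export
preprocess_sites <- function(sites, depth_min = 20, cap_multiplier = 5,
                             cap_mode = c("rescale", "drop")) {
  cap_mode <- match.arg(cap_mode)
  if (is.null(nrow(sites)) || nrow(sites) == 0) stop("no SNP sites supplied")
  depth <- sites$n_H + sites$n_T
  keep <- depth >= depth_min
  if (!any(keep)) stop("insufficient data: all sites below depth_min")
  out <- sites[keep, , drop = FALSE]
  out$n_H <- as.integer(out$n_H)
  out$n_T <- as.integer(out$n_T)
  depth <- depth[keep]
  cap <- cap_multiplier * median(depth)
  over <- depth > cap
  if (any(over)) {
    if (cap_mode == "drop") {
      out <- out[!over, , drop = FALSE]
      if (nrow(out) == 0) stop("insufficient data: all sites above depth cap")
    } else {
      cap_tot <- round_half_up(cap)
      n_t <- round_half_up(cap_tot * out$n_T[over] / depth[over])
      out$n_T[over] <- as.integer(n_t)
      out$n_H[over] <- as.integer(cap_tot - n_t)
    }
  }
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_capped") <- sum(over)
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Maximum-likelihood tumor purity from SNP-site read depths
#'
#' Evaluates the cohort log-likelihood on the grid `{0, grid_step, ..., 1}`
#' and returns the maximising purity; ties are broken toward the smallest
#' grid point. For purely homozygous data the estimator has the closed form
#' `sum(n_T) / sum(n_H + n_T)`, which the grid search recovers to within one
#' grid step; the grid formulation additionally handles mixed HOM/HET site
#' sets where no closed form exists.
#'
#' @param sites Data frame of SNP sites, normally already passed through
#'   [preprocess_sites()].
#' @param grid_step Grid resolution in `(0, 0.1]` (default 0.001).
#' @return An object of class `purity_estimate`: a list with `theta_hat`,
#'   `loglik_grid` (data frame `theta`, `loglik`), `n_sites_used`, and
#'   `n_sites_capped` (carried over from preprocessing when available).
#' @examples
#' sites <- data.frame(genotype_class = "HOM", n_H = c(2, 3), n_T = c(8, 7))
#' estimate_purity(sites)$theta_hat  # 15/20 = 0.75
#' @export
estimate_purity <- function(sites, grid_step = 0.001) {
  if (is.null(nrow(sites)) || nrow(sites) == 0) stop("no SNP sites supplied")
  stopifnot(grid_step > 0, grid_step <= 0.1)
  grid <- seq(0, 1, by = grid_step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  ll <- cohort_loglik(sites, grid)
  if (all(!is.finite(ll))) stop("log-likelihood non-finite on entire grid")
  best <- which.max(ll)  # first index on ties = smallest theta
  structure(
    list(
      theta_hat = grid[best],
      loglik_grid = data.frame(theta = grid, loglik = ll),
      n_sites_used = nrow(sites),
      n_sites_capped = attr(sites, "n_capped") %||% NA_integer_
    ),
    class = "purity_estimate"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("Tumor purity estimate: theta_hat = %.3f (%d sites",
              x$theta_hat, x$n_sites_used))
  if (!is.na(x$n_sites_capped)) cat(sprintf(", %d depth-capped", x$n_sites_capped))
  cat(")\n")
  invisible(x)
}

#' Assign HOM/HET genotype class from cell-line allele fractions
#'
#' Convenience for callers that start from cell-line sequencing rather than
#' curated genotype calls: the cell-line alternative-allele fraction is
#' thresholded into homozygous (`>= hom_min`), heterozygous
#' (`[het_min, hom_min)`), or `NA` (likely host-shared or artefactual,
#' excluded upstream).
#'
#' @param alt_frac Numeric vector of cell-line alt-allele fractions.
#' @param hom_min Minimum fraction called homozygous (default 0.85).
#' @param het_min Minimum fraction called heterozygous (default 0.15).
#' @return Character vector `"HOM"`, `"HET"`, or `NA`.
#' @export
assign_genotype_class <- function(alt_frac, hom_min = 0.85, het_min = 0.15) {
  stopifnot(het_min < hom_min)
  out <- rep(NA_character_, length(alt_frac))
  out[alt_frac >= hom_min] <- "HOM"
  out[alt_frac >= het_min & alt_frac < hom_min] <- "HET"
  out
}
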