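# Independent brute-force oracles used to validate the package's
# implementations. These are deliberately written as slow, literal
# transcriptions of the definitions and share no code with R/.

# Running-sum single-sample enrichment score, literal loop over the
# descending-rank gene order.
brute_ssgsea <- function(expr, gene_set, alpha = 0.25) {
  r <- rank(expr, ties.method = "average")
  ord <- names(sort(r, decreasing = TRUE))
  in_set <- ord %in% gene_set
  w <- r[ord]^alpha
  denom_in <- sum(w[in_set])
  n_out <- sum(!in_set)
  f_in <- 0; f_out <- 0; score <- 0
  for (i in seq_along(ord)) {
    if (in_set[i]) f_in <- f_in + w[i] / denom_in else f_out <- f_out + 1 / n_out
    score <- score + (f_in - f_out)
  }
  unname(score)
}

# Mann-Whitney U statistic by direct pair counting.
brute_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled observations to the two groups (tie-free inputs only).
brute_u_pvalue <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  obs <- brute_u_stat(x, y)
  mu <- length(x) * length(y) / 2
  combos <- combn(length(pool), n)
  us <- apply(combos, 2, function(idx) brute_u_stat(pool[idx], pool[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Spearman rho from first principles: average ranks computed by counting,
# then the Pearson product-moment formula on the ranks.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Deterministic HOM/HET site table with known pooled counts.
make_sites <- function(n_hom, n_het, depth = 50, theta = 0.8, t1 = 0.5,
                       seed = 1) {
  set.seed(seed)
  rows <- list()
  if (n_hom > 0) {
    n_t <- rbinom(n_hom, depth, theta)
    rows$hom <- data.frame(genotype_class = "HOM", H1 = NA, T1 = NA,
                           n_H = depth - n_t, n_T = n_t)
  }
  if (n_het > 0) {
    n_t <- rbinom(n_het, depth, theta * t1)
    rows$het <- data.frame(genotype_class = "HET", H1 = 1 - t1, T1 = t1,
                           n_H = depth - n_t, n_T = n_t)
  }
  do.call(rbind, rows)
}
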