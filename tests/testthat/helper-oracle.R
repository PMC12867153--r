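# Independent reference implementations used as oracles. These are written
# from the definitions directly (exhaustive search, manual percentile
# arithmetic, full permutation enumeration) and share no code with the
# package internals they check.

# all indices within `radius` of query point q (inclusive), excluding q
brute_neighbors <- function(x, y, radius, q) {
  d <- sqrt((x - x[q])^2 + (y - y[q])^2)
  sort(setdiff(which(d <= radius), q))
}

# linear-interpolation percentile between order statistics
brute_percentile <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(s[n])
  s[lo + 1] * (1 - (h - lo)) + s[lo + 2] * (h - lo)
}

# exhaustive per-cancer-cell pressure for one sample table
brute_pressure <- function(tab, marker, radius, cancer_idx, p = 0.9) {
  vapply(cancer_idx, function(q) {
    nb <- brute_neighbors(tab$x, tab$y, radius, q)
    if (length(nb) == 0L) NA_real_ else brute_percentile(tab[[marker]][nb], p)
  }, numeric(1))
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# values into groups of the observed sizes (tie-free inputs only)
enumerate_ranksum_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  ranks <- rank(pool)
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - na * (na + 1) / 2
  })
  mu <- na * (n - na) / 2
  # symmetric null: double the smaller tail, capped at 1
  if (u_obs <= mu) min(1, 2 * mean(u_all <= u_obs))
  else min(1, 2 * mean(u_all >= u_obs))
}

# small helper: synthetic single-sample table with uniform cells
random_cell_table <- function(n, n_markers = 2, seed, field = 100,
                              sample_id = "s1", cancer_frac = 0.3) {
  set.seed(seed)
  tab <- data.frame(sample_id = sample_id,
                    cell_id = sprintf("c%04d", seq_len(n)),
                    x = runif(n, 0, field), y = runif(n, 0, field),
                    area = runif(n, 50, 150),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_markers)) {
    tab[[paste0("M", k)]] <- rlnorm(n, 3, 1)
  }
  tab$cell_class <- ifelse(seq_len(n) <= round(cancer_frac * n),
                           "cancer", "other")
  tab
}
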