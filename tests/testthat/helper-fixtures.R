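# Small deterministic fixtures and independent brute-force oracles.

make_sheet <- function(ids, substrate = "populus", time_h = 12,
                       bio_rep = seq_along(ids), tech_rep = 1L,
                       platform = "rnaseq") {
  data.frame(sample_id = ids, substrate = substrate, time_h = time_h,
             bio_rep = bio_rep, tech_rep = tech_rep, platform = platform,
             stringsAsFactors = FALSE)
}

make_counts <- function(values, ids = paste0("s", seq_len(ncol(values))),
                        genes = sprintf("g%03d", seq_len(nrow(values))),
                        sheet = make_sheet(ids)) {
  dimnames(values) <- list(genes, ids)
  expression_matrix(values, sheet, "raw_count")
}

# a 2x2 factorial sheet with n_bio replicates per condition
factorial_sheet <- function(n_bio = 2, platform = "rnaseq", tech_rep = 1L) {
  d <- expand.grid(bio_rep = seq_len(n_bio), time_h = c(12, 37),
                   substrate = c("populus", "switchgrass"),
                   tech_rep = seq_len(tech_rep),
                   stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%dh_b%d_t%d_%s", d$substrate, d$time_h,
                         d$bio_rep, d$tech_rep, platform)
  d$platform <- platform
  d[, c("sample_id", "substrate", "time_h", "bio_rep", "tech_rep",
        "platform")]
}

geomean <- function(x) exp(mean(log(x)))

# --- independent oracles (coded apart from the production path) ---

# brute-force TMM: sort-and-slice trimming, explicit loop over genes
bf_tmm_log2 <- function(xj, xr, Nj, Nr, trim_m = 0.30, trim_a = 0.05) {
  M <- A <- w <- c()
  for (g in seq_along(xj)) {
    if (xj[g] > 0 && xr[g] > 0) {
      pj <- xj[g] / Nj; pr <- xr[g] / Nr
      M <- c(M, log2(pj / pr))
      A <- c(A, 0.5 * log2(pj * pr))
      w <- c(w, (Nj - xj[g]) / (Nj * xj[g]) + (Nr - xr[g]) / (Nr * xr[g]))
    }
  }
  n <- length(M)
  keepM <- order(M)[(floor(n * trim_m) + 1):(n - floor(n * trim_m))]
  keepA <- order(A)[(floor(n * trim_a) + 1):(n - floor(n * trim_a))]
  keep <- intersect(keepM, keepA)
  sum(M[keep] / w[keep]) / sum(1 / w[keep])
}

# exhaustive grid-search mode of a Gaussian-kernel density
bf_kde_mode <- function(m, h, step = 1e-4) {
  grid <- seq(min(m) - 3 * h, max(m) + 3 * h, by = step)
  dens <- vapply(grid, function(x) sum(dnorm(x, m, h)), numeric(1))
  grid[which.max(dens)]
}

# stepwise Benjamini-Hochberg: q_i = min over i' >= i of p_(i') * m / i'
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# pooled-variance two-group t-test across a 4-group cell-means layout
bf_pooled_t <- function(groups, l, r) {
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- sum(n) - k
  s2 <- ss / df
  delta <- mean(groups[[l]]) - mean(groups[[r]])
  t <- delta / sqrt(s2 * (1 / n[l] + 1 / n[r]))
  list(delta = delta, t = t, p = 2 * pt(-abs(t), df))
}
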