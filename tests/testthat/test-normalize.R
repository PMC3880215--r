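counts44 <- function() {
  set.seed(1)
  vals <- matrix(rpois(400 * 4, lambda = rep(c(5, 50, 500, 2), each = 100)),
                 400, 4)
  make_counts(vals, sheet = make_sheet(paste0("s", 1:4)))
}

test_that("RPM arithmetic, conservation and factors", {
  vals <- matrix(c(200, 1999800, 100, 999900), 2, 2)
  em <- make_counts(vals, ids = c("a", "b"),
                    sheet = make_sheet(c("a", "b")))
  r <- normalize_rpm(em)
  lin <- 2^r$normalized$values
  expect_equal(lin["g001", "a"], 100)          # 200 reads in 2M -> 100 RPM
  expect_equal(unname(r$factors), c(2, 1))
  expect_equal(unname(colSums(lin)), c(1e6, 1e6))  # exact conservation

  # equal totals: one shared constant
  em2 <- make_counts(matrix(c(10, 90, 30, 70), 2, 2))
  r2 <- normalize_rpm(em2)
  ratio <- 2^r2$normalized$values / em2$values
  expect_equal(max(ratio), min(ratio))

  zero <- make_counts(matrix(c(1, 2, 0, 0), 2, 2))
  expect_error(suppressMessages(normalize_rpm(zero)), "s2")
})

test_that("RPM shifts the median by -1 log2 per doubling of library size", {
  set.seed(2)
  base <- rpois(500, 100)
  em <- make_counts(cbind(base, base * 2), ids = c("n1", "n2"),
                    sheet = make_sheet(c("n1", "n2")))
  r <- normalize_rpm(em)
  med_raw <- median(log2(base))
  med_norm <- median(r$normalized$values[, "n1"])
  # library 1e6 would leave values unchanged; here N ~ 5e4, so the median
  # shifts by log2(1e6/N)
  expect_equal(med_norm, med_raw + log2(1e6 / sum(base)), tolerance = 1e-10)
})

test_that("RPKM arithmetic, identity case and length homogeneity", {
  vals <- matrix(c(200, 1999800), 2, 1)
  em <- make_counts(vals, ids = "a", sheet = make_sheet("a"))
  lens <- data.frame(gene_id = c("g001", "g002"), length_bp = c(1000, 2000))
  r <- normalize_rpkm(em, lens)
  expect_equal(2^r$normalized$values["g001", "a"], 100)

  # L = 1000 bp and N = 1e6 leaves raw counts unchanged
  em2 <- make_counts(matrix(c(300, 1e6 - 300), 2, 1), ids = "a",
                     sheet = make_sheet("a"))
  lens2 <- data.frame(gene_id = c("g001", "g002"),
                      length_bp = c(1000, 1000))
  r2 <- normalize_rpkm(em2, lens2)
  expect_equal(2^r2$normalized$values[, "a"], c(g001 = 300, g002 = 1e6 - 300))

  lens3 <- transform(lens2, length_bp = length_bp * 2)
  r3 <- normalize_rpkm(em2, lens3)
  expect_equal(2^r3$normalized$values, 2^r2$normalized$values / 2)

  # genes without a length are dropped, not defaulted
  expect_message(r4 <- normalize_rpkm(em2, lens2[1, , drop = FALSE]),
                 "without annotated length")
  expect_equal(nrow(r4$normalized$values), 1)
})

test_that("UQS: symmetry, scale equivariance, equalized upper quartiles", {
  a <- c(0, 10, 20, 30, 40)
  em <- make_counts(cbind(a, a), ids = c("s1", "s2"),
                    sheet = make_sheet(c("s1", "s2")))
  expect_equal(unname(normalize_uqs(em)$factors), c(1, 1))

  em2 <- make_counts(cbind(a, 2 * a), ids = c("s1", "s2"),
                     sheet = make_sheet(c("s1", "s2")))
  f <- normalize_uqs(em2)$factors
  expect_equal(unname(f[2] / f[1]), 2)

  em3 <- make_counts(cbind(a, 3 * a), ids = c("s1", "s2"),
                     sheet = make_sheet(c("s1", "s2")))
  f3 <- normalize_uqs(em3)$factors
  expect_equal(unname(f3[2] / f3[1]), 3)

  # post-normalization nonzero 75th percentiles are equal across samples
  em4 <- counts44()
  u <- normalize_uqs(em4)
  lin <- sweep(em4$values, 2, u$factors, `/`)
  q <- apply(lin, 2, function(x) quantile(x[x > 0], 0.75, type = 7))
  expect_equal(max(q) - min(q), 0, tolerance = 1e-9)
})

test_that("TMM: identity, pure-scaling invariance, brute-force oracle, edgeR cross-check", {
  # identical samples: all M are 0, both factors 1
  x0 <- rpois(200, 60) + 1
  em_id <- make_counts(cbind(x0, x0), ids = c("s1", "s2"),
                       sheet = make_sheet(c("s1", "s2")))
  expect_equal(unname(normalize_tmm(em_id, ref = "s1")$factors), c(1, 1))

  # B = 3 x A: M values identically 0, composition factor 1 for both
  a <- rpois(300, 50) + 1
  em2 <- make_counts(cbind(a, 3 * a), ids = c("s1", "s2"),
                     sheet = make_sheet(c("s1", "s2")))
  t2 <- normalize_tmm(em2, ref = "s1")
  expect_equal(unname(t2$factors), c(1, 1), tolerance = 1e-12)

  # planted composition shift: independent brute-force implementation
  set.seed(7)
  base <- rpois(1000, 100) + 1
  b <- base
  up <- sample.int(1000, 100)
  b[up] <- b[up] * 8
  em3 <- make_counts(cbind(base, b), ids = c("s1", "s2"),
                     sheet = make_sheet(c("s1", "s2")))
  t3 <- normalize_tmm(em3, ref = "s1")
  oracle <- 2^bf_tmm_log2(b, base, sum(b), sum(base))
  got <- unname(t3$factors["s2"] / t3$factors["s1"])
  expect_lt(abs(got / oracle - 1), 0.05)

  skip_if_not_installed("edgeR")
  f_e <- edgeR::calcNormFactors(em3$values, method = "TMM",
                                refColumn = 1, doWeighting = TRUE)
  expect_lt(abs(got / (f_e[2] / f_e[1]) - 1), 0.05)
})

test_that("KDMM: symmetry, degenerate unimodal case, mode vs grid-search oracle", {
  em <- counts44()
  k0 <- normalize_kdmm(make_counts(cbind(em$values[, 1], em$values[, 1]),
                                   ids = c("s1", "s2"),
                                   sheet = make_sheet(c("s1", "s2"))))
  expect_equal(unname(k0$factors), c(1, 1), tolerance = 1e-9)

  # sample proportional to the pseudo-reference pattern: factor tracks c
  x <- rpois(400, 200) + 1
  em2 <- make_counts(cbind(x, 4 * x), ids = c("s1", "s2"),
                     sheet = make_sheet(c("s1", "s2")))
  k2 <- normalize_kdmm(em2)
  expect_equal(unname(k2$factors[2] / k2$factors[1]), 4, tolerance = 1e-6)

  # bimodal M mixture: mode finds the majority component, mean does not
  set.seed(11)
  m <- c(rnorm(800, 0, 0.1), rnorm(200, 3, 0.1))
  h <- bw.nrd0(m)
  mode_hat <- normconcord:::kdmm_location(m, statistic = "mode")
  expect_lt(abs(mode_hat - 0), 0.05)
  mean_hat <- normconcord:::kdmm_location(m, statistic = "mean")
  expect_equal(mean_hat, mean(m))
  expect_gt(mean_hat, 0.5)
  # oracle equivalence: exhaustive grid search at 1e-4 resolution
  expect_lt(abs(mode_hat - bf_kde_mode(m, h)), 1e-4 + 1e-6)
})

test_that("UQS/TMM/KDMM factors have geometric mean one", {
  em <- counts44()
  for (r in list(normalize_uqs(em), normalize_tmm(em), normalize_kdmm(em))) {
    expect_equal(geomean(r$factors), 1, tolerance = 1e-12)
    expect_equal(geomean(size_factors(r)), 1, tolerance = 1e-12)
  }
})

test_that("scale equivariance: scaling one sample leaves its normalized values unchanged", {
  set.seed(3)
  vals <- matrix(rpois(1200, 80) + 1, 300, 4)  # all-positive genes
  em <- make_counts(vals, sheet = make_sheet(paste0("s", 1:4)))
  em_sc <- em
  em_sc$values[, 2] <- em$values[, 2] * 5
  # factors are anchored at geometric mean 1, so scaling one sample by c
  # shifts every normalized value by the same log2(c)/n constant and
  # changes nothing else: the matrix difference must be that constant.
  for (fn in list(normalize_uqs, normalize_kdmm)) {
    n1 <- fn(em, pseudocount = 0)
    n2 <- fn(em_sc, pseudocount = 0)
    d <- n2$normalized$values - n1$normalized$values
    expect_lt(diff(range(d)), 1e-8)
    expect_equal(mean(d), log2(5) / 4, tolerance = 1e-6)
  }
  # TMM's precision weights depend weakly on absolute counts, so its
  # equivariance is approximate rather than exact
  t1 <- normalize_tmm(em, ref = "s1", pseudocount = 0)
  t2 <- normalize_tmm(em_sc, ref = "s1", pseudocount = 0)
  expect_equal(unname(t2$factors), unname(t1$factors), tolerance = 5e-3)
  d <- t2$normalized$values - t1$normalized$values
  expect_lt(diff(range(d)), 0.01)
  expect_equal(mean(d), log2(5) / 4, tolerance = 1e-2)
})

test_that("LOESS: fixed point, constant offset removal, sinusoidal bias reduction", {
  set.seed(5)
  n <- 5000
  abar0 <- rnorm(n, 10, 1)
  mk <- function(y) {
    rownames(y) <- sprintf("g%04d", seq_len(nrow(y)))
    colnames(y) <- paste0("s", seq_len(ncol(y)))
    expression_matrix(y, make_sheet(colnames(y), platform = "array",
                                    bio_rep = seq_len(ncol(y))),
                      "log2_intensity")
  }
  same <- mk(cbind(abar0, abar0, abar0))
  r <- normalize_loess(same)
  expect_equal(r$normalized$values, same$values, tolerance = 1e-8)

  # constant additive offset is within the span of the smoother
  y <- cbind(abar0 + rnorm(n, 0, 0.05), abar0 + rnorm(n, 0, 0.05) + 2,
             abar0 + rnorm(n, 0, 0.05))
  off <- normalize_loess(mk(y))
  expect_lt(abs(mean(off$normalized$values[, 2] -
                       rowMeans(off$normalized$values))), 1e-3)

  # intensity-dependent bias: binned residual trend shrinks >= 10-fold
  y2 <- cbind(abar0 + rnorm(n, 0, 0.1),
              abar0 + 0.5 * sin(abar0) + rnorm(n, 0, 0.1),
              abar0 + rnorm(n, 0, 0.1), abar0 + rnorm(n, 0, 0.1))
  em2 <- mk(y2)
  ln <- normalize_loess(em2, span = 0.3)
  abar <- rowMeans(y2)
  qb <- cut(abar, quantile(abar, seq(0, 1, length.out = 21)),
            include.lowest = TRUE)
  trend <- function(v) max(abs(tapply(v, qb, mean)))
  before <- trend(y2[, 2] - abar)
  after <- trend(ln$normalized$values[, 2] - rowMeans(ln$normalized$values))
  expect_gt(before / after, 10)

  expect_error(normalize_loess(mk(cbind(abar0[1:50], abar0[1:50]))),
               "at least")
})

test_that("distribution summaries flag the depth-rescaling methods", {
  sim <- suppressMessages(simulate_experiment(sim_config(
    n_genes = 1200, seed = 12)))
  lens <- data.frame(gene_id = names(sim$truth$gene_lengths),
                     length_bp = unname(sim$truth$gene_lengths))
  res <- suppressMessages(list(
    rpm = normalize_rpm(sim$counts), rpkm = normalize_rpkm(sim$counts, lens),
    uqs = normalize_uqs(sim$counts), kdmm = normalize_kdmm(sim$counts)))
  tab <- suppressMessages(compare_distributions(res, raw = sim$counts))
  shift <- tapply(abs(tab$median_shift), tab$method, mean)
  expect_gt(shift["RPM"], shift["KDMM"])
  expect_gt(shift["RPM"], shift["UQS"])
  expect_gt(shift["RPKM"], shift["KDMM"])
  expect_true(all(c("RPM", "RPKM") %in% attr(tab, "flagged_methods")))

  # methods that rescale by identical factors give identical summaries
  em <- counts44()
  u <- normalize_uqs(em)
  fake <- u; fake$method <- "OTHER"
  tab2 <- compare_distributions(list(u, fake))
  num <- c("q05", "q25", "q50", "q75", "q95", "mean", "sd")
  expect_equal(as.matrix(tab2[tab2$method == "UQS", num]),
               as.matrix(tab2[tab2$method == "OTHER", num]),
               ignore_attr = TRUE)
})

test_that("zero-handling policy: pseudocount on zero cells or missing", {
  em <- make_counts(matrix(c(0, 5, 10, 3, 5, 10), 3, 2))
  r <- normalize_rpm(em)
  expect_true(all(is.finite(r$normalized$values)))
  rm <- normalize_rpm(em, zero_policy = "missing")
  expect_true(is.na(rm$normalized$values[1, 1]))
  expect_false(anyNA(rm$normalized$values[-1, ]))
  # genes with no counts anywhere are removed first
  em2 <- make_counts(matrix(c(0, 5, 10, 0, 5, 10), 3, 2) * c(0, 1, 1))
  expect_message(r2 <- normalize_rpm(em2), "removed")
  expect_equal(nrow(r2$normalized$values), 2)
})
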