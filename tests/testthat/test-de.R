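# a log2 matrix over the 2x2 design with given per-condition group means
log2_design_matrix <- function(gene_means, n_bio = 2, noise_sd = 0,
                               platform = "rnaseq") {
  sheet <- factorial_sheet(n_bio = n_bio, platform = platform)
  conds <- paste0(sheet$substrate, "_", sheet$time_h, "h")
  vals <- sapply(seq_len(nrow(sheet)), function(j)
    gene_means[, conds[j]] + rnorm(nrow(gene_means), 0, noise_sd))
  vals <- matrix(vals, nrow = nrow(gene_means))
  dimnames(vals) <- list(rownames(gene_means), sheet$sample_id)
  expression_matrix(vals, sheet,
                    if (platform == "array") "log2_intensity" else
                      "log2_count")
}

cond_cols <- c("populus_12h", "populus_37h", "switchgrass_12h",
               "switchgrass_37h")

test_that("technical replicates collapse by arithmetic mean, idempotently", {
  sheet <- factorial_sheet(n_bio = 1, platform = "array", tech_rep = 3)
  sheet <- sheet[sheet$substrate == "populus" & sheet$time_h == 12, ]
  vals <- matrix(c(4, 6, 5), 1, 3,
                 dimnames = list("g1", sheet$sample_id))
  em <- expression_matrix(vals, sheet, "log2_intensity")
  cl <- collapse_technical(em)
  expect_equal(unname(cl$values[1, 1]), 5)   # mean of 4, 6, 5
  expect_equal(ncol(cl$values), 1)
  expect_equal(collapse_technical(cl)$values, cl$values)  # idempotent

  # single tech rep passes through unchanged
  one <- subset_matrix(em, samples = 1)
  expect_equal(unname(collapse_technical(one)$values), unname(one$values))
})

test_that("identical groups give zero ratio and p = 1; contrasts follow left minus right", {
  gm <- matrix(5, 2, 4, dimnames = list(c("g1", "g2"), cond_cols))
  gm["g2", "populus_12h"] <- 8  # 3 log2 units above everything else
  set.seed(1)
  em <- log2_design_matrix(gm, n_bio = 3, noise_sd = 0.2)
  de <- suppressWarnings(fit_anova(em, alpha = 0.05, lfc = 1))
  flat <- de[de$gene == "g1", ]
  expect_true(all(abs(flat$log2_ratio) < 0.5))
  c1 <- de[de$gene == "g2" &
             de$contrast == "populus_12h_vs_switchgrass_12h", ]
  expect_gt(c1$log2_ratio, 2)   # positive: left (populus 12 h) higher
})

test_that("per-gene t statistic and p match a hand-coded pooled-variance computation", {
  gm <- matrix(c(8, 5, 6, 6), 1, 4, dimnames = list("g1", cond_cols))
  set.seed(2)
  em <- log2_design_matrix(gm, n_bio = 2, noise_sd = 0.3)
  de <- suppressWarnings(fit_anova(em))
  cond <- paste0(em$samples$substrate, "_", em$samples$time_h, "h")
  groups <- lapply(cond_cols, function(g) em$values[1, cond == g])
  names(groups) <- cond_cols
  orc <- bf_pooled_t(groups, "populus_12h", "populus_37h")
  row <- de[de$contrast == "populus_12h_vs_populus_37h", ]
  expect_equal(row$log2_ratio, unname(orc$delta), tolerance = 1e-12)
  expect_equal(row$p_value, unname(orc$p), tolerance = 1e-12)
  expect_equal(abs(row$log2_ratio - 3) < 1.5, TRUE)  # near planted effect
})

test_that("per-contrast BH adjustment matches the stepwise formula", {
  expect_equal(bf_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))  # hand case
  set.seed(3)
  gm <- matrix(rnorm(50 * 4, 5, 1), 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), cond_cols))
  em <- log2_design_matrix(gm, n_bio = 2, noise_sd = 0.5)
  de <- suppressWarnings(fit_anova(em))
  for (ct in unique(de$contrast)) {
    sub <- de[de$contrast == ct, ]
    expect_equal(sub$fdr_q, bf_bh(sub$p_value), tolerance = 1e-12)
    expect_true(all(sub$fdr_q >= sub$p_value - 1e-12))
  }
})

test_that("contrast arithmetic is closed: (A-B) + (B-C) = (A-C) exactly", {
  set.seed(4)
  gm <- matrix(rnorm(20 * 4, 6, 2), 20, 4,
               dimnames = list(sprintf("g%02d", 1:20), cond_cols))
  em <- log2_design_matrix(gm, n_bio = 2, noise_sd = 0.4)
  chain <- data.frame(
    name = c("ab", "bc", "ac"),
    left = c("populus_12h", "populus_37h", "populus_12h"),
    right = c("populus_37h", "switchgrass_12h", "switchgrass_12h"))
  de <- suppressWarnings(fit_anova(em, contrasts = chain))
  w <- reshape(de[, c("gene", "contrast", "log2_ratio")],
               idvar = "gene", timevar = "contrast", direction = "wide")
  expect_equal(w$log2_ratio.ab + w$log2_ratio.bc, w$log2_ratio.ac,
               tolerance = 1e-12)
})

test_that("threshold logic: significance and fold filters combine per contrast", {
  # 40 null genes cushion the BH adjustment around two planted effects
  gm <- matrix(5, 42, 4,
               dimnames = list(sprintf("g%02d", 1:42), cond_cols))
  gm["g01", "populus_12h"] <- 5.5  # significant but under the fold bar
  gm["g02", "populus_12h"] <- 9    # significant and >= 1 log2
  set.seed(5)
  em <- log2_design_matrix(gm, n_bio = 6, noise_sd = 0.1)
  de <- suppressWarnings(fit_anova(em))
  s <- call_differential(de)
  expect_true("g01" %in% s$genes_any_sig)
  expect_false("g01" %in% s$genes_sig_fold)
  expect_true("g02" %in% s$genes_sig_fold)
})

test_that("degenerate inputs are rejected or flagged", {
  gm <- matrix(5, 2, 4, dimnames = list(c("g1", "g2"), cond_cols))
  em1 <- log2_design_matrix(gm, n_bio = 1, noise_sd = 0.1)
  expect_error(fit_anova(em1), "fewer than 2")
  # zero pooled variance: p forced to 1 with a warning
  em0 <- log2_design_matrix(gm, n_bio = 2, noise_sd = 0)
  expect_warning(de <- fit_anova(em0), "zero pooled variance")
  expect_true(all(de$p_value == 1))
})

test_that("planted effects are recovered with correct signs and monotone power", {
  recov <- function(n_bio, lo, hi, seed) {
    cfg <- sim_config(n_genes = 600, n_bio = n_bio,
                      effect_log2_range = c(lo, hi), seed = seed)
    sim <- suppressMessages(simulate_experiment(cfg))
    de <- suppressWarnings(fit_anova(suppressMessages(
      normalize_kdmm(sim$counts))))
    list(de = de, truth = sim$truth)
  }
  r <- recov(5, 2, 4, 31)
  # sign agreement for called DE genes with large true effects
  eff <- r$truth$effects
  sub <- r$de[r$de$sig_flag & r$de$fold_flag, ]
  tru <- eff[cbind(match(sub$gene, rownames(eff)),
                   match(sub$contrast, colnames(eff)))]
  big <- abs(tru) >= 2
  expect_gt(mean(sign(sub$log2_ratio[big]) == sign(tru[big])), 0.99)

  # power is non-decreasing in effect size and in replication
  n_calls_eff <- sapply(list(c(0.3, 0.5), c(1, 1.5), c(2.5, 3)),
                        function(rg)
    call_differential(recov(3, rg[1], rg[2], 32)$de)$n_sig_fold)
  expect_true(all(diff(n_calls_eff) >= 0))
  n_calls_rep <- sapply(c(2, 4, 8), function(nb)
    call_differential(recov(nb, 1.5, 2, 33)$de)$n_sig_fold)
  expect_true(all(diff(n_calls_rep) >= 0))
})
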