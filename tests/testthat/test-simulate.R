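test_that("genotype simulation is deterministic and respects declared MAFs", {
  g1 <- simulate_genotypes(250, 80, seed = 42)
  g2 <- simulate_genotypes(250, 80, seed = 42)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)

  # empirical MAF within +-0.05 of declared at n >= 200
  expect_lt(max(abs(empirical_maf(g1$dosage) -
                      fold_maf(g1$variants$maf))), 0.05)
  # no monomorphic columns
  expect_true(all(apply(g1$dosage, 2, function(x) length(unique(x)) > 1)))
  # positions strictly increasing
  expect_true(all(diff(g1$variants$pos) > 0))
})

test_that("LD structure follows the block model", {
  # rho = 0: mean pairwise r2 within blocks stays at the null level
  g0 <- simulate_genotypes(1000, 60, ld_block_size = 6, ld_rho = 0, seed = 1)
  r2 <- function(g) {
    vals <- c()
    for (b in split(seq_len(60), rep(1:10, each = 6))) {
      cm <- cor(g$dosage[, b])^2
      vals <- c(vals, cm[upper.tri(cm)])
    }
    mean(vals)
  }
  expect_lte(r2(g0), 0.02)

  # blocks of one variant cannot correlate
  g1 <- simulate_genotypes(1000, 60, ld_block_size = 1, ld_rho = 0.9, seed = 1)
  adj <- mean(vapply(seq_len(59), function(j) {
    cor(g1$dosage[, j], g1$dosage[, j + 1])^2
  }, numeric(1)))
  expect_lte(adj, 0.02)

  # rho > 0 produces real dosage correlation inside blocks
  g2 <- simulate_genotypes(1000, 60, ld_block_size = 6, ld_rho = 0.8, seed = 1)
  expect_gt(r2(g2), 0.2)
})

test_that("degenerate and invalid genotype arguments are rejected", {
  expect_error(simulate_genotypes(10, 50), "at least 30")
  expect_error(simulate_genotypes(100, 50, maf_low = 0.01), "maf_low")
  expect_error(simulate_genotypes(100, 50, ld_rho = 1), "ld_rho")
  # maf fixed at 0.5: mean dosage ~ 1
  g <- simulate_genotypes(1000, 40, maf_low = 0.5, maf_high = 0.5, seed = 2)
  expect_lt(abs(mean(g$dosage) - 1), 0.05)
})

test_that("cascade truth composes layer slopes exactly", {
  tr <- cascade_truth(50, beta = 0.4, lambda_r = 0.6, lambda_p = 0.5,
                      gamma_r = 0.1, gamma_p = -0.2, seed = 7)
  expect_equal(tr$slope_ribo, rep(0.6 * 0.4 + 0.1, 50))
  expect_equal(tr$slope_protein, rep(0.5 * (0.6 * 0.4 + 0.1) - 0.2, 50))
  # identity attenuation reproduces identical slopes at all layers
  tr1 <- cascade_truth(10, beta = 0.3, lambda_r = 1, lambda_p = 1, seed = 7)
  expect_equal(tr1$slope_mrna, tr1$slope_ribo)
  expect_equal(tr1$slope_ribo, tr1$slope_protein)
  # full buffering erases downstream mRNA-derived signal
  tr0 <- cascade_truth(10, beta = 0.3, lambda_r = 0, lambda_p = 1, seed = 7)
  expect_equal(tr0$slope_ribo, rep(0, 10))
  expect_equal(tr0$slope_protein, rep(0, 10))
  expect_error(cascade_truth(10, lambda_r = 1.2), "\\[0, 1\\]")
})

test_that("noiseless identity cascade gives equal per-allele effects across layers", {
  g <- simulate_genotypes(400, 300, ld_block_size = 1, ld_rho = 0, seed = 5)
  tr <- cascade_truth(100, beta = 0.5, lambda_r = 1, lambda_p = 1,
                      noise_sd = 1e-3, factor_sd = 0, seed = 6)
  sim <- simulate_cascade(g, tr, nb_size = 1e5,
                          base_log2_range = c(10, 12), seed = 8)
  slope_at <- function(mat) {
    vapply(seq_len(100), function(i) {
      marginal_summary_stats(
        g$dosage[, sim$truth$variant_id[[i]], drop = FALSE], mat[, i]
      )$beta
    }, numeric(1))
  }
  s_m <- slope_at(counts_to_log_cpm(sim$mrna))
  s_r <- slope_at(counts_to_log_cpm(sim$ribo))
  s_p <- slope_at(sim$protein)
  expect_lt(median(abs(s_r / s_m - 1)), 0.02)
  expect_lt(median(abs(s_p / s_m - 1)), 0.02)
})

test_that("attenuation parameters are recovered by cross-layer regression", {
  g <- tiny_genotypes(n = 200, v = 250, seed = 9)
  tr <- cascade_truth(250, beta = 0.6, lambda_r = 0.75, lambda_p = 0.8,
                      noise_sd = c(0.4, 0.4, 0.4), seed = 7)
  sim <- simulate_cascade(g, tr, seed = 7)
  slope_at <- function(mat) {
    vapply(seq_len(250), function(i) {
      marginal_summary_stats(
        g$dosage[, sim$truth$variant_id[[i]], drop = FALSE], mat[, i]
      )$beta
    }, numeric(1))
  }
  s_m <- slope_at(counts_to_log_cpm(sim$mrna))
  s_r <- slope_at(counts_to_log_cpm(sim$ribo))
  s_p <- slope_at(sim$protein)
  # regression through the origin of downstream on upstream slopes
  expect_lt(abs(sum(s_r * s_m) / sum(s_m^2) - 0.75), 0.05)
  expect_lt(abs(sum(s_p * s_r) / sum(s_r^2) - 0.80), 0.05)
})

test_that("protein-only genetic effects make pQTL-positive eQTL-null genes", {
  g <- tiny_genotypes(n = 300, v = 20, seed = 12)
  tr <- cascade_truth(20, beta = 0, gamma_p = 0.8,
                      noise_sd = c(0.5, 0.5, 0.5), factor_sd = 0, seed = 13)
  sim <- simulate_cascade(g, tr, seed = 14)
  ps <- vapply(seq_len(20), function(i) {
    marginal_summary_stats(
      g$dosage[, sim$truth$variant_id[[i]], drop = FALSE], sim$protein[, i]
    )$pvalue
  }, numeric(1))
  ms <- vapply(seq_len(20), function(i) {
    marginal_summary_stats(
      g$dosage[, sim$truth$variant_id[[i]], drop = FALSE],
      counts_to_log_cpm(sim$mrna)[, i]
    )$pvalue
  }, numeric(1))
  expect_true(all(ps < 1e-4))       # strong pQTLs by construction
  expect_gt(mean(ms > 0.05), 0.8)   # eQTL-null
})

test_that("GWAS summary statistics obey their internal identities", {
  g <- tiny_genotypes(n = 100, v = 60, seed = 15)
  tr <- cascade_truth(10, beta = 0.5, causal_for_outcome = c(TRUE, rep(FALSE, 9)),
                      seed = 16)
  sim <- simulate_cascade(g, tr, seed = 17)
  gw <- simulate_gwas(g, sim$truth, outcome_h2 = 0.3, n_gwas = 800, seed = 18)
  expect_equal(gw$zscore, gw$beta / gw$se, tolerance = 1e-9)
  expect_equal(gw$pvalue, 2 * pnorm(-abs(gw$zscore)), tolerance = 1e-9)
  expect_true(all(gw$n == 800))
  expect_error(simulate_gwas(g, sim$truth, outcome_h2 = 1.2), "outcome_h2")
  tr_null <- cascade_truth(10, beta = 0.5, seed = 16)
  sim_null <- simulate_cascade(g, tr_null, seed = 17)
  expect_error(simulate_gwas(g, sim_null$truth, 0.3, 500, 1), "causal_for_outcome")
})

test_that("null GWAS is calibrated and causal-gene GWAS peaks at the causal cis variant", {
  g <- simulate_genotypes(60, 400, ld_block_size = 8, ld_rho = 0.5, seed = 19)
  # calibration: flagged causal gene with a zero protein slope leaves the
  # liability pure environmental noise
  tr0 <- cascade_truth(40, beta = 0.4,
                       causal_for_outcome = c(TRUE, rep(FALSE, 39)), seed = 20)
  tr0$slope_protein <- rep(0, 40)
  gw0 <- simulate_gwas(g, within(tr0, variant_id <- sprintf("v%05d", 1:40)),
                       outcome_h2 = 0.5, n_gwas = 4000, seed = 21)
  expect_lt(abs(mean(gw0$pvalue < 0.05) - 0.05), 0.02)

  # single causal gene: lead GWAS variant lies in its LD block
  tr1 <- cascade_truth(40, beta = 0.6,
                       causal_for_outcome = c(TRUE, rep(FALSE, 39)), seed = 11)
  sim1 <- simulate_cascade(g, tr1, seed = 11)
  gw1 <- simulate_gwas(g, sim1$truth, outcome_h2 = 0.3, n_gwas = 5000, seed = 11)
  lead <- gw1$variant_id[[which.min(gw1$pvalue)]]
  causal <- sim1$truth$variant_id[[1]]
  expect_gt(abs(cor(g$dosage[, lead], g$dosage[, causal])), 0.5)

  # pure pleiotropy: GWAS hit at a variant that is no gene's cis signal
  tr2 <- cascade_truth(40, beta = 0,
                       pleiotropy_effect = c(rep(0, 39), 0.5), seed = 22)
  sim2 <- simulate_cascade(g, tr2, seed = 23)
  gw2 <- simulate_gwas(g, sim2$truth, outcome_h2 = 0.2, n_gwas = 5000, seed = 24)
  pleio_variant <- sim2$truth$variant_id[[40]]
  expect_lt(gw2$pvalue[gw2$variant_id == pleio_variant], 1e-6)
})
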