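test_that("elastic-net models learn real cis signal and reject noise", {
  g <- tiny_genotypes(n = 200, v = 60, seed = 41)
  win <- whole_window(g)
  set.seed(41)
  y <- 0.8 * g$dosage[, 10] + rnorm(200, sd = 0.6)
  y <- drop(scale(y))
  m <- train_prediction_model(win, g, y, seed = 41)
  expect_true(m$retained)
  expect_gt(m$r_cv, 0.5)
  # the heaviest weight sits in the causal variant's LD block (blocks of 6)
  top <- names(which.max(abs(m$weights)))
  top_idx <- match(top, g$variants$variant_id)
  expect_equal(ceiling(top_idx / 6), ceiling(10 / 6))

  # single causal variant, no LD, noiseless
  g2 <- simulate_genotypes(100, 3, ld_block_size = 1, ld_rho = 0, seed = 42)
  y2 <- drop(scale(g2$dosage[, 2]))
  m2 <- train_prediction_model(whole_window(g2), g2, y2, seed = 42)
  expect_gt(m2$r_cv, 0.99)

  # fewer than 2 cis variants: no model
  g3 <- simulate_genotypes(50, 1, ld_block_size = 1, ld_rho = 0, seed = 43)
  expect_message(m3 <- train_prediction_model(whole_window(g3), g3, rnorm(50)),
                 "fewer than 2")
  expect_null(m3)
})

test_that("pure-noise genes pass the joint retention rule rarely", {
  g <- tiny_genotypes(n = 185, v = 40, seed = 43)
  win <- whole_window(g)
  set.seed(43)
  retained <- vapply(1:120, function(i) {
    m <- train_prediction_model(win, g, rnorm(185), seed = 5000 + i)
    m$retained
  }, logical(1))
  expect_lte(mean(retained), 0.07)
})

test_that("imputation follows the linear model and checks variants", {
  g <- tiny_genotypes(n = 80, v = 10, seed = 44)
  mod <- structure(list(gene_id = "g", layer = "mrna",
                        weights = c(v00003 = 1), intercept = 2,
                        retained = TRUE, conditional = FALSE),
                   class = "prediction_model")
  expect_equal(unname(impute_expression(mod, g)),
               unname(g$dosage[, "v00003"] + 2))
  mod0 <- mod; mod0$weights <- numeric(0)
  expect_equal(unname(impute_expression(mod0, g)), rep(2, 80))
  modm <- mod; names(modm$weights) <- "vMISSING"
  expect_error(impute_expression(modm, g), "vMISSING")
})

test_that("in-sample imputation fit is at least the out-of-fold r_cv", {
  g <- tiny_genotypes(n = 200, v = 40, seed = 45)
  win <- whole_window(g)
  set.seed(45)
  y <- drop(scale(0.6 * g$dosage[, 7] + rnorm(200, sd = 0.8)))
  m <- train_prediction_model(win, g, y, seed = 45)
  r_in <- cor(impute_expression(m, g), y)
  expect_gte(r_in, m$r_cv - 0.02)
})

test_that("conditional residualization is orthogonal to its regressors", {
  set.seed(46)
  e_k <- rnorm(100)
  other1 <- 0.5 * e_k + rnorm(100)
  other2 <- rnorm(100)
  ce <- conditional_residualize(e_k, list(other1, other2))
  expect_lt(abs(cor(ce$residual, other1)), 1e-8)
  expect_lt(abs(cor(ce$residual, other2)), 1e-8)
  expect_equal(ce$reconstructed, mean(e_k) + ce$residual)

  # focal expression exactly equal to a regressor: residual ~ 0
  ce2 <- conditional_residualize(other1, list(other1))
  expect_lt(sd(ce2$residual), 1e-10)

  # orthogonal regressor leaves the expression intact up to centering
  orth <- rnorm(100)
  orth <- orth - mean(orth)
  eko <- e_k - drop(cor(e_k, orth)) * orth * sd(e_k) / sd(orth)  # de-correlate
  ce3 <- conditional_residualize(eko, list(orth))
  expect_gt(cor(ce3$reconstructed, eko), 0.999)

  # collinear regressors: later one dropped with warning
  expect_warning(ce4 <- conditional_residualize(e_k, list(other1, other1 * 2)),
                 "collinear")
  expect_length(ce4$slopes, 1)
})

test_that("rc2 contrasts shared against specific genetic architecture", {
  g <- tiny_genotypes(n = 80, v = 10, seed = 47)
  mk <- function(w) structure(list(gene_id = "g", layer = "mrna", weights = w,
                                   intercept = 0, retained = TRUE,
                                   conditional = FALSE),
                              class = "prediction_model")
  m1 <- mk(c(v00002 = 0.5))
  expect_equal(compute_rc2(m1, m1, g)$rc2, 1)
  m0 <- mk(numeric(0))  # constant imputation
  rc <- compute_rc2(m1, m0, g)
  expect_equal(rc$rc2, 0)
  expect_true(rc$degenerate)
})

test_that("two independent cis signals, one shared, give intermediate rc2", {
  # gene with two causal variants of equal variance; the conditional model
  # keeps only the gene-specific one, so rc2 ~ 0.5
  set.seed(47)
  reps <- purrr::map_dbl(1:12, function(i) {
    g <- simulate_genotypes(300, 40, ld_block_size = 1, ld_rho = 0,
                            seed = 470 + i)
    v1 <- drop(scale(g$dosage[, 5]))   # shared with the other layer
    v2 <- drop(scale(g$dosage, center = TRUE)[, 25]) # focal-specific
    v2 <- drop(scale(g$dosage[, 25]))
    y <- drop(scale(v1 + v2 + rnorm(300, sd = 0.4)))
    other_imputed <- v1
    win <- whole_window(g)
    orig <- train_prediction_model(win, g, y, seed = 470 + i)
    ce <- conditional_residualize(y, list(other_imputed))
    idx <- cascadeQTL:::cis_variant_idx(g, win)
    x <- g$dosage[, idx, drop = FALSE]
    cond <- cascadeQTL:::fit_enet_model(x, ce$reconstructed, "g", "mrna",
                                        seed = 471 + i, conditional = TRUE)
    compute_rc2(orig, cond, g)$rc2
  })
  expect_lt(abs(median(reps) - 0.5), 0.15)
})

test_that("permutation null calibration: independent layers uniform, shared layers extreme", {
  g <- tiny_genotypes(n = 150, v = 30, seed = 53)
  win <- whole_window(g)
  idx <- cascadeQTL:::cis_variant_idx(g, win)
  x <- g$dosage[, idx, drop = FALSE]
  set.seed(53)

  # independent: focal gene has its own signal; "other layer" imputation is
  # driven by different variants -> empirical p should be non-extreme
  p_indep <- purrr::map_dbl(1:30, function(i) {
    y <- drop(scale(0.7 * g$dosage[, 3 + (i %% 10)] + rnorm(150, sd = 0.8)))
    # an unrelated gene's genetic imputation: genotype-like but independent
    # of every variant in this gene's cis set
    other <- drop(scale(rbinom(150, 2, 0.3)))
    orig <- train_prediction_model(win, g, y, seed = 530 + i)
    if (!orig$retained) return(NA_real_)
    ce <- conditional_residualize(y, list(other))
    cond <- cascadeQTL:::fit_enet_model(x, ce$reconstructed, "g", "mrna",
                                        seed = 531 + i, conditional = TRUE)
    rc <- compute_rc2(orig, cond, g)
    permutation_null_rc2(x, y, list(other), impute_expression(orig, g),
                         rc$rc2, n_perm = 50, seed = 532 + i)$empirical_p
  })
  p_indep <- p_indep[!is.na(p_indep)]
  # no sharing: small p (evidence of sharing) must be rare
  expect_lt(mean(p_indep <= 1 / 51), 0.2)

  # fully shared: the other layer's imputation IS the focal genetic signal
  p_shared <- purrr::map_dbl(1:15, function(i) {
    v <- g$dosage[, 5 + (i %% 10)]
    y <- drop(scale(0.9 * v + rnorm(150, sd = 0.5)))
    other <- drop(scale(v))
    orig <- train_prediction_model(win, g, y, seed = 560 + i)
    if (!orig$retained) return(NA_real_)
    ce <- conditional_residualize(y, list(other))
    cond <- cascadeQTL:::fit_enet_model(x, ce$reconstructed, "g", "mrna",
                                        seed = 561 + i, conditional = TRUE)
    rc <- compute_rc2(orig, cond, g)
    permutation_null_rc2(x, y, list(other), impute_expression(orig, g),
                         rc$rc2, n_perm = 50, seed = 562 + i)$empirical_p
  })
  p_shared <- p_shared[!is.na(p_shared)]
  expect_gte(mean(p_shared <= 1 / 51), 0.8)
  # minimum attainable p with 50 permutations
  expect_gte(min(p_shared), 1 / 51 - 1e-12)
})

test_that("classification rule matches the FDR/rc2 regions", {
  expect_equal(classify_gene(0.05, 0.3), "shared")
  expect_equal(classify_gene(0.5, 0.95), "specific")
  expect_equal(classify_gene(0.05, 0.95), "unclassified")
  expect_equal(classify_gene(0.5, 0.3), "unclassified")
  expect_equal(classify_gene(NA, 0.3), "unclassified")
  expect_equal(
    classify_gene(c(0.01, 0.9), c(0.1, 0.99)),
    c("shared", "specific")
  )
})

test_that("the end-to-end specificity caller labels shared and protein-specific genes", {
  # 12 genes: half fully shared across layers, half protein-specific
  g <- tiny_genotypes(n = 185, v = 72, seed = 57)
  shared_flag <- rep(c(TRUE, FALSE), each = 6)
  tr <- cascade_truth(12,
                      beta = ifelse(shared_flag, 0.7, 0),
                      lambda_r = 1, lambda_p = 1,
                      gamma_p = ifelse(shared_flag, 0, 0.7),
                      noise_sd = c(0.7, 0.7, 0.7), factor_sd = 0, seed = 57)
  sim <- simulate_cascade(g, tr, base_log2_range = c(10, 11), seed = 58)
  layers <- purrr::map(
    list(mrna = counts_to_log_cpm(sim$mrna), ribo = counts_to_log_cpm(sim$ribo),
         protein = sim$protein),
    residualize
  )
  res <- suppressMessages(suppressWarnings(
    call_specificity(layers, g, sim$annotation, n_perm = 30, seed = 59)
  ))
  expect_true(all(c("gene_id", "layer", "rc2", "empirical_p", "fdr", "label")
                  %in% names(res)))
  prot_spec <- res[res$layer == "protein" &
                     res$gene_id %in% tr$gene_id[!shared_flag], ]
  if (nrow(prot_spec) > 0) {
    expect_gt(mean(prot_spec$rc2 > 0.9), 0.5)
  }
  shared_rows <- res[res$gene_id %in% tr$gene_id[shared_flag], ]
  if (nrow(shared_rows) > 0) {
    expect_gt(mean(shared_rows$rc2 < 0.5), 0.5)
  }
})
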