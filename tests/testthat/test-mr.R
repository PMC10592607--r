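test_that("LD clumping keeps index variants and matches a brute-force oracle", {
  # perfect LD: one instrument survives
  g <- tiny_genotypes(n = 100, v = 10, seed = 81)
  for (j in 2:10) g$dosage[, j] <- g$dosage[, 1]
  stats <- tibble::tibble(variant_id = g$variants$variant_id,
                          pvalue = seq(0.001, 0.01, length.out = 10))
  expect_equal(nrow(ld_clump(stats, g, r2_max = 0.5)), 1)
  expect_equal(ld_clump(stats, g)$variant_id, "v00001")

  # mutually independent variants all below threshold are all retained
  g2 <- simulate_genotypes(500, 12, ld_block_size = 1, ld_rho = 0, seed = 82)
  stats2 <- tibble::tibble(variant_id = g2$variants$variant_id, pvalue = 0.01)
  expect_equal(nrow(ld_clump(stats2, g2, r2_max = 0.2)), 12)

  # nothing passes the threshold
  expect_equal(nrow(ld_clump(stats2, g2, p_threshold = 0.001)), 0)

  # 20-variant toy against an independently coded greedy oracle
  g3 <- simulate_genotypes(300, 20, ld_block_size = 4, ld_rho = 0.8, seed = 83)
  set.seed(83)
  stats3 <- tibble::tibble(variant_id = g3$variants$variant_id,
                           pvalue = runif(20, 0, 0.04))
  r2m <- cor(g3$dosage)^2
  pos <- g3$variants$pos
  oracle <- character()
  cand <- order(stats3$pvalue)
  alive <- rep(TRUE, 20)
  while (any(alive[cand])) {
    i <- cand[alive[cand]][1]
    oracle <- c(oracle, stats3$variant_id[i])
    drop_set <- which(alive & abs(pos - pos[i]) <= 1000 * 1000 & r2m[i, ] > 0.5)
    alive[c(i, drop_set)] <- FALSE
  }
  expect_identical(ld_clump(stats3, g3, r2_max = 0.5)$variant_id, oracle)
})

test_that("harmonization flips swapped alleles and drops palindromic/incompatible variants", {
  expo <- tibble::tibble(variant_id = c("a", "b", "c", "d"),
                         effect_allele = c("A", "A", "A", "C"),
                         other_allele = c("G", "G", "C", "G"),
                         beta = c(0.3, 0.3, 0.3, 0.3), se = 0.1)
  outc <- tibble::tibble(variant_id = c("a", "b", "c", "d"),
                         effect_allele = c("G", "A", "A", "C"),
                         other_allele = c("A", "C", "C", "G"),
                         beta = c(-0.2, 0.1, 0.2, 0.4), se = 0.1)
  h <- suppressMessages(harmonize(expo, outc))
  # a: swapped -> flipped; b: incompatible -> dropped; c: same -> kept;
  # d: palindromic C/G -> dropped
  expect_identical(h$variant_id, c("a", "c"))
  expect_equal(h$beta_out, c(0.2, 0.2))
})

test_that("IVW matches its weighted-least-squares closed form and recovers causal effects", {
  # 5-instrument toy, closed form computed independently
  set.seed(67)
  inst <- tibble::tibble(beta_exp = c(0.2, 0.5, -0.3, 0.4, 0.25),
                         se_exp = 0.05,
                         beta_out = c(0.07, 0.14, -0.10, 0.11, 0.08),
                         se_out = c(0.02, 0.03, 0.025, 0.04, 0.02))
  w <- 1 / inst$se_out^2
  est_cf <- sum(w * inst$beta_exp * inst$beta_out) / sum(w * inst$beta_exp^2)
  se_cf <- sqrt(1 / sum(w * inst$beta_exp^2))
  r <- mr_ivw(inst)
  expect_equal(r$estimate, est_cf, tolerance = 1e-10)
  expect_equal(r$se, se_cf, tolerance = 1e-10)

  # single instrument: Wald ratio
  r1 <- mr_ivw(inst[1, ])
  expect_equal(r1$estimate, 0.07 / 0.2, tolerance = 1e-12)
  expect_true(r1$single_instrument)

  # simulation: outcome = 0.3 * exposure across 20 instruments
  bx <- rnorm(20, 0, 0.3)
  by <- 0.3 * bx + rnorm(20, sd = 0.02)
  sim_inst <- tibble::tibble(beta_exp = bx, se_exp = 0.03,
                             beta_out = by, se_out = 0.02)
  expect_lt(abs(mr_ivw(sim_inst)$estimate - 0.3), 0.05)
})

test_that("Egger regression measures directional pleiotropy through its intercept", {
  set.seed(71)
  bx <- abs(rnorm(20, 0.4, 0.15))
  # pure intercept: outcome = 0.1 regardless of exposure
  inst <- tibble::tibble(beta_exp = bx, se_exp = 0.03,
                         beta_out = 0.1 + rnorm(20, sd = 0.01), se_out = 0.02)
  e <- mr_egger(inst)
  expect_lt(abs(e$intercept - 0.1), 0.02)
  expect_lt(abs(e$estimate), 0.05)
  expect_lt(e$intercept_p, 0.01)

  # type-I error of the intercept test under no pleiotropy
  rej <- vapply(1:150, function(i) {
    bx <- rnorm(20, 0, 0.3)
    by <- 0.25 * bx + rnorm(20, sd = 0.02)
    mr_egger(tibble::tibble(beta_exp = bx, se_exp = 0.03,
                            beta_out = by, se_out = 0.02))$intercept_p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.08)

  # directional pleiotropy on the 30% weakest of 20 instruments is
  # detected > 50% of the time (exponential exposure effects)
  set.seed(73)
  pow <- vapply(1:80, function(i) {
    bx <- rexp(20, rate = 1 / 0.3)
    pleio <- numeric(20)
    pleio[order(bx)[1:6]] <- 0.3
    by <- 0.25 * bx + pleio + rnorm(20, sd = 0.02)
    mr_egger(tibble::tibble(beta_exp = bx, se_exp = 0.03,
                            beta_out = by, se_out = 0.02))$intercept_p < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.5)

  expect_message(e2 <- mr_egger(inst[1:2, ]), "fewer than 3")
  expect_true(is.na(e2$estimate))
})

test_that("verdicts follow the FDR and intercept rules", {
  expect_equal(two_sample_verdict(0.05, 0.5), "pass")
  expect_equal(two_sample_verdict(0.05, 0.01), "fail_pleiotropy")
  expect_equal(two_sample_verdict(0.5, 0.5), "fail_effect")
  expect_equal(two_sample_verdict(NA, 0.5), "untested")
  expect_equal(cascade_classify(TRUE, TRUE), "both-passed")
  expect_equal(cascade_classify(TRUE, FALSE), "single-passed")
  expect_equal(cascade_classify(FALSE, FALSE), "none-passed")
  expect_equal(cascade_classify(NA, TRUE), "single-passed")
})

test_that("2SLS matches explicit two-stage matrix algebra and is exact on noiseless chains", {
  # noiseless chain: outcome = 2 * exposure, exposure = G
  g <- tiny_genotypes(n = 50, v = 3, seed = 85)
  x <- g$dosage[, 1]
  y <- 2 * x
  r <- tsls(x, y, g$dosage[, 1, drop = FALSE])
  expect_equal(r$estimate, 2, tolerance = 1e-10)

  # 50-sample toy vs hand-rolled matrix algebra
  set.seed(86)
  Z <- matrix(rbinom(150, 2, 0.3), 50, 3)
  xe <- drop(Z %*% c(0.4, 0.2, -0.3)) + rnorm(50)
  ye <- 0.7 * xe + rnorm(50)
  fit <- tsls(xe, ye, Z)
  Zi <- cbind(1, Z)
  xhat <- Zi %*% solve(crossprod(Zi), crossprod(Zi, xe))
  W <- cbind(1, xhat)
  b <- solve(crossprod(W), crossprod(W, ye))
  u <- ye - cbind(1, xe) %*% b
  vcv <- drop(crossprod(u)) / (50 - 2) * solve(crossprod(W))
  expect_equal(fit$estimate, b[[2]], tolerance = 1e-10)
  expect_equal(fit$se, sqrt(vcv[2, 2]), tolerance = 1e-10)

  # confounded exposure-outcome: 2SLS debiases, naive OLS does not
  # (averaged over 5 replicates to separate bias from estimator noise)
  reps <- purrr::map_dfr(1:5, function(r) {
    g2 <- simulate_genotypes(500, 8, ld_block_size = 1, ld_rho = 0,
                             seed = 79 + r)
    set.seed(790 + r)
    conf <- rnorm(500)
    xc <- drop(g2$dosage %*% rep(0.5, 8)) + 0.5 * conf + rnorm(500, sd = 0.8)
    yc <- 0.3 * xc + 0.5 * conf + rnorm(500)
    fit <- tsls(xc, yc, g2$dosage)
    tibble::tibble(est = fit$estimate, naive = coef(lm(yc ~ xc))[[2]],
                   f = fit$f_statistic, weak = fit$weak_instruments)
  })
  expect_lt(abs(mean(reps$est) - 0.3), 0.07)
  expect_gt(mean(reps$naive), 0.36)
  expect_true(all(reps$f > 10))
  expect_false(any(reps$weak))

  # collinear instruments dropped with warning
  Zc <- cbind(Z, Z[, 1])
  expect_warning(tsls(xe, ye, Zc), "collinear")
  expect_error(tsls(xe[1:4], ye[1:4], Z[1:4, ]), "n >")
})

test_that("two-sample MR pipeline passes causal genes and flags pleiotropy", {
  g <- simulate_genotypes(185, 120, ld_block_size = 6, ld_rho = 0.6,
                          pos_spacing = c(20000, 60000), seed = 87)
  tr <- cascade_truth(10, beta = 0.6, lambda_r = 1, lambda_p = 1,
                      causal_for_outcome = rep(c(TRUE, FALSE), 5),
                      factor_sd = 0, seed = 87)
  sim <- simulate_cascade(g, tr, base_log2_range = c(10, 11), seed = 88)
  gw <- simulate_gwas(g, sim$truth, outcome_h2 = 0.25, n_gwas = 20000, seed = 89)
  mrna <- residualize(counts_to_log_cpm(sim$mrna))
  wins <- cis_windows(sim$annotation)
  expo <- purrr::map_dfr(1:10, function(i) {
    sc <- nominal_scan(wins[i, ], g, mrna[, i])
    va <- g$variants[match(sc$variant_id, g$variants$variant_id), ]
    dplyr::mutate(sc, gene_id = tr$gene_id[[i]], layer = "mrna",
                  effect_allele = va$alt, other_allele = va$ref,
                  beta = .data$slope)
  })
  res <- suppressMessages(mr_two_sample(expo, gw, g))
  expect_s3_class(res, "mr_result")
  causal <- res$verdict[res$gene_id %in% tr$gene_id[tr$causal_for_outcome]]
  noncausal <- res$verdict[res$gene_id %in% tr$gene_id[!tr$causal_for_outcome]]
  expect_gte(mean(causal == "pass"), 0.6)
  expect_lte(mean(noncausal == "pass"), 0.4)
})

test_that("one-sample MR cascade classifies full, attenuated and specific architectures", {
  g <- simulate_genotypes(185, 90, ld_block_size = 6, ld_rho = 0.6, seed = 91)
  # 5 full-cascade genes, 5 protein-buffered, 5 protein-specific
  tr <- cascade_truth(15,
                      beta = c(rep(0.8, 10), rep(0, 5)),
                      lambda_r = 1,
                      lambda_p = rep(c(1, 0, 1), each = 5),
                      gamma_p = rep(c(0, 0, 0.8), each = 5),
                      noise_sd = c(0.6, 0.6, 0.6), factor_sd = 0, seed = 91)
  sim <- simulate_cascade(g, tr, base_log2_range = c(10, 11), seed = 92)
  layers <- purrr::map(
    list(mrna = counts_to_log_cpm(sim$mrna), ribo = counts_to_log_cpm(sim$ribo),
         protein = sim$protein),
    residualize
  )
  res <- suppressMessages(mr_one_sample(layers, g, sim$annotation))
  v <- res$verdicts
  full <- v$class[v$gene_id %in% tr$gene_id[1:5]]
  buffered <- v$class[v$gene_id %in% tr$gene_id[6:10]]
  expect_gte(mean(full == "both-passed"), 0.6)
  expect_gte(mean(buffered == "single-passed"), 0.6)
  expect_true(all(c("upstream_pass", "downstream_pass", "class") %in% names(v)))
})
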