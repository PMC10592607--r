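#' Property checks on reference synthetic cohorts
#'
#' Each `check_*` function simulates its study condition from scratch,
#' runs the relevant pipeline stages, and returns the measured quantities
#' as a named list of numbers. They are the package's reference
#' experiments: the test suite asserts on their outputs and
#' `scripts/acceptance.R` reports them.
#'
#' @name property-checks
#' @keywords internal
NULL

# one preprocessed cohort drawn from a fixed truth
.cohort <- function(truth, n_samples, n_variants, seed) {
  g <- simulate_genotypes(n_samples, n_variants, ld_block_size = 10,
                          ld_rho = 0.7, seed = derive_seed(seed, 1L))
  sim <- simulate_cascade(g, truth, seed = derive_seed(seed, 2L))
  list(g = g, sim = sim)
}

.residual_log2 <- function(x, n_factors = 5) {
  # factor-adjusted but NOT rescaled: keeps per-allele log2 units
  fs <- estimate_hidden_factors(x, n_factors)
  vals <- lm.fit(cbind(1, fs$factors), unclass(x))$residuals
  dimnames(vals) <- dimnames(x)
  omics_matrix(vals, layer = om_layer(x), stage = "residualized")
}

#' Attenuation-ratio recovery and pi1 replication asymmetry
#'
#' Simulates a 500-gene truth with mean attenuation 0.75 (ribo) and 0.8
#' (protein); draws `n_cohorts` independent n=200 cohorts plus one larger
#' external cohort in which eQTLs are discovered independently
#' (CMC-style); measures the external-list effect profile (sign-oriented
#' layer means on factor-adjusted log2 data, pooled across cohorts) and
#' the cross-layer pi1 replication matrix (replication p-values pooled
#' across cohorts).
#'
#' @param seed Master seed.
#' @param n_genes,n_samples,n_cohorts Study condition sizes.
#' @param n_perm Permutations per gene for the QTL mapping.
#' @return Named list: lambda_r_hat, lambda_p_hat, t-test p-values, pi1
#'   entries and the replication asymmetry.
#' @export
check_attenuation <- function(seed = 1L, n_genes = 500, n_samples = 200,
                              n_cohorts = 4, n_perm = 150) {
  truth <- cascade_truth(n_genes, seed = derive_seed(seed, 10L))
  n_var <- 600

  # external discovery cohort (larger, independent)
  gx <- simulate_genotypes(600, n_var, ld_block_size = 10, ld_rho = 0.7,
                           seed = derive_seed(seed, 11L))
  simx <- simulate_cascade(gx, truth, seed = derive_seed(seed, 12L))
  mx <- suppressWarnings(residualize(quantile_normalize(
    filter_low_expression(counts_to_log_cpm(simx$mrna)))))
  wins <- cis_windows(simx$annotation)
  ext <- purrr::map_dfr(truth$gene_id, function(gg) {
    sc <- nominal_scan(wins[wins$gene_id == gg, ], gx, mx[, gg])
    sc <- sc[which.min(sc$pvalue), ]
    if (nrow(sc) == 1 && sc$pvalue < 1e-4) {
      tibble::tibble(gene_id = gg, variant_id = sc$variant_id,
                     discovery_slope = sc$slope)
    } else NULL
  })

  eff_pool <- list(); pvec <- list()
  for (k in seq_len(n_cohorts)) {
    # each cohort contributes one paired profile; effects pool across cohorts
    co <- .cohort(truth, n_samples, n_var, derive_seed(seed, 20L + k))
    adj <- list(
      mrna = .residual_log2(filter_low_expression(counts_to_log_cpm(co$sim$mrna))),
      ribo = .residual_log2(filter_low_expression(counts_to_log_cpm(co$sim$ribo))),
      protein = .residual_log2(filter_low_expression(co$sim$protein))
    )
    ep <- suppressMessages(external_effect_profile(ext, adj, co$g))
    eff_pool[[k]] <- dplyr::mutate(ep$effects, cohort = k)

    layers <- suppressWarnings(purrr::map(
      list(mrna = co$sim$mrna, ribo = co$sim$ribo, protein = co$sim$protein),
      function(m) preprocess_layer(m, n_factors = 5)$matrix
    ))
    common <- Reduce(intersect, purrr::map(layers, rownames))
    layers <- purrr::map(layers, function(m) {
      omics_matrix(unclass(m)[common, , drop = FALSE], om_layer(m), om_stage(m))
    })
    gq <- subset_samples(co$g, common)
    qtl <- suppressWarnings(map_cis_qtls(layers, gq, co$sim$annotation,
                                         n_perm = n_perm,
                                         seed = derive_seed(seed, 30L + k)))
    for (d in c("mrna", "ribo")) {
      disc <- qtl[qtl$layer == d & qtl$significant, ]
      for (r in setdiff(c("mrna", "ribo", "protein"), d)) {
        key <- paste(d, r, sep = "->")
        st <- lead_variant_stats(disc, layers[[r]], gq)
        pvec[[key]] <- c(pvec[[key]], st$pvalue)
      }
    }
  }

  pooled <- dplyr::bind_rows(eff_pool)
  om <- pooled |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(m = mean(.data$oriented_effect), .groups = "drop")
  mget_l <- function(l) om$m[om$layer == l]
  wide <- tidyr::pivot_wider(
    dplyr::mutate(pooled, id = paste(.data$cohort, .data$pair_id)),
    id_cols = "id", names_from = "layer", values_from = "oriented_effect"
  )
  tt_p <- function(a, b) t.test(wide[[a]], wide[[b]], paired = TRUE)$p.value
  pi1 <- purrr::map_dbl(pvec, function(p) 1 - storey_pi0(p))
  list(
    lambda_r_hat = mget_l("ribo") / mget_l("mrna"),
    lambda_p_hat = mget_l("protein") / mget_l("ribo"),
    ttest_p_mrna_ribo = tt_p("mrna", "ribo"),
    ttest_p_ribo_protein = tt_p("ribo", "protein"),
    n_external = nrow(ext),
    pi1_e_to_r = unname(pi1[["mrna->ribo"]]),
    pi1_r_to_e = unname(pi1[["ribo->mrna"]]),
    pi1_e_to_p = unname(pi1[["mrna->protein"]]),
    replication_asymmetry = unname(pi1[["ribo->mrna"]] - pi1[["mrna->ribo"]])
  )
}

#' Calibration of the permutation QTL mapper and FDR control
#'
#' (a) 500 null genes at n_perm = 1000: uniformity of the empirical
#' p-values (KS test), Spearman agreement between the Beta-approximated
#' and direct-rank p-values, and their mean absolute difference.
#' (b) 20 replicates of a mixed cohort (half strong signal, half null):
#' realized false discovery proportion among q < 0.1 calls.
#'
#' @param seed Master seed.
#' @param n_null Null genes for the calibration arm.
#' @param n_perm Permutations for the calibration arm.
#' @param n_reps,genes_per_rep,n_perm_fdp FDP-arm sizes.
#' @return Named list: ks_p, spearman_beta_vs_rank, mean_abs_diff,
#'   mean_fdp.
#' @export
check_qtl_calibration <- function(seed = 1L, n_null = 500, n_perm = 1000,
                                  n_reps = 20, genes_per_rep = 120,
                                  n_perm_fdp = 300) {
  g <- simulate_genotypes(200, 40, ld_block_size = 10, ld_rho = 0.7,
                          seed = derive_seed(seed, 41L))
  win <- tibble::tibble(gene_id = "null", chrom = g$variants$chrom[[1]],
                        start = 1, end = max(g$variants$pos) + 1)
  set.seed(derive_seed(seed, 42L))
  res <- purrr::map_dfr(seq_len(n_null), function(i) {
    permutation_pass(win, g, rnorm(nrow(g$dosage)), n_perm = n_perm,
                     seed = derive_seed(seed, 1000L + i))
  })
  ks_p <- ks.test(res$empirical_p, "punif")$p.value
  rho <- cor(res$empirical_p, res$rank_p, method = "spearman")
  mad_ <- mean(abs(res$empirical_p - res$rank_p))

  fdp <- purrr::map_dbl(seq_len(n_reps), function(r) {
    gs <- simulate_genotypes(185, genes_per_rep, ld_block_size = 6,
                             ld_rho = 0.7, seed = derive_seed(seed, 60L + r))
    is_null <- rep(c(FALSE, TRUE), length.out = genes_per_rep)
    tr <- cascade_truth(genes_per_rep, beta = ifelse(is_null, 0, 0.5),
                        lambda_r = 1, lambda_p = 1,
                        seed = derive_seed(seed, 80L + r))
    sm <- simulate_cascade(gs, tr, seed = derive_seed(seed, 100L + r))
    lay <- suppressWarnings(preprocess_layer(sm$mrna, n_factors = 5)$matrix)
    gs <- subset_samples(gs, rownames(lay))
    q <- suppressWarnings(map_cis_qtls(list(mrna = lay), gs, sm$annotation,
                                       n_perm = n_perm_fdp, fdr = 0.1,
                                       seed = derive_seed(seed, 120L + r)))
    called <- q$gene_id[q$significant]
    if (length(called) == 0) return(0)
    mean(called %in% tr$gene_id[is_null])
  })
  list(ks_p = ks_p, spearman_beta_vs_rank = rho, mean_abs_diff = mad_,
       mean_fdp = mean(fdp))
}

#' Specificity classifier error rates
#'
#' (a) A fully shared cohort (strong cis effects propagating unattenuated
#' to all layers): fraction of analysed gene-layer pairs labeled
#' "specific" (false-specificity rate). (b) A protein-specific
#' construction: genes with an mRNA eQTL fully buffered before protein
#' plus an independent protein-only cis effect (marginal R^2 0.2) at a
#' different variant; fraction of analysed protein rows recovered as
#' "specific".
#'
#' @param seed Master seed.
#' @param n_shared,n_specific Gene counts for the two arms.
#' @param n_samples Cohort size.
#' @param n_perm rc2 permutations.
#' @return Named list: false_specific_rate, protein_specific_recovery,
#'   n_shared_tested, n_specific_tested.
#' @export
check_specificity <- function(seed = 1L, n_shared = 200, n_specific = 60,
                              n_samples = 185, n_perm = 50) {
  run_arm <- function(truth, n_var, gamma_offset, sd_seed) {
    g <- simulate_genotypes(n_samples, n_var, ld_block_size = 6, ld_rho = 0.7,
                            pos_spacing = c(20000, 100000),
                            seed = derive_seed(seed, sd_seed))
    sim <- simulate_cascade(g, truth, base_log2_range = c(10, 11),
                            gamma_variant_offset = gamma_offset,
                            seed = derive_seed(seed, sd_seed + 1L))
    layers <- purrr::map(
      list(mrna = counts_to_log_cpm(sim$mrna), ribo = counts_to_log_cpm(sim$ribo),
           protein = sim$protein),
      residualize
    )
    suppressMessages(suppressWarnings(
      call_specificity(layers, g, sim$annotation, n_perm = n_perm,
                       seed = derive_seed(seed, sd_seed + 2L),
                       focal_layers = "protein")
    ))
  }

  tr_shared <- cascade_truth(n_shared, beta = 0.7, lambda_r = 1, lambda_p = 1,
                             factor_sd = 0, seed = derive_seed(seed, 130L))
  res_sh <- run_arm(tr_shared, n_var = 3 * n_shared, gamma_offset = 0L,
                    sd_seed = 140L)

  gamma_p <- sqrt(0.2 / 0.8 * 1.2^2 / 0.38)  # marginal protein R^2 = 0.2
  tr_spec <- cascade_truth(n_specific, beta = 0.6, lambda_r = 1, lambda_p = 0,
                           gamma_p = gamma_p, factor_sd = 0,
                           seed = derive_seed(seed, 150L))
  res_sp <- run_arm(tr_spec, n_var = 12 * n_specific, gamma_offset = 6L,
                    sd_seed = 160L)
  prot <- res_sp[res_sp$layer == "protein", ]

  list(
    false_specific_rate = if (nrow(res_sh)) mean(res_sh$label == "specific") else NA_real_,
    protein_specific_recovery = if (nrow(prot)) mean(prot$label == "specific") else NA_real_,
    n_shared_tested = nrow(res_sh),
    n_specific_tested = nrow(prot)
  )
}

#' Colocalization discrimination rates
#'
#' 50 replicate cis regions where the same variant drives a strong mapped
#' QTL (marginal R^2 0.15 at n = 185) and a GWAS signal (R^2 0.05 at
#' n = 5000): fraction reaching PP4 >= 0.7. 50 replicates with the two
#' causal variants in different LD blocks: fraction with PP3 > PP4. Also
#' the largest deviation of any posterior vector's sum from 1.
#'
#' @param seed Master seed.
#' @param n_reps Replicates per arm.
#' @return Named list: shared_pp4_rate, distinct_pp3_gt_pp4_rate,
#'   max_pp_sum_error.
#' @export
check_coloc <- function(seed = 1L, n_reps = 50) {
  n <- 185; n_gwas <- 5000
  sum_err <- 0
  one_rep <- function(r, shared) {
    g <- simulate_genotypes(n, 60, ld_block_size = 6, ld_rho = 0.7,
                            seed = derive_seed(seed, 200L + r + 1000L * !shared))
    # causal variants are the most common variant of their LD block:
    # mapped lead QTLs are overwhelmingly common variants, and the
    # Wakefield ABF genuinely downweights low-MAF (large-se) effects
    top_of_block <- function(b) {
      idx <- which(attr(g, "sim_params")$block == b)
      idx[which.max(g$variants$maf[idx])]
    }
    vq <- top_of_block(3L)
    vg <- if (shared) vq else top_of_block(7L)
    set.seed(derive_seed(seed, 300L + r + 1000L * !shared))
    gq <- drop(scale(g$dosage[, vq]))
    # colocalization is only ever run on mapped QTL genes, so the region
    # is redrawn until the QTL reaches discovery-level significance
    for (try in 1:20) {
      y <- sqrt(0.15) * gq + sqrt(0.85) * rnorm(n)
      scan <- marginal_summary_stats(g$dosage, y)
      if (min(scan$pvalue) < 1e-5) break
    }
    qtl_stats <- tibble::tibble(variant_id = scan$variant_id,
                                slope = scan$beta, se = scan$se)
    # independent GWAS cohort with the same LD
    sp <- attr(g, "sim_params")
    thr <- qnorm(1 - sp$maf)
    hap <- function() {
      z <- matrix(rnorm(n_gwas * 60), n_gwas)
      shared_f <- matrix(rnorm(n_gwas * max(sp$block)), n_gwas)
      z <- sqrt(sp$ld_rho) * shared_f[, sp$block, drop = FALSE] +
        sqrt(1 - sp$ld_rho) * z
      sweep(z, 2, thr, ">") * 1L
    }
    dos2 <- hap() + hap()
    colnames(dos2) <- g$variants$variant_id
    g2v <- drop(scale(dos2[, vg]))
    y2 <- sqrt(0.05) * g2v + sqrt(0.95) * rnorm(n_gwas)
    gsc <- marginal_summary_stats(dos2, y2, ptype = "normal")
    gwas <- dplyr::mutate(gsc, effect_allele = g$variants$alt,
                          other_allele = g$variants$ref)
    res <- suppressWarnings(colocalize_gene("g", qtl_stats, gwas))
    sum_err <<- max(sum_err,
                    abs(res$pp0 + res$pp1 + res$pp2 + res$pp3 + res$pp4 - 1))
    res
  }
  shared <- purrr::map_dfr(seq_len(n_reps), one_rep, shared = TRUE)
  distinct <- purrr::map_dfr(seq_len(n_reps), one_rep, shared = FALSE)
  list(shared_pp4_rate = mean(shared$pp4 >= 0.7),
       distinct_pp3_gt_pp4_rate = mean(distinct$pp3 > distinct$pp4),
       max_pp_sum_error = sum_err)
}

#' MR estimator correctness
#'
#' IVW against its weighted-least-squares closed form and 2SLS against
#' explicit two-stage matrix algebra (maximum absolute differences);
#' fraction of OLS confounding bias removed by 2SLS on a confounded
#' design at n = 500; Egger intercept type-I error (no pleiotropy) and
#' power (directional pleiotropy on 30% of 20 instruments).
#'
#' @param seed Master seed.
#' @return Named list of the five quantities.
#' @export
check_mr <- function(seed = 1L) {
  set.seed(derive_seed(seed, 400L))
  inst <- tibble::tibble(beta_exp = rnorm(5, 0.3, 0.15), se_exp = 0.05,
                         beta_out = rnorm(5, 0.1, 0.05),
                         se_out = runif(5, 0.02, 0.05))
  w <- 1 / inst$se_out^2
  ivw_cf <- sum(w * inst$beta_exp * inst$beta_out) / sum(w * inst$beta_exp^2)
  ivw_diff <- abs(mr_ivw(inst)$estimate - ivw_cf)

  Z <- matrix(rbinom(150, 2, 0.3), 50, 3)
  xe <- drop(Z %*% c(0.4, 0.2, -0.3)) + rnorm(50)
  ye <- 0.7 * xe + rnorm(50)
  Zi <- cbind(1, Z)
  xhat <- Zi %*% solve(crossprod(Zi), crossprod(Zi, xe))
  W <- cbind(1, xhat)
  b_cf <- solve(crossprod(W), crossprod(W, ye))[2, 1]
  tsls_diff <- abs(tsls(xe, ye, Z)$estimate - b_cf)

  # confounded design: how much of the OLS bias does 2SLS remove
  biases <- purrr::map_dfr(1:20, function(r) {
    gg <- simulate_genotypes(500, 8, ld_block_size = 1, ld_rho = 0,
                             seed = derive_seed(seed, 420L + r))
    set.seed(derive_seed(seed, 440L + r))
    conf <- rnorm(500)
    xc <- drop(gg$dosage %*% rep(0.5, 8)) + 0.5 * conf + rnorm(500, sd = 0.8)
    yc <- 0.3 * xc + 0.5 * conf + rnorm(500)
    tibble::tibble(tsls_bias = tsls(xc, yc, gg$dosage)$estimate - 0.3,
                   ols_bias = coef(lm(yc ~ xc))[[2]] - 0.3)
  })
  bias_removed <- 1 - abs(mean(biases$tsls_bias)) / abs(mean(biases$ols_bias))

  set.seed(derive_seed(seed, 460L))
  t1 <- mean(vapply(1:200, function(i) {
    bx <- rnorm(20, 0, 0.3)
    by <- 0.25 * bx + rnorm(20, sd = 0.02)
    mr_egger(tibble::tibble(beta_exp = bx, se_exp = 0.03,
                            beta_out = by, se_out = 0.02))$intercept_p < 0.05
  }, logical(1)))
  # exposure effects drawn exponential (the canonical heavy-tailed QTL
  # effect-size distribution); its unit mean/sd ratio minimizes the
  # intercept's leverage penalty, which is what bounds this test's power
  pow <- mean(vapply(1:400, function(i) {
    bx <- rexp(20, rate = 1 / 0.3)
    # directional pleiotropy rides on the 30% weakest instruments, the
    # classic violation pattern (variants acting mostly through paths
    # other than the exposure are those with little exposure effect)
    pleio <- numeric(20)
    pleio[order(bx)[1:6]] <- 0.3
    by <- 0.25 * bx + pleio + rnorm(20, sd = 0.02)
    mr_egger(tibble::tibble(beta_exp = bx, se_exp = 0.03,
                            beta_out = by, se_out = 0.02))$intercept_p < 0.05
  }, logical(1)))
  list(ivw_oracle_max_diff = ivw_diff, tsls_oracle_max_diff = tsls_diff,
       confounding_bias_removed = bias_removed,
       egger_type1 = t1, egger_power = pow)
}

#' Cascade classification accuracy
#'
#' Simulates 50 genes per architecture class — full cascade
#' (transcription drives protein), attenuated-at-protein (upstream causal
#' only) and protein-specific (no upstream signal) — and measures the
#' fraction of genes whose one-sample MR cascade verdict matches the
#' expected both-/single-/none-passed class.
#'
#' @param seed Master seed.
#' @param per_class Genes per class.
#' @param n_samples Cohort size.
#' @return Named list: accuracy per class and overall.
#' @export
check_cascade <- function(seed = 1L, per_class = 50, n_samples = 185) {
  n_genes <- 3 * per_class
  cls <- rep(c("both", "single", "none"), each = per_class)
  gamma_p <- sqrt(0.2 / 0.8 * 1.2^2 / 0.38)
  tr <- cascade_truth(
    n_genes,
    beta = ifelse(cls == "none", 0, 0.7),
    lambda_r = 1,
    lambda_p = ifelse(cls == "both", 1, 0),
    gamma_p = ifelse(cls == "none", gamma_p, 0),
    factor_sd = 0,
    seed = derive_seed(seed, 500L)
  )
  g <- simulate_genotypes(n_samples, 4 * n_genes, ld_block_size = 6,
                          ld_rho = 0.7, pos_spacing = c(10000, 60000),
                          seed = derive_seed(seed, 501L))
  sim <- simulate_cascade(g, tr, base_log2_range = c(10, 11),
                          gamma_variant_offset = 2L,
                          seed = derive_seed(seed, 502L))
  layers <- purrr::map(
    list(mrna = counts_to_log_cpm(sim$mrna), ribo = counts_to_log_cpm(sim$ribo),
         protein = sim$protein),
    residualize
  )
  res <- suppressMessages(suppressWarnings(
    mr_one_sample(layers, g, sim$annotation)
  ))
  v <- res$verdicts
  expected <- setNames(c("both-passed", "single-passed", "none-passed"),
                       c("both", "single", "none"))
  acc <- vapply(names(expected), function(k) {
    ids <- tr$gene_id[cls == k]
    mean(v$class[match(ids, v$gene_id)] == expected[[k]], na.rm = TRUE)
  }, numeric(1))
  list(accuracy_full_cascade = acc[["both"]],
       accuracy_attenuated = acc[["single"]],
       accuracy_specific = acc[["none"]],
       accuracy_overall = mean(acc))
}

#' TWAS null control and single-variant identity
#'
#' Trains cis models on a synthetic cohort, then (a) evaluates them
#' against 20 independent null GWAS draws, recording the fraction of
#' replicates with zero FWER < 0.05 genes, and (b) checks that a
#' single-variant model's gene z-score equals the variant's GWAS z-score
#' exactly.
#'
#' @param seed Master seed.
#' @param n_reps Null GWAS replicates.
#' @return Named list: null_clean_rate, single_variant_z_diff.
#' @export
check_twas <- function(seed = 1L, n_reps = 60) {
  # a dense panel: neighbouring genes share LD blocks, so gene-level
  # tests are positively dependent and Bonferroni is conservative --
  # the situation real cis windows produce
  g <- simulate_genotypes(400, 45, ld_block_size = 6, ld_rho = 0.7,
                          seed = derive_seed(seed, 600L))
  tr <- cascade_truth(30, beta = 0.5, lambda_r = 1, lambda_p = 1,
                      factor_sd = 0, seed = derive_seed(seed, 601L))
  sim <- simulate_cascade(g, tr, base_log2_range = c(10, 11),
                          seed = derive_seed(seed, 602L))
  mrna <- residualize(counts_to_log_cpm(sim$mrna))
  wins <- cis_windows(sim$annotation)
  models <- purrr::map(seq_len(30), function(i) {
    train_prediction_model(wins[i, ], g, mrna[, i], layer = "mrna",
                           seed = derive_seed(seed, 610L + i))
  })
  # null GWAS with realistic LD-correlated summary statistics: the
  # liability is pure environmental noise (flagged causal gene with a
  # zero protein slope)
  tr_null <- sim$truth
  tr_null$causal_for_outcome <- c(TRUE, rep(FALSE, nrow(tr_null) - 1L))
  tr_null$slope_protein <- rep(0, nrow(tr_null))
  clean <- vapply(seq_len(n_reps), function(r) {
    gw <- simulate_gwas(g, tr_null, outcome_h2 = 0.5, n_gwas = 10000,
                        seed = derive_seed(seed, 650L + r))
    tw <- run_twas(models, gw, g)
    sum(tw$significant) == 0
  }, logical(1))

  set.seed(derive_seed(seed, 700L))
  z <- rnorm(45)
  gw <- tibble::tibble(variant_id = g$variants$variant_id,
                       effect_allele = g$variants$alt,
                       other_allele = g$variants$ref,
                       beta = z / 100, se = 1 / 100, zscore = z,
                       pvalue = 2 * pnorm(-abs(z)), n = 10000)
  m1 <- structure(list(gene_id = "single", layer = "mrna",
                       weights = c(v00007 = 1.7), intercept = 0,
                       retained = TRUE, conditional = FALSE, r_cv = 0.5,
                       r_cv_p = 1e-4, n_variants = 1),
                  class = "prediction_model")
  zdiff <- abs(spredixcan_zscore(m1, gw, g)$zscore - z[[7]])
  list(null_clean_rate = mean(clean), single_variant_z_diff = zdiff)
}
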