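#' Greedy LD clumping
#'
#' Repeatedly picks the smallest-p variant below `p_threshold` as an index
#' variant and removes every remaining variant within `window_kb` of it
#' whose dosage r-squared with the index exceeds `r2_max`; PLINK-style
#' defaults are a 1000 kb window and r2 0.5, with instrument selection at
#' p < 0.05.
#'
#' @param stats Tibble variant_id, pvalue (e.g. a [nominal_scan()] result).
#' @param genotypes A `variant_table` providing positions and the r2
#'   estimates.
#' @param r2_max Maximum allowed r2 between retained instruments.
#' @param window_kb Clumping window in kilobases.
#' @param p_threshold Instrument selection p-value threshold.
#' @return Tibble of index variants (variant_id, pvalue, pos), possibly
#'   empty.
#' @export
ld_clump <- function(stats, genotypes, r2_max = 0.5, window_kb = 1000,
                     p_threshold = 0.05) {
  cand <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(stats), "variant_id", "pvalue"),
    genotypes$variants[, c("variant_id", "pos")], by = "variant_id"
  ) |>
    dplyr::filter(.data$pvalue < p_threshold) |>
    dplyr::arrange(.data$pvalue)
  kept <- list()
  while (nrow(cand) > 0) {
    idx <- cand[1, ]
    kept[[length(kept) + 1L]] <- idx
    near <- abs(cand$pos - idx$pos) <= window_kb * 1000
    r2 <- rep(0, nrow(cand))
    if (any(near)) {
      r2[near] <- suppressWarnings(cor(
        genotypes$dosage[, idx$variant_id],
        genotypes$dosage[, cand$variant_id[near], drop = FALSE]
      ))^2
    }
    r2[is.na(r2)] <- 1
    drop_mask <- (near & r2 > r2_max) | cand$variant_id == idx$variant_id
    cand <- cand[!drop_mask, , drop = FALSE]
  }
  if (length(kept) == 0) {
    return(tibble::tibble(variant_id = character(), pvalue = numeric(),
                          pos = numeric()))
  }
  dplyr::bind_rows(kept)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure effect allele: flips the
#' outcome beta when the effect/other alleles are swapped, drops
#' strand-ambiguous palindromic (A/T, C/G) variants, and drops variants
#' whose allele pairs are incompatible. Drops are reported via messages.
#'
#' @param exposure Tibble variant_id, effect_allele, other_allele, beta, se.
#' @param outcome Tibble with the same columns.
#' @return Tibble variant_id, beta_exp, se_exp, beta_out, se_out.
#' @export
harmonize <- function(exposure, outcome) {
  j <- dplyr::inner_join(
    dplyr::select(exposure, "variant_id", ea_x = "effect_allele",
                  oa_x = "other_allele", beta_exp = "beta", se_exp = "se"),
    dplyr::select(outcome, "variant_id", ea_y = "effect_allele",
                  oa_y = "other_allele", beta_out = "beta", se_out = "se"),
    by = "variant_id"
  )
  pal <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  palind <- pal(j$ea_x, j$oa_x)
  if (any(palind)) inform(sprintf("dropping %d palindromic variant(s)", sum(palind)))
  j <- j[!palind, , drop = FALSE]
  same <- j$ea_x == j$ea_y & j$oa_x == j$oa_y
  swapped <- j$ea_x == j$oa_y & j$oa_x == j$ea_y
  incompat <- !(same | swapped)
  if (any(incompat)) inform(sprintf("dropping %d allele-incompatible variant(s)", sum(incompat)))
  j <- j[!incompat, , drop = FALSE]
  flip <- j$ea_x == j$oa_y & j$oa_x == j$ea_y
  j$beta_out[flip] <- -j$beta_out[flip]
  dplyr::select(j, "variant_id", "beta_exp", "se_exp", "beta_out", "se_out")
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect weighted regression of outcome betas on exposure betas
#' through the origin, weights `1/se_out^2`. A single instrument falls
#' back to the Wald ratio with a first-order delta-method standard error
#' (flagged in the output).
#'
#' @param instruments Harmonized tibble (beta_exp, se_exp, beta_out,
#'   se_out).
#' @return One-row tibble: method, estimate, se, pvalue, n_instruments,
#'   single_instrument.
#' @export
mr_ivw <- function(instruments) {
  k <- nrow(instruments)
  if (k < 1) abort("need at least one instrument")
  bx <- instruments$beta_exp; by <- instruments$beta_out
  w <- 1 / instruments$se_out^2
  if (k == 1) {
    est <- by / bx
    se <- instruments$se_out / abs(bx)
  } else {
    est <- sum(w * bx * by) / sum(w * bx^2)
    se <- sqrt(1 / sum(w * bx^2))
  }
  z <- est / se
  tibble::tibble(method = "IVW", estimate = est, se = se,
                 pvalue = 2 * pnorm(-abs(z)),
                 n_instruments = k, single_instrument = k == 1)
}

#' MR-Egger regression with intercept-based pleiotropy test
#'
#' Orients all exposure betas positive (flipping the paired outcome betas),
#' then fits a weighted regression of outcome on exposure betas with a free
#' intercept, weights `1/se_out^2`. A nonzero intercept indicates
#' directional horizontal pleiotropy. Requires at least 3 instruments.
#'
#' @param instruments Harmonized tibble.
#' @return One-row tibble: method, estimate, se, pvalue, intercept,
#'   intercept_se, intercept_p, n_instruments.
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) {
    inform("fewer than 3 instruments: Egger pleiotropy test unavailable")
    return(tibble::tibble(method = "Egger", estimate = NA_real_, se = NA_real_,
                          pvalue = NA_real_, intercept = NA_real_,
                          intercept_se = NA_real_, intercept_p = NA_real_,
                          n_instruments = k))
  }
  flip <- sign(instruments$beta_exp)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exp * flip
  by <- instruments$beta_out * flip
  w <- 1 / instruments$se_out^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  tibble::tibble(method = "Egger",
                 estimate = sm["bx", 1], se = sm["bx", 2],
                 pvalue = sm["bx", 4],
                 intercept = sm["(Intercept)", 1],
                 intercept_se = sm["(Intercept)", 2],
                 intercept_p = sm["(Intercept)", 4],
                 n_instruments = k)
}

#' Pass/fail verdict for a two-sample MR test
#'
#' pass iff the IVW effect survives the FDR cutoff AND the Egger intercept
#' shows no pleiotropy (`intercept_p > intercept_alpha`); otherwise
#' fail_pleiotropy (effect fine, intercept significant), fail_effect, or
#' untested when either input is missing.
#'
#' @param fdr BH-adjusted IVW p-value(s).
#' @param intercept_p Egger intercept p-value(s).
#' @param fdr_cutoff FDR threshold (0.1).
#' @param intercept_alpha Intercept test level (0.05).
#' @return Character verdicts.
#' @export
two_sample_verdict <- function(fdr, intercept_p, fdr_cutoff = 0.1,
                               intercept_alpha = 0.05) {
  dplyr::case_when(
    is.na(fdr) | is.na(intercept_p) ~ "untested",
    fdr < fdr_cutoff & intercept_p > intercept_alpha ~ "pass",
    fdr < fdr_cutoff ~ "fail_pleiotropy",
    TRUE ~ "fail_effect"
  )
}

#' Two-stage least squares (one-sample MR)
#'
#' Stage 1 regresses the exposure on the instrument dosages; stage 2
#' regresses the outcome on the fitted exposure, with standard errors
#' computed from the structural residuals (outcome minus coefficients
#' applied to the observed exposure), the correct 2SLS covariance. The
#' first-stage F statistic measures instrument strength (F < 10 sets
#' `weak_instruments`). The pleiotropy proxy `intercept_p` is the stage-2
#' intercept test on z-scored exposure and outcome. Collinear instrument
#' columns are dropped with a warning.
#'
#' @param exposure,outcome Numeric vectors on the same samples.
#' @param instruments Dosage matrix (samples x instruments).
#' @return One-row tibble: method, estimate, se, pvalue, intercept,
#'   intercept_p, f_statistic, n_instruments, weak_instruments.
#' @export
tsls <- function(exposure, outcome, instruments) {
  Z <- as.matrix(instruments)
  n <- length(exposure)
  if (n != length(outcome) || n != nrow(Z)) abort("sample dimensions disagree")
  if (n <= ncol(Z) + 2) abort("need n > n_instruments + 2")
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1) {
    keep <- qr(cbind(1, Z))$pivot[seq_len(qrz$rank)] - 1L
    keep <- keep[keep > 0]
    warn(sprintf("dropping %d collinear instrument column(s)", ncol(Z) - length(keep)))
    Z <- Z[, keep, drop = FALSE]
  }
  core <- function(x, y) {
    s1 <- lm.fit(cbind(1, Z), x)
    xhat <- x - s1$residuals
    W <- cbind(1, xhat)
    b <- drop(solve(crossprod(W), crossprod(W, y)))
    u <- y - cbind(1, x) %*% b          # structural residuals use observed x
    sigma2 <- sum(u^2) / (n - 2)
    vcv <- sigma2 * solve(crossprod(W))
    # first-stage F for the excluded instruments
    rss1 <- sum(s1$residuals^2)
    rss0 <- sum((x - mean(x))^2)
    f <- ((rss0 - rss1) / ncol(Z)) / (rss1 / (n - ncol(Z) - 1))
    list(b = b, se = sqrt(diag(vcv)), f = f)
  }
  main <- core(exposure, outcome)
  std <- core(drop(scale(exposure)), drop(scale(outcome)))
  tz <- main$b[[2]] / main$se[[2]]
  iz <- std$b[[1]] / std$se[[1]]
  tibble::tibble(
    method = "TSLS",
    estimate = main$b[[2]], se = main$se[[2]],
    pvalue = t_pvalue(tz, n - 2),
    intercept = std$b[[1]], intercept_p = t_pvalue(iz, n - 2),
    f_statistic = main$f, n_instruments = ncol(Z),
    weak_instruments = main$f < 10
  )
}

#' Cascade verdict from the two adjacent-layer MR tests
#'
#' Combines the mRNA -> ribosome-occupancy (upstream) and ribosome
#' occupancy -> protein (downstream) pass flags into both-passed /
#' single-passed / none-passed.
#'
#' @param upstream_pass,downstream_pass Logical flags (NA = untested,
#'   counted as a fail).
#' @return Character class per gene.
#' @export
cascade_classify <- function(upstream_pass, downstream_pass) {
  up <- !is.na(upstream_pass) & upstream_pass
  dn <- !is.na(downstream_pass) & downstream_pass
  dplyr::case_when(up & dn ~ "both-passed",
                   up | dn ~ "single-passed",
                   TRUE ~ "none-passed")
}

#' Two-sample MR over a set of genes
#'
#' For each gene: clump the exposure (QTL nominal scan) statistics into
#' independent instruments, harmonize with the GWAS, run IVW and Egger,
#' then BH-adjust the IVW p-values across all tested gene x layer pairs
#' and apply the pass rule (FDR < `fdr_cutoff` and Egger intercept p >
#' `intercept_alpha`).
#'
#' @param exposure_stats Tibble with gene_id, layer, variant_id,
#'   effect_allele, other_allele, beta, se, pvalue (per-variant QTL
#'   nominal statistics of the candidate genes).
#' @param gwas A `gwas_summary` tibble.
#' @param genotypes A `variant_table` (clumping LD reference).
#' @param r2_max,window_kb,p_threshold Clumping parameters.
#' @param fdr_cutoff,intercept_alpha Verdict thresholds.
#' @return A `mr_result` tibble with IVW estimate/se/p, Egger intercept
#'   fields, fdr and verdict per gene x layer.
#' @export
mr_two_sample <- function(exposure_stats, gwas, genotypes,
                          r2_max = 0.5, window_kb = 1000, p_threshold = 0.05,
                          fdr_cutoff = 0.1, intercept_alpha = 0.05) {
  groups <- dplyr::group_split(dplyr::group_by(exposure_stats, .data$gene_id, .data$layer))
  rows <- purrr::map_dfr(groups, function(g) {
    base <- tibble::tibble(gene_id = g$gene_id[[1]], layer = g$layer[[1]])
    clumped <- ld_clump(g, genotypes, r2_max, window_kb, p_threshold)
    if (nrow(clumped) == 0) {
      return(dplyr::mutate(base, estimate = NA_real_, se = NA_real_,
                           pvalue = NA_real_, intercept_p = NA_real_,
                           n_instruments = 0L))
    }
    harm <- harmonize(g[g$variant_id %in% clumped$variant_id, ], gwas)
    if (nrow(harm) == 0) {
      return(dplyr::mutate(base, estimate = NA_real_, se = NA_real_,
                           pvalue = NA_real_, intercept_p = NA_real_,
                           n_instruments = 0L))
    }
    ivw <- mr_ivw(harm)
    egg <- mr_egger(harm)
    dplyr::mutate(base, estimate = ivw$estimate, se = ivw$se,
                  pvalue = ivw$pvalue, intercept = egg$intercept,
                  intercept_p = egg$intercept_p,
                  n_instruments = ivw$n_instruments)
  })
  rows$fdr <- p.adjust(rows$pvalue, method = "BH")
  rows$verdict <- two_sample_verdict(rows$fdr, rows$intercept_p,
                                     fdr_cutoff, intercept_alpha)
  structure(rows, class = c("mr_result", class(rows)))
}

#' One-sample MR between adjacent omics layers with cascade classification
#'
#' For each gene, tests mRNA -> ribosome occupancy and ribosome occupancy
#' -> protein by 2SLS, using as instruments the LD-clumped upstream-layer
#' cis variants with nominal p < `p_threshold`. P-values are BH-adjusted
#' across all gene x pathway tests; a pathway passes when FDR <
#' `fdr_cutoff` and the intercept pleiotropy proxy has p >
#' `intercept_alpha`; the per-gene verdicts combine via
#' [cascade_classify()].
#'
#' @param layers Named list with residualized mrna, ribo, protein
#'   `omics_matrix` objects on shared samples.
#' @param genotypes A `variant_table` on the same samples.
#' @param annotation Gene annotation tibble.
#' @param genes Genes to test (default: all annotated genes present in all
#'   layers).
#' @param r2_max,window_kb,p_threshold Instrument selection parameters.
#' @param fdr_cutoff,intercept_alpha Pass thresholds.
#' @param maf_min Cis MAF filter.
#' @return List with `$tests` (a `mr_result` tibble, one row per gene x
#'   pathway) and `$verdicts` (gene_id, upstream_pass, downstream_pass,
#'   class).
#' @export
mr_one_sample <- function(layers, genotypes, annotation, genes = NULL,
                          r2_max = 0.5, window_kb = 1000, p_threshold = 0.05,
                          fdr_cutoff = 0.1, intercept_alpha = 0.05,
                          maf_min = 0.05) {
  stopifnot(all(c("mrna", "ribo", "protein") %in% names(layers)))
  wins <- cis_windows(annotation)
  genes <- genes %||% Reduce(intersect, c(list(wins$gene_id),
                                          purrr::map(layers, colnames)))
  pathways <- list(upstream = c("mrna", "ribo"), downstream = c("ribo", "protein"))
  rows <- purrr::map_dfr(genes, function(g) {
    win <- wins[wins$gene_id == g, ]
    purrr::imap_dfr(pathways, function(pw, pname) {
      expo <- layers[[pw[[1]]]][, g]
      outc <- layers[[pw[[2]]]][, g]
      scan <- nominal_scan(win, genotypes, expo, maf_min)
      clumped <- ld_clump(scan, genotypes, r2_max, window_kb, p_threshold)
      base <- tibble::tibble(gene_id = g, pathway = pname)
      if (nrow(clumped) == 0 ||
          length(expo) <= nrow(clumped) + 2) {
        return(dplyr::mutate(base, estimate = NA_real_, se = NA_real_,
                             pvalue = NA_real_, intercept_p = NA_real_,
                             f_statistic = NA_real_, n_instruments = 0L,
                             weak_instruments = NA))
      }
      fit <- tsls(expo, outc, genotypes$dosage[, clumped$variant_id, drop = FALSE])
      dplyr::bind_cols(base, dplyr::select(fit, -"method", -"intercept"))
    })
  })
  rows$fdr <- p.adjust(rows$pvalue, method = "BH")
  rows$pass <- !is.na(rows$fdr) & rows$fdr < fdr_cutoff &
    !is.na(rows$intercept_p) & rows$intercept_p > intercept_alpha
  verdicts <- rows |>
    dplyr::select("gene_id", "pathway", "pass") |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "pass") |>
    dplyr::transmute(gene_id = .data$gene_id,
                     upstream_pass = .data$upstream,
                     downstream_pass = .data$downstream,
                     class = cascade_classify(.data$upstream, .data$downstream))
  list(tests = structure(rows, class = c("mr_result", class(rows))),
       verdicts = verdicts)
}
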