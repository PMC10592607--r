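#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect `beta` with standard error `se` and a normal
#' effect prior with standard deviation `prior_sd`:
#' `logABF = 0.5 * (log(1 - r) + r * z^2)` with `z = beta/se` and
#' `r = prior_sd^2 / (prior_sd^2 + se^2)`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param prior_sd Prior effect scale (0.15 for a standardized quantitative
#'   trait).
#' @return Vector of log ABFs.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) abort("`se` must be positive")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

#' Five-hypothesis colocalization posteriors from per-variant log ABFs
#'
#' Enumerates, in log space, H0 (no association), H1/H2 (one trait only),
#' H3 (two distinct causal variants) and H4 (one shared causal variant)
#' under a single-causal-variant-per-trait assumption, with per-variant
#' prior probabilities `p1`, `p2` and shared prior `p12`:
#' H1 is proportional to `p1 * sum(BF1)`, H2 to `p2 * sum(BF2)`, H3 to
#' `p1 * p2 * (sum(BF1) * sum(BF2) - sum(BF1*BF2))` and H4 to
#' `p12 * sum(BF1*BF2)`, normalized against H0 = 1. With a single variant
#' the distinct-pair sum is empty, so pp3 = 0 exactly.
#'
#' @param logabf_qtl,logabf_gwas Equal-length log-ABF vectors over the same
#'   variants in the same allele orientation.
#' @param p1,p2,p12 Prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param variant_ids Optional variant names for the lead-shared-variant
#'   report.
#' @return Tibble with pp0..pp4, n_snps, lead_shared_variant.
#' @export
coloc_posteriors <- function(logabf_qtl, logabf_gwas,
                             p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             variant_ids = NULL) {
  if (length(logabf_qtl) != length(logabf_gwas)) {
    abort("log-ABF vectors must cover the same variants")
  }
  n <- length(logabf_qtl)
  l1 <- logsumexp(logabf_qtl)
  l2 <- logsumexp(logabf_gwas)
  l12 <- logsumexp(logabf_qtl + logabf_gwas)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + l1,
    h2 = log(p2) + l2,
    h3 = log(p1) + log(p2) + logdiff(l1 + l2, l12),
    h4 = log(p12) + l12
  )
  pp <- exp(lh - logsumexp(lh))
  lead <- if (!is.null(variant_ids)) {
    variant_ids[[which.max(logabf_qtl + logabf_gwas)]]
  } else {
    NA_character_
  }
  tibble::tibble(pp0 = pp[[1]], pp1 = pp[[2]], pp2 = pp[[3]],
                 pp3 = pp[[4]], pp4 = pp[[5]],
                 n_snps = n, lead_shared_variant = lead)
}

#' Colocalize one gene's QTL signal with GWAS
#'
#' Joins the gene's per-variant QTL nominal statistics (slope and slope
#' standard error from the cis scan) with GWAS summary statistics over the
#' shared variants, converts both to Wakefield log ABFs and evaluates the
#' five-hypothesis posteriors. The gene is reported as colocalized when
#' `pp4 >= pph4_cutoff` (0.7 by default). GWAS rows lacking beta/se fall
#' back to the z/sqrt(n) scaling.
#'
#' @param gene_id Gene label for the output row.
#' @param qtl_stats Tibble variant_id, slope, se from [nominal_scan()].
#' @param gwas A `gwas_summary` tibble.
#' @param pph4_cutoff Reporting threshold on pp4.
#' @param prior_sd_qtl,prior_sd_gwas Wakefield prior scales.
#' @param p1,p2,p12 Hypothesis priors.
#' @return One-row tibble: gene_id, pp0..pp4, n_snps, lead_shared_variant,
#'   colocalized.
#' @export
colocalize_gene <- function(gene_id, qtl_stats, gwas, pph4_cutoff = 0.7,
                            prior_sd_qtl = 0.15, prior_sd_gwas = 0.15,
                            p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  joined <- dplyr::inner_join(
    dplyr::select(qtl_stats, "variant_id", qtl_beta = "slope", qtl_se = "se"),
    gwas, by = "variant_id"
  )
  if (nrow(joined) == 0) abort(sprintf("gene %s: no variant overlaps the GWAS", gene_id))
  if (nrow(joined) < 10) {
    warn(sprintf("gene %s: only %d overlapping variants, posteriors unstable",
                 gene_id, nrow(joined)))
  }
  no_beta <- is.na(joined$beta) | is.na(joined$se)
  joined$beta[no_beta] <- joined$zscore[no_beta] / sqrt(joined$n[no_beta])
  joined$se[no_beta] <- 1 / sqrt(joined$n[no_beta])
  res <- coloc_posteriors(
    wakefield_abf(joined$qtl_beta, joined$qtl_se, prior_sd_qtl),
    wakefield_abf(joined$beta, joined$se, prior_sd_gwas),
    p1 = p1, p2 = p2, p12 = p12, variant_ids = joined$variant_id
  )
  dplyr::mutate(res, gene_id = gene_id, colocalized = .data$pp4 >= pph4_cutoff,
                .before = 1)
}
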