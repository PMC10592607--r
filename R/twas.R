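#' Summary-statistic gene-level association z-score
#'
#' Combines a gene's cis prediction-model weights with GWAS per-variant
#' z-scores under an LD reference:
#' `z_gene = sum_i w_i * (sigma_i / sigma_g) * z_i`, where `sigma_i` is the
#' dosage standard deviation of variant i and
#' `sigma_g = sqrt(w' Sigma w)` the standard deviation of the imputed
#' expression under the LD covariance `Sigma`. The LD reference is the QTL
#' cohort's genotypes (the models' training data), the standard practice
#' when GWAS-cohort LD is unavailable.
#'
#' @param model A retained `prediction_model`.
#' @param gwas A `gwas_summary` tibble.
#' @param genotypes A `variant_table` serving as the LD reference.
#' @return One-row tibble: gene_id, layer, zscore, pvalue,
#'   n_model_snps_used, testable.
#' @export
spredixcan_zscore <- function(model, gwas, genotypes) {
  vars <- intersect(names(model$weights), gwas$variant_id)
  vars <- intersect(vars, colnames(genotypes$dosage))
  if (length(vars) == 0) abort(sprintf("gene %s: no model variant has GWAS statistics", model$gene_id))
  w <- model$weights[vars]
  z <- gwas$zscore[match(vars, gwas$variant_id)]
  dos <- genotypes$dosage[, vars, drop = FALSE]
  sig_i <- apply(dos, 2, sd)
  Sigma <- cov(dos)
  sig_g <- sqrt(max(drop(t(w) %*% Sigma %*% w), 0))
  if (sig_g == 0) {
    return(tibble::tibble(gene_id = model$gene_id, layer = model$layer,
                          zscore = NA_real_, pvalue = NA_real_,
                          n_model_snps_used = length(vars), testable = FALSE))
  }
  zg <- sum(w * sig_i * z) / sig_g
  tibble::tibble(gene_id = model$gene_id, layer = model$layer,
                 zscore = zg, pvalue = 2 * pnorm(-abs(zg)),
                 n_model_snps_used = length(vars), testable = TRUE)
}

#' Cauchy (omnibus) combination of dependent p-values
#'
#' `T = mean(tan((0.5 - p) * pi))`, `p_combined = 0.5 - atan(T) / pi`.
#' Robust to arbitrary dependence between the component tests, which makes
#' it suitable for combining per-isoform association p-values of one gene
#' without estimating their correlation. The choice of the Cauchy
#' combination as the omnibus rule is this package's own; any p-value of 0
#' is clipped to 1e-300 with a warning.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
omnibus_combine <- function(pvalues) {
  stopifnot(length(pvalues) >= 1, all(pvalues <= 1), all(pvalues >= 0))
  if (any(pvalues == 0)) {
    warn("p-value of 0 clipped to 1e-300")
    pvalues[pvalues == 0] <- 1e-300
  }
  if (length(pvalues) == 1) return(pvalues)
  tstat <- mean(tan((0.5 - pvalues) * pi))
  min(max(0.5 - atan(tstat) / pi, 0), 1)
}

#' Bonferroni family-wise error rates
#'
#' @param pvalues Nominal p-values.
#' @param n_tests Number of tests in the family (defaults to
#'   `length(pvalues)`; must be at least that).
#' @return `pmin(1, pvalues * n_tests)`.
#' @export
fwer_adjust <- function(pvalues, n_tests = length(pvalues)) {
  if (n_tests < length(pvalues)) abort("`n_tests` must be >= length(pvalues)")
  pmin(1, pvalues * n_tests)
}

#' Gene-level TWAS across layers
#'
#' Applies [spredixcan_zscore()] to every retained model, then Bonferroni
#' adjusts within each layer (the per-layer test family) and marks
#' significance at `fwer <= alpha`.
#'
#' @param models List of `prediction_model`s (across genes and layers).
#' @param gwas A `gwas_summary` tibble.
#' @param genotypes LD-reference `variant_table`.
#' @param alpha Family-wise significance level.
#' @return A `twas_result` tibble: gene_id, layer, zscore, pvalue, fwer,
#'   n_model_snps_used, significant.
#' @export
run_twas <- function(models, gwas, genotypes, alpha = 0.05) {
  models <- purrr::compact(models)
  models <- purrr::keep(models, ~ .x$retained)
  if (length(models) == 0) abort("no retained prediction models")
  res <- purrr::map_dfr(models, function(m) {
    tryCatch(spredixcan_zscore(m, gwas, genotypes), error = function(e) NULL)
  })
  res <- res |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(fwer = fwer_adjust(.data$pvalue, dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$fwer) & .data$fwer <= alpha)
  structure(res, class = c("twas_result", class(res)))
}
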