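# nominal p (and slope) of each discovery lead variant in another layer
lead_variant_stats <- function(leads, mat, genotypes) {
  stopifnot(all(c("gene_id", "lead_variant_id") %in% names(leads)))
  purrr::pmap_dfr(leads[, c("gene_id", "lead_variant_id")], function(gene_id, lead_variant_id) {
    if (!(gene_id %in% colnames(mat)) ||
        !(lead_variant_id %in% colnames(genotypes$dosage))) {
      return(NULL)
    }
    st <- marginal_summary_stats(
      genotypes$dosage[, lead_variant_id, drop = FALSE], mat[, gene_id]
    )
    tibble::tibble(gene_id = gene_id, variant_id = lead_variant_id,
                   slope = st$beta, se = st$se, pvalue = st$pvalue)
  })
}

#' Storey pi1 replication of a discovery QTL set in another layer
#'
#' For each discovery gene's lead variant, computes the nominal association
#' p-value in the replication layer and estimates the true-positive
#' fraction pi1 = 1 - pi0 of that p-value vector.
#'
#' @param discovery Tibble of significant discovery QTLs (needs gene_id,
#'   lead_variant_id).
#' @param replication_layer Residualized `omics_matrix` of the replication
#'   omics type.
#' @param genotypes A `variant_table`.
#' @return pi1 estimate in 0..1 (warns below 20 discovery genes).
#' @export
replication_pi1 <- function(discovery, replication_layer, genotypes) {
  if (nrow(discovery) == 0) abort("empty discovery set")
  if (nrow(discovery) < 20) warn("fewer than 20 discovery genes: pi0 smoothing is unstable")
  st <- lead_variant_stats(discovery, replication_layer, genotypes)
  1 - storey_pi0(st$pvalue)
}

#' Full 3x3 pi1 replication matrix with asymmetry statistics
#'
#' Rows are discovery layers, columns replication layers; the diagonal is 1
#' by convention. The per-pair asymmetry statistic is
#' pi1(downstream -> upstream) - pi1(upstream -> downstream): positive
#' values mean downstream QTLs replicate better upstream than vice versa,
#' the signature of effect attenuation along the cascade.
#'
#' @param qtl A `qtl_result` covering the layers in `layers`.
#' @param layers Named list of residualized `omics_matrix` objects.
#' @param genotypes A `variant_table`.
#' @return A `replication_matrix`: list with `$pi1` (matrix) and
#'   `$asymmetry` (tibble of upstream/downstream pairs).
#' @export
replication_matrix <- function(qtl, layers, genotypes) {
  lnames <- names(layers)
  m <- matrix(1, length(lnames), length(lnames), dimnames = list(lnames, lnames))
  for (d in lnames) {
    disc <- qtl[qtl$layer == d & qtl$significant, ]
    for (r in setdiff(lnames, d)) {
      m[d, r] <- if (nrow(disc) == 0) NA_real_ else {
        replication_pi1(disc, layers[[r]], genotypes)
      }
    }
  }
  order_rank <- c(mrna = 1, ribo = 2, protein = 3)
  pairs <- if (length(lnames) >= 2) {
    utils::combn(lnames, 2, simplify = FALSE)
  } else {
    list()
  }
  asym <- purrr::map_dfr(pairs, function(pr) {
    up <- pr[[which.min(order_rank[pr])]]
    down <- pr[[which.max(order_rank[pr])]]
    tibble::tibble(upstream = up, downstream = down,
                   asymmetry = m[down, up] - m[up, down])
  })
  structure(list(pi1 = m, asymmetry = asym), class = "replication_matrix")
}

#' @export
print.replication_matrix <- function(x, ...) {
  cat("<replication_matrix> pi1 (rows = discovery, cols = replication)\n")
  print(round(x$pi1, 3))
  invisible(x)
}

#' Direction-aware cutoff-based replication rates
#'
#' For each p-value cutoff, the rate is the fraction of discovery lead
#' variants whose replication-layer p-value is below the cutoff AND whose
#' replication slope agrees in sign with the discovery slope.
#'
#' @param discovery Tibble of discovery QTLs (gene_id, lead_variant_id,
#'   slope).
#' @param replication_layer Residualized `omics_matrix`.
#' @param genotypes A `variant_table`.
#' @param p_cutoffs Vector of replication p-value cutoffs.
#' @return Tibble cutoff, rate, n.
#' @export
directional_replication_rate <- function(discovery, replication_layer, genotypes,
                                         p_cutoffs = c(0.01, 0.05, 0.1, 0.5, 1)) {
  st <- lead_variant_stats(discovery, replication_layer, genotypes)
  joined <- dplyr::inner_join(
    dplyr::select(discovery, "gene_id", disc_slope = "slope"),
    st, by = "gene_id"
  )
  purrr::map_dfr(p_cutoffs, function(ct) {
    tibble::tibble(
      cutoff = ct,
      rate = mean(joined$pvalue < ct & sign(joined$slope) == sign(joined$disc_slope)),
      n = nrow(joined)
    )
  })
}

#' Aggregate per-allele effect profile of an external QTL list
#'
#' Evaluates an externally discovered (gene, variant) list on all three
#' layers of this dataset: per layer, the per-allele slope of the log2-scale
#' quantification (not the standardized residuals, so effects are
#' comparable across layers in log2 fold-change units), the mean absolute
#' slope with a normal-approximation 95% CI, and paired two-sided t-tests
#' between layers. Because the external list was discovered independently,
#' the profile is free of this dataset's winner's-curse ascertainment.
#'
#' @param external_snps Tibble with gene_id, variant_id and optionally
#'   discovery_slope (the external study's effect estimate). When
#'   discovery_slope is present each layer's slope is additionally
#'   orientated by its sign, giving the unbiased `mean_oriented` estimate
#'   of the mean effect magnitude: the external sign is independent of
#'   this dataset's noise, so sign-oriented slopes average to the true
#'   magnitude without the upward folding bias that `|slope|` carries on
#'   weak effects.
#' @param layers Named list of log2-scale `omics_matrix` objects (e.g.
#'   quantile-normalized log-CPM / log-abundance), same samples.
#' @param genotypes A `variant_table`.
#' @return An `effect_profile`: list with `$profile` (tibble layer,
#'   mean_abs_effect, ci_low, ci_high, mean_abs_debiased, n_snps),
#'   `$tests` (pairwise t-test tibble) and `$effects` (per-SNP absolute
#'   slopes by layer). `mean_abs_debiased` averages the noise-deconvolved
#'   magnitude `sqrt(max(slope^2 - se^2, 0))`, the estimator to use when
#'   ratios of layer means are read as attenuation fractions; the raw
#'   mean of `|slope|` is inflated by its sampling noise on weak effects.
#' @export
external_effect_profile <- function(external_snps, layers, genotypes) {
  if (nrow(external_snps) == 0) abort("empty external QTL list")
  present <- external_snps$variant_id %in% colnames(genotypes$dosage)
  if (any(!present)) {
    inform(sprintf("dropping %d external SNP(s) absent from genotypes", sum(!present)))
    external_snps <- external_snps[present, , drop = FALSE]
  }
  if (nrow(external_snps) == 0) abort("no external SNP present in genotypes")

  has_sign <- "discovery_slope" %in% names(external_snps)
  eff <- purrr::imap(layers, function(mat, nm) {
    st <- lead_variant_stats(
      dplyr::rename(external_snps, lead_variant_id = "variant_id"),
      mat, genotypes
    )
    out <- tibble::tibble(
      pair_id = paste(st$gene_id, st$variant_id, sep = "|"),
      gene_id = st$gene_id, layer = nm, abs_effect = abs(st$slope),
      # noise-deconvolved magnitude: E[slope^2] = effect^2 + se^2, so this
      # removes the folded-|.| inflation on near-null effects
      abs_effect_debiased = sqrt(pmax(st$slope^2 - st$se^2, 0))
    )
    if (has_sign) {
      ds <- external_snps$discovery_slope[match(out$gene_id, external_snps$gene_id)]
      out$oriented_effect <- st$slope * sign(ds)
    }
    out
  })
  # keep only SNPs evaluated in every layer so the comparison is paired
  common <- Reduce(intersect, purrr::map(eff, "pair_id"))
  eff <- dplyr::bind_rows(eff) |> dplyr::filter(.data$pair_id %in% common)

  profile <- eff |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      mean_abs_effect = mean(.data$abs_effect),
      ci_low = mean(.data$abs_effect) - 1.96 * sd(.data$abs_effect) / sqrt(dplyr::n()),
      ci_high = mean(.data$abs_effect) + 1.96 * sd(.data$abs_effect) / sqrt(dplyr::n()),
      mean_abs_debiased = mean(.data$abs_effect_debiased),
      mean_oriented = if (has_sign) mean(.data$oriented_effect) else NA_real_,
      n_snps = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$layer, names(layers)))

  # pairwise contrasts use the sign-oriented effects when available
  # (same ordering, no folding bias), |slope| otherwise
  test_col <- if (has_sign) "oriented_effect" else "abs_effect"
  wide <- tidyr::pivot_wider(
    stats::setNames(eff[, c("pair_id", "layer", test_col)],
                    c("pair_id", "layer", "value")),
    names_from = "layer", values_from = "value"
  )
  tests <- purrr::map_dfr(utils::combn(names(layers), 2, simplify = FALSE), function(pr) {
    tt <- t.test(wide[[pr[[1]]]], wide[[pr[[2]]]], paired = TRUE)
    tibble::tibble(layer_a = pr[[1]], layer_b = pr[[2]], pvalue = tt$p.value)
  })
  structure(list(profile = profile, tests = tests, effects = eff),
            class = "effect_profile")
}

#' @export
print.effect_profile <- function(x, ...) {
  cat("<effect_profile> mean |per-allele effect| (log2 units)\n")
  print(x$profile)
  invisible(x)
}
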