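STAGES <- c("raw_counts", "log_cpm", "filtered", "quantile_normalized", "residualized")

#' Construct an omics quantification layer
#'
#' A thin wrapper around a sample x gene matrix carrying the omics layer
#' (mrna / ribo / protein) and the processing stage. Stages only move
#' forward through raw_counts -> log_cpm -> filtered -> quantile_normalized
#' -> residualized; protein abundances arrive already log-scale, so protein
#' layers are typically constructed at stage `"log_cpm"`.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, both
#'   dimensions named.
#' @param layer One of "mrna", "ribo", "protein".
#' @param stage One of the five processing stages.
#' @return An `omics_matrix`.
#' @export
omics_matrix <- function(values, layer = c("mrna", "ribo", "protein"),
                         stage = STAGES) {
  layer <- match.arg(layer)
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(values, layer = layer, stage = stage,
            class = c("omics_matrix", "matrix", "array"))
}

om_layer <- function(x) attr(x, "layer")
om_stage <- function(x) attr(x, "stage")

advance_stage <- function(x, new_values, new_stage) {
  if (match(new_stage, STAGES) < match(om_stage(x), STAGES)) {
    abort(sprintf("stage may not move backwards (%s -> %s)", om_stage(x), new_stage))
  }
  omics_matrix(new_values, layer = om_layer(x), stage = new_stage)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s stage=%s: %d samples x %d genes\n",
              om_layer(x), om_stage(x), nrow(x), ncol(x)))
  invisible(x)
}

#' log2 counts-per-million
#'
#' `log2((count + 0.5) / (library_size + 1) * 1e6)`, the standard
#' pseudocounted CPM used ahead of linear modelling of RNA-seq/ribo-seq
#' counts. The 0.5/1 offsets avoid log(0) while keeping the transform
#' library-size invariant.
#'
#' @param counts An `omics_matrix` at stage `raw_counts` with nonnegative
#'   counts.
#' @return An `omics_matrix` at stage `log_cpm`.
#' @export
counts_to_log_cpm <- function(counts) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (om_stage(counts) != "raw_counts") abort("input must be at stage raw_counts")
  if (any(counts < 0)) abort("counts must be nonnegative")
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    abort(sprintf("zero-total sample(s): %s",
                  paste(rownames(counts)[lib == 0], collapse = ", ")))
  }
  out <- log2((unclass(counts) + 0.5) / (lib + 1) * 1e6)
  advance_stage(counts, out, "log_cpm")
}

#' Drop genes that are mostly unexpressed
#'
#' A gene is removed iff it falls below `threshold` in strictly more than
#' `max_fraction` of samples (so a gene low in exactly 75% of samples is
#' kept at the defaults). For count layers at stage `log_cpm` the threshold
#' is on the CPM scale (default CPM < 1); for protein layers it applies
#' directly to the stored log-scale abundance.
#'
#' @param x An `omics_matrix` at stage `log_cpm`.
#' @param threshold Expression cutoff (CPM units for count layers, log units
#'   for protein).
#' @param max_fraction Maximum tolerated fraction of below-threshold samples.
#' @return Filtered `omics_matrix` at stage `filtered`, gene order preserved.
#' @export
filter_low_expression <- function(x, threshold = 1, max_fraction = 0.75) {
  stopifnot(inherits(x, "omics_matrix"))
  cut <- if (om_layer(x) %in% c("mrna", "ribo") && om_stage(x) == "log_cpm") {
    if (threshold <= 0) -Inf else log2(threshold)
  } else {
    threshold
  }
  frac_low <- colMeans(unclass(x) < cut)
  keep <- frac_low <= max_fraction
  advance_stage(x, unclass(x)[, keep, drop = FALSE], "filtered")
}

#' Flag low-connectivity outlier samples
#'
#' Connectivity of sample j is the sum over the other samples of the
#' Pearson correlation of their gene-expression profiles (signed sum).
#' Connectivities are z-scored across samples and a sample is flagged iff
#' its z falls below `z_cutoff` (conventionally -5 for RNA-seq, -3.5 for
#' ribo-seq, -6 for protein). A constant (zero-variance) sample is flagged
#' unconditionally with a warning.
#'
#' @param x An `omics_matrix` with at least 10 samples.
#' @param z_cutoff Flagging threshold in standard deviations (negative).
#' @return Character vector of flagged sample ids.
#' @export
flag_outlier_samples <- function(x, z_cutoff = -5) {
  stopifnot(inherits(x, "omics_matrix"))
  if (nrow(x) < 10) abort("need at least 10 samples for a meaningful connectivity z-score")
  v <- apply(x, 1, sd)
  const <- v == 0
  if (any(const)) {
    warn(sprintf("constant sample(s) flagged unconditionally: %s",
                 paste(rownames(x)[const], collapse = ", ")))
  }
  ok <- !const
  flags <- rownames(x)[const]
  if (sum(ok) >= 3) {
    cm <- cor(t(unclass(x)[ok, , drop = FALSE]))
    conn <- rowSums(cm) - 1
    z <- (conn - mean(conn)) / sd(conn)
    flags <- c(flags, rownames(x)[ok][z < z_cutoff])
  }
  flags
}

#' Quantile normalization across samples
#'
#' Forces every sample's value distribution onto the cross-sample mean of
#' order statistics; ties receive the mean of their would-be quantile
#' values. The computation is delegated to [limma::normalizeQuantiles()].
#'
#' @param x An `omics_matrix` with no missing values.
#' @return An `omics_matrix` at stage `quantile_normalized`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (anyNA(x)) abort("missing values must be imputed before quantile normalization")
  out <- t(limma::normalizeQuantiles(t(unclass(x)), ties = TRUE))
  dimnames(out) <- dimnames(x)
  advance_stage(x, out, "quantile_normalized")
}

#' Estimate hidden nuisance factors by principal components
#'
#' Computes the top principal components of the gene-standardized matrix as
#' surrogates for unobserved technical/biological confounders, with the
#' fraction of variance each explains. Factor scores are mutually
#' orthogonal by construction.
#'
#' @param x An `omics_matrix`.
#' @param n_factors Number of factors, `< min(n_samples - 1, n_genes)` and
#'   at most `n_samples - 2`.
#' @return A `factor_set`: list with `$factors` (sample x factor score
#'   matrix) and `$var_explained`.
#' @export
estimate_hidden_factors <- function(x, n_factors) {
  stopifnot(inherits(x, "omics_matrix"))
  n <- nrow(x); g <- ncol(x)
  if (n_factors >= min(n - 1, g) || n_factors > n - 2) {
    abort("`n_factors` too large for this matrix")
  }
  keep <- apply(x, 2, sd) > 0
  pc <- prcomp(unclass(x)[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_factors), drop = FALSE]
  rownames(scores) <- rownames(x)
  structure(list(factors = scores, var_explained = ve[seq_len(n_factors)],
                 all_var_explained = ve),
            class = "factor_set")
}

#' Elbow rule for the number of hidden factors
#'
#' Scree-gap elbow: walks down the variance-explained profile and stops at
#' the first factor whose marginal gain over the next factor falls below
#' `threshold` (default 1 percentage point); the factors before that point
#' are retained. On structureless data the profile is flat from the start
#' (neighbouring eigenvalues of a noise matrix are nearly equal), so the
#' rule retains nothing, while planted components create large gaps and
#' are kept.
#'
#' @param factors A `factor_set`.
#' @param threshold Variance-explained gap cutoff.
#' @return Integer count of factors to retain (possibly 0).
#' @export
choose_n_factors <- function(factors, threshold = 0.01) {
  ve <- factors$all_var_explained %||% factors$var_explained
  gaps <- -diff(c(ve, 0))
  flat <- which(gaps < threshold)
  if (length(flat) == 0) length(ve) else flat[[1]] - 1L
}

#' Residualize expression on nuisance factors
#'
#' Per-gene ordinary least squares of expression on the factor scores; the
#' residuals are then centered and scaled to unit standard deviation, which
#' is the form every downstream association stage consumes. Genes whose
#' residual is exactly constant (e.g. a gene equal to a factor) are dropped
#' with a warning.
#'
#' @param x An `omics_matrix`.
#' @param factors A `factor_set` on the same samples (or NULL to only
#'   center/scale).
#' @return An `omics_matrix` at stage `residualized` with per-gene mean 0
#'   and sd 1.
#' @export
residualize <- function(x, factors = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  vals <- unclass(x)
  if (!is.null(factors)) {
    f <- factors$factors
    if (!identical(rownames(f), rownames(vals))) {
      abort("factor and matrix sample ids must be aligned")
    }
    design <- cbind(`(Intercept)` = 1, f)
    if (qr(design)$rank < ncol(design)) abort("collinear factors")
    fit <- lm.fit(design, vals)
    vals <- as.matrix(fit$residuals)
  }
  sds <- apply(vals, 2, sd)
  sds[sds < 1e-10 * max(sds)] <- 0   # numerically-exact factor matches
  if (any(sds == 0)) {
    warn(sprintf("dropping %d gene(s) with zero residual variance: %s",
                 sum(sds == 0),
                 paste(head(colnames(vals)[sds == 0], 5), collapse = ", ")))
    vals <- vals[, sds > 0, drop = FALSE]
  }
  vals <- scale(vals)
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  advance_stage(x, vals, "residualized")
}

#' Pick one representative protein isoform per gene
#'
#' Keeps, for each gene, the isoform with the highest median abundance
#' across samples; median ties break lexicographically by isoform id for
#' determinism. Isoforms absent from the mapping are dropped with a warning.
#'
#' @param protein An `omics_matrix` whose columns are isoform ids.
#' @param isoform_to_gene Data frame with columns `isoform_id`, `gene_id`;
#'   every isoform maps to exactly one gene.
#' @return An `omics_matrix` with one column per gene (named by gene id).
#' @export
select_representative_isoform <- function(protein, isoform_to_gene) {
  stopifnot(inherits(protein, "omics_matrix"))
  map <- tibble::as_tibble(isoform_to_gene)
  if (anyDuplicated(map$isoform_id)) abort("each isoform must map to exactly one gene")
  unmapped <- setdiff(colnames(protein), map$isoform_id)
  if (length(unmapped) > 0) {
    warn(sprintf("dropping %d unmapped isoform(s): %s", length(unmapped),
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  meds <- apply(protein, 2, median)
  pick <- tibble::tibble(isoform_id = colnames(protein), med = meds) |>
    dplyr::inner_join(map, by = "isoform_id") |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$med), .data$isoform_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  out <- unclass(protein)[, pick$isoform_id, drop = FALSE]
  colnames(out) <- pick$gene_id
  omics_matrix(out, layer = om_layer(protein), stage = om_stage(protein))
}

#' Full preprocessing of one quantification layer
#'
#' Convenience wrapper chaining log-CPM (count layers only), low-expression
#' filtering, outlier-sample removal, quantile normalization, hidden-factor
#' estimation and residualization.
#'
#' @param x An `omics_matrix` at stage `raw_counts` (mrna/ribo) or
#'   `log_cpm` (protein).
#' @param n_factors Hidden factors to remove; `NULL` selects by
#'   [choose_n_factors()].
#' @param z_cutoff Connectivity z-score cutoff for sample outliers.
#' @param cpm_threshold,max_low_fraction Passed to [filter_low_expression()].
#' @return List with `$matrix` (residualized `omics_matrix`), `$factors`
#'   (the `factor_set` removed), `$flagged_samples`.
#' @export
preprocess_layer <- function(x, n_factors = NULL, z_cutoff = -5,
                             cpm_threshold = 1, max_low_fraction = 0.75) {
  if (om_stage(x) == "raw_counts") x <- counts_to_log_cpm(x)
  x <- filter_low_expression(x, cpm_threshold, max_low_fraction)
  flagged <- flag_outlier_samples(x, z_cutoff)
  if (length(flagged) > 0) {
    x <- advance_stage(x, unclass(x)[setdiff(rownames(x), flagged), , drop = FALSE],
                       om_stage(x))
  }
  x <- quantile_normalize(x)
  k <- n_factors %||% {
    probe <- estimate_hidden_factors(x, min(20L, nrow(x) - 2L, ncol(x) - 1L))
    max(1L, choose_n_factors(probe))
  }
  fs <- estimate_hidden_factors(x, k)
  list(matrix = residualize(x, fs), factors = fs, flagged_samples = flagged)
}
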