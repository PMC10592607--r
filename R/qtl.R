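#' Cis windows around annotated genes
#'
#' The cis region of a gene runs from `window` bp upstream of its start to
#' `window` bp downstream of its end (1-based inclusive, clamped at 1), so
#' the window length is gene length + 2 Mb at the default.
#'
#' @param annotation Tibble with gene_id, chrom, start, end.
#' @param window Flank size in bp (default 1 Mb).
#' @return Tibble gene_id, chrom, start, end.
#' @export
cis_windows <- function(annotation, window = 1e6) {
  dplyr::transmute(
    tibble::as_tibble(annotation),
    gene_id = .data$gene_id, chrom = .data$chrom,
    start = pmax(1, .data$start - window),
    end = .data$end + window
  )
}

# variant indices falling in a gene's cis window after the MAF filter
cis_variant_idx <- function(genotypes, win, maf_min = 0.05) {
  v <- genotypes$variants
  emaf <- empirical_maf(genotypes$dosage)
  which(v$chrom == win$chrom & v$pos >= win$start & v$pos <= win$end &
          emaf > maf_min)
}

#' Per-variant nominal cis association scan
#'
#' Simple linear regression of a residualized expression vector on each
#' common variant (empirical MAF > `maf_min`) in the gene's cis window,
#' with two-sided t-test p-values.
#'
#' @param window One-row tibble from [cis_windows()].
#' @param genotypes A `variant_table`.
#' @param expression Named numeric vector, residualized expression, sample
#'   order matching the dosage rows.
#' @param maf_min Minor-allele frequency filter (strict >).
#' @return Tibble variant_id, slope, se, pvalue, maf; zero rows (with a
#'   message) if no variant survives.
#' @export
nominal_scan <- function(window, genotypes, expression, maf_min = 0.05) {
  idx <- cis_variant_idx(genotypes, window, maf_min)
  if (length(idx) == 0) {
    inform(sprintf("no cis variants for gene %s; skipped", window$gene_id))
    return(tibble::tibble(variant_id = character(), slope = numeric(),
                          se = numeric(), pvalue = numeric(), maf = numeric()))
  }
  dos <- genotypes$dosage[, idx, drop = FALSE]
  st <- marginal_summary_stats(dos, expression)
  tibble::tibble(variant_id = st$variant_id, slope = st$beta, se = st$se,
                 pvalue = st$pvalue, maf = empirical_maf(dos))
}

# fit Beta(a, b) to permutation minimum p-values by maximum likelihood
# (L-BFGS-B, method-of-moments start); NULL on degenerate input/failure
fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  if (sd(x) == 0) return(NULL)
  m <- mean(x); v <- var(x)
  k <- m * (1 - m) / v - 1
  start <- c(max(m * k, 1e-3), max((1 - m) * k, 1e-3))
  nll <- function(par) -sum(dbeta(x, par[[1]], par[[2]], log = TRUE))
  fit <- tryCatch(
    optim(start, nll, method = "L-BFGS-B", lower = c(1e-4, 1e-4)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$convergence != 0) return(NULL)
  fit$par
}

#' Permutation pass for one gene
#'
#' Permutes the expression vector `n_perm` times (genotypes are left intact
#' so LD is preserved), records the minimum nominal p-value of each
#' permutation scan, fits a Beta distribution to the minima by maximum
#' likelihood, and evaluates the observed minimum p at the fitted Beta CDF
#' to obtain a smooth gene-level empirical p-value. If the Beta fit
#' degenerates the direct permutation rank `(r + 1) / (n_perm + 1)` is used
#' with a warning. The lead variant is the one with the smallest nominal p.
#'
#' @inheritParams nominal_scan
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @return One-row tibble: gene_id, lead_variant_id, slope, slope_se,
#'   nominal_p, beta_shape1, beta_shape2, empirical_p, rank_p,
#'   n_variants_tested.
#' @export
permutation_pass <- function(window, genotypes, expression, n_perm = 1000,
                             seed = 1L, maf_min = 0.05) {
  scan <- nominal_scan(window, genotypes, expression, maf_min)
  if (nrow(scan) == 0) return(NULL)
  lead <- which.min(scan$pvalue)
  obs_min <- scan$pvalue[[lead]]

  idx <- match(scan$variant_id, colnames(genotypes$dosage))
  xs <- scale(genotypes$dosage[, idx, drop = FALSE])
  n <- length(expression)
  set.seed(seed)
  perm <- matrix(0, n, n_perm)
  for (j in seq_len(n_perm)) perm[, j] <- expression[sample.int(n)]
  ys <- scale(perm)
  r <- crossprod(xs, ys) / (n - 1)              # variants x permutations
  r2max <- apply(r^2, 2, max)
  tmax <- sqrt(r2max * (n - 2) / pmax(1 - r2max, 1e-12))
  minp <- t_pvalue(tmax, n - 2)

  rank_p <- (sum(minp <= obs_min) + 1) / (n_perm + 1)
  ab <- fit_beta_ml(minp)
  if (is.null(ab)) {
    warn(sprintf("gene %s: degenerate beta fit, using direct permutation rank",
                 window$gene_id))
    emp <- rank_p; ab <- c(NA_real_, NA_real_)
  } else {
    emp <- pbeta(obs_min, ab[[1]], ab[[2]])
  }
  tibble::tibble(
    gene_id = window$gene_id,
    lead_variant_id = scan$variant_id[[lead]],
    slope = scan$slope[[lead]], slope_se = scan$se[[lead]],
    nominal_p = obs_min,
    beta_shape1 = ab[[1]], beta_shape2 = ab[[2]],
    empirical_p = emp, rank_p = rank_p,
    n_variants_tested = nrow(scan)
  )
}

#' Storey q-values and the null proportion pi0
#'
#' Estimates pi0 on the lambda grid (`mean(p > lambda) / (1 - lambda)`),
#' smooths the estimates with a cubic spline and takes the value at the
#' largest lambda, clipped to (0, 1]; q-values are the rank-monotone
#' `pi0 * m * p / rank` minima.
#'
#' @param pvalues Vector of p-values in 0..1 (>= 100 recommended; fewer
#'   draws a warning about unstable smoothing).
#' @param lambda_grid Grid for the pi0 estimate.
#' @return List with `$qvalues` and `$pi0`.
#' @export
storey_qvalues <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  if (m < 100) warn("fewer than 100 p-values: pi0 smoothing is unstable")
  pi0 <- storey_pi0(pvalues, lambda_grid)
  o <- order(pvalues, decreasing = TRUE)
  q <- rep(NA_real_, m)
  q[o] <- cummin(pi0 * m * pvalues[o] / rank(pvalues, ties.method = "max")[o])
  q <- pmin(q, 1)
  list(qvalues = q, pi0 = pi0)
}

storey_pi0 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  m <- length(pvalues)
  if (all(pvalues == 1)) return(1)
  pi0_l <- vapply(lambda_grid, function(l) mean(pvalues > l) / (1 - l), numeric(1))
  pi0 <- if (length(lambda_grid) >= 4 && sd(pi0_l) > 0) {
    # weight grid points by the precision of their tail estimate
    # (var of pi0(lambda) scales like 1/(1 - lambda)); stabilizes the
    # extrapolation to max lambda on short p-vectors
    sp <- smooth.spline(lambda_grid, pi0_l, w = 1 - lambda_grid, df = 3)
    predict(sp, x = max(lambda_grid))$y
  } else {
    pi0_l[[length(pi0_l)]]
  }
  min(max(pi0, 1e-8), 1)
}

#' Map cis-QTLs on every layer
#'
#' Runs the permutation pass for each gene of each residualized layer,
#' computes Storey q-values per layer across genes, and marks the
#' significant set at `qvalue < fdr`. Per-gene permutation seeds are derived
#' deterministically from `seed`.
#'
#' @param layers Named list of residualized `omics_matrix` objects (any
#'   subset of mrna/ribo/protein) sharing the same samples.
#' @param genotypes A `variant_table` on the same samples.
#' @param annotation Gene annotation tibble (gene_id, chrom, start, end).
#' @param n_perm Permutations per gene.
#' @param fdr Study-wide FDR cutoff on the Storey q-value.
#' @param maf_min MAF filter.
#' @param seed Master seed.
#' @return A `qtl_result` tibble: one row per gene x layer with lead
#'   variant, slopes, beta-approximation parameters, empirical and rank
#'   p-values, qvalue and `significant`.
#' @export
map_cis_qtls <- function(layers, genotypes, annotation, n_perm = 1000,
                         fdr = 0.1, maf_min = 0.05, seed = 1L) {
  stopifnot(is.list(layers), length(layers) >= 1)
  samp <- rownames(layers[[1]])
  for (ly in layers) {
    if (!identical(rownames(ly), samp)) abort("sample ids differ across layers")
  }
  if (!identical(samp, rownames(genotypes$dosage))) {
    abort("sample ids differ between layers and genotypes")
  }
  if (nrow(annotation) == 0) {
    return(empty_qtl_result())
  }
  wins <- cis_windows(annotation)
  out <- purrr::imap(layers, function(mat, layer_name) {
    genes <- intersect(wins$gene_id, colnames(mat))
    rows <- purrr::map(seq_along(genes), function(i) {
      g <- genes[[i]]
      win <- wins[wins$gene_id == g, ]
      permutation_pass(win, genotypes, mat[, g],
                       n_perm = n_perm,
                       seed = derive_seed(seed, i * 131L + match(layer_name, names(layers))),
                       maf_min = maf_min)
    })
    res <- dplyr::bind_rows(rows)
    if (nrow(res) == 0) return(res)
    res$layer <- layer_name
    st <- storey_qvalues(res$empirical_p)
    res$qvalue <- st$qvalues
    res$pi0 <- st$pi0
    res
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_qtl_result())
  res$significant <- res$qvalue < fdr
  res <- dplyr::relocate(res, "gene_id", "layer")
  class(res) <- c("qtl_result", class(res))
  res
}

empty_qtl_result <- function() {
  res <- tibble::tibble(
    gene_id = character(), layer = character(), lead_variant_id = character(),
    slope = numeric(), slope_se = numeric(), nominal_p = numeric(),
    beta_shape1 = numeric(), beta_shape2 = numeric(), empirical_p = numeric(),
    rank_p = numeric(), n_variants_tested = integer(), qvalue = numeric(),
    pi0 = numeric(), significant = logical()
  )
  class(res) <- c("qtl_result", class(res))
  res
}

#' @importFrom stats dbeta
NULL
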