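#' Simulate common biallelic genotypes with block LD
#'
#' Draws alt-allele dosages for `n_samples` individuals at `n_variants` sites.
#' Haplotypes come from a latent Gaussian copula: within each block of
#' `ld_block_size` consecutive variants the latent variables share pairwise
#' correlation `ld_rho`, and each haplotype allele is the indicator that its
#' latent variable exceeds the normal quantile of `1 - maf`. Summing two
#' independent haplotypes per individual yields Hardy-Weinberg genotype
#' frequencies at every site while preserving the block correlation, which is
#' the minimal LD structure needed to exercise clumping and colocalization.
#'
#' @param n_samples Number of individuals (>= 30; smaller cohorts make the
#'   downstream per-gene regressions unidentifiable).
#' @param n_variants Number of variant sites.
#' @param maf_low,maf_high Bounds of the uniform distribution the per-variant
#'   minor-allele frequency is drawn from; must satisfy
#'   `0.05 <= maf_low <= maf_high <= 0.5`.
#' @param ld_block_size Number of consecutive variants per LD block.
#' @param ld_rho Latent pairwise correlation within a block, in `[0, 1)`.
#' @param chrom Chromosome name stamped on all variants.
#' @param pos_spacing Two-element range of the inter-variant spacing in bp
#'   (uniformly drawn); controls how many variants a +-1 Mb cis window
#'   holds.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A `variant_table`: a list with `$variants`, a tibble of
#'   variant_id/chrom/pos/ref/alt/maf, and `$dosage`, a sample x variant
#'   matrix of alt-allele counts in 0..2. Simulation parameters are kept as
#'   attributes so an independent cohort with the same allele frequencies and
#'   LD structure can be drawn later (see [simulate_gwas()]).
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_low = 0.05, maf_high = 0.5,
                               ld_block_size = 10, ld_rho = 0.7,
                               chrom = "1", pos_spacing = c(500, 5000),
                               seed = 1L) {
  if (n_samples < 30) {
    abort("`n_samples` must be at least 30: downstream regressions are unidentifiable below that")
  }
  if (!(maf_low >= 0.05 && maf_low <= maf_high && maf_high <= 0.5)) {
    abort("need 0.05 <= maf_low <= maf_high <= 0.5")
  }
  if (ld_rho < 0 || ld_rho >= 1) abort("`ld_rho` must be in [0, 1)")
  set.seed(seed)

  maf <- runif(n_variants, maf_low, maf_high)
  pos <- cumsum(sample(pos_spacing[[1]]:pos_spacing[[2]], n_variants,
                       replace = TRUE))
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_variants, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1)))

  block <- rep(seq_len(ceiling(n_variants / ld_block_size)),
               each = ld_block_size)[seq_len(n_variants)]
  thr <- qnorm(1 - maf)

  draw_haplotype <- function() {
    z <- matrix(rnorm(n_samples * n_variants), n_samples, n_variants)
    if (ld_rho > 0 && ld_block_size > 1) {
      shared <- matrix(rnorm(n_samples * max(block)), n_samples)
      z <- sqrt(ld_rho) * shared[, block, drop = FALSE] + sqrt(1 - ld_rho) * z
    }
    sweep(z, 2, thr, ">") * 1L
  }
  dosage <- draw_haplotype() + draw_haplotype()

  # redraw any monomorphic column independently; keeps the declared MAF
  mono <- which(apply(dosage, 2, function(x) length(unique(x)) == 1L))
  for (j in mono) {
    repeat {
      col <- rbinom(n_samples, 2L, maf[j])
      if (length(unique(col)) > 1L) break
    }
    dosage[, j] <- col
  }

  variant_id <- sprintf("v%05d", seq_len(n_variants))
  dimnames(dosage) <- list(sprintf("S%03d", seq_len(n_samples)), variant_id)

  structure(
    list(
      variants = tibble::tibble(variant_id = variant_id, chrom = chrom,
                                pos = pos, ref = ref, alt = alt, maf = maf),
      dosage = dosage
    ),
    class = "variant_table",
    sim_params = list(maf = maf, ld_block_size = ld_block_size,
                      ld_rho = ld_rho, block = block, seed = seed)
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d samples x %d variants, chrom %s\n",
              nrow(x$dosage), ncol(x$dosage), x$variants$chrom[[1]]))
  print(head(x$variants, 5))
  invisible(x)
}

#' Ground-truth parameters for a simulated molecular cascade
#'
#' One row per gene. `beta` is the per-allele cis effect on (log2) mRNA;
#' `lambda_r` and `lambda_p` in `[0, 1]` attenuate that effect at the
#' ribosome-occupancy and protein layers; `gamma_r` / `gamma_p` are genetic
#' effects arising only at those layers (omics-specific signal); `causal_for_outcome`
#' marks genes whose protein genetic component drives the simulated GWAS
#' trait; `pleiotropy_effect` is a direct variant-to-outcome effect bypassing
#' expression. Hidden-factor loadings per layer are stored as matrix
#' attributes (`loadings_mrna` etc.) so the preprocessing stage has real
#' confounding to remove.
#'
#' The implied per-allele genetic slopes are `beta` (mRNA),
#' `lambda_r * beta + gamma_r` (ribo) and
#' `lambda_p * (lambda_r * beta + gamma_r) + gamma_p` (protein): setting both
#' lambdas to 1 with zero gamma reproduces identical effects at all layers,
#' and `lambda_r = 0` erases all mRNA-derived signal downstream.
#'
#' @param n_genes Number of genes.
#' @param beta Per-allele mRNA effect(s) in log2 units, recycled. The
#'   default `NULL` draws a sparse mixture: a fraction `prop_qtl` of genes
#'   get an effect from N(0, 0.45^2) and the rest are exactly null, giving
#'   a cohort where roughly half the genes carry a detectable cis effect —
#'   the regime bulk brain cohorts sit in. Pass a constant for fully
#'   controlled designs.
#' @param prop_qtl Fraction of genes with a nonzero cis effect when `beta`
#'   is drawn by default.
#' @param lambda_r,lambda_p Attenuation fractions in `[0, 1]`, recycled.
#'   The default `NULL` models all-or-none buffering: a gene either
#'   propagates its upstream genetic effect fully (lambda = 1) or is
#'   completely buffered (lambda = 0), with 25% of genes buffered at the
#'   ribosome layer and 20% at the protein layer, so the mean attenuation
#'   is exactly 0.75 and 0.8. Buffering is assigned within strata of
#'   |beta| rank (balanced sampling), so any effect-size-selected gene
#'   subset carries the same buffered fraction — the aggregate effect
#'   ratio of a discovered-QTL subset is then a stable estimate of the
#'   mean attenuation. Pass scalars or per-gene vectors for other
#'   designs.
#' @param gamma_r,gamma_p Layer-specific genetic effects, recycled.
#' @param causal_for_outcome Logical flag(s), recycled.
#' @param pleiotropy_effect Direct variant->outcome effect(s), recycled.
#' @param noise_sd Length-3 (or recyclable) vector of residual standard
#'   deviations for the mrna/ribo/protein layers, log2 units. The default
#'   hierarchy (0.7 < 1.0 < 1.2) mirrors the measurement precision of the
#'   three assays: RNA-seq is the cleanest, ribosome profiling loses most
#'   reads to rRNA/tRNA contamination, and label-free mass spectrometry is
#'   noisier still — which is why downstream layers yield far fewer QTLs
#'   at equal sample size.
#' @param n_factors Number of shared hidden factors.
#' @param factor_sd Standard deviation of the factor loadings; 0 disables
#'   confounding.
#' @param seed Seed for the loading draws.
#' @return A `cascade_truth` tibble.
#' @export
cascade_truth <- function(n_genes,
                          beta = NULL, prop_qtl = 0.45,
                          lambda_r = NULL, lambda_p = NULL,
                          gamma_r = 0, gamma_p = 0,
                          causal_for_outcome = FALSE,
                          pleiotropy_effect = 0,
                          noise_sd = c(mrna = 0.7, ribo = 1.0, protein = 1.2),
                          n_factors = 5, factor_sd = 0.3,
                          seed = 1L) {
  set.seed(seed)
  beta <- beta %||% (rnorm(n_genes, 0, 0.45) * (runif(n_genes) < prop_qtl))
  # all-or-none buffering with the four joint categories (unbuffered at
  # both layers / ribo-only / protein-only / both) assigned in exact
  # proportions within each |beta|-rank stratum of 20 genes, so any
  # effect-size-selected subset carries E[lambda_r] = 0.75 and
  # E[lambda_p | lambda_r = 1] = 0.8 essentially exactly
  if (is.null(lambda_r) || is.null(lambda_p)) {
    lam_r <- rep(1, n_genes); lam_p <- rep(1, n_genes)
    strata <- split(order(abs(rep_len(beta, n_genes))),
                    ceiling(seq_len(n_genes) / 20))
    for (s in strata) {
      m <- length(s)
      n11 <- round(m * 0.6); n10 <- round(m * 0.15); n01 <- round(m * 0.2)
      cat_ <- rep(c("uu", "up", "pu", "pp"),
                  c(n11, n10, n01, max(m - n11 - n10 - n01, 0)))[seq_len(m)]
      cat_ <- sample(cat_)
      lam_r[s[cat_ %in% c("pu", "pp")]] <- 0
      lam_p[s[cat_ %in% c("up", "pp")]] <- 0
    }
    lambda_r <- lambda_r %||% lam_r
    lambda_p <- lambda_p %||% lam_p
  }
  if (any(lambda_r < 0 | lambda_r > 1) || any(lambda_p < 0 | lambda_p > 1)) {
    abort("attenuation parameters `lambda_r`, `lambda_p` must lie in [0, 1]")
  }
  noise_sd <- rep_len(noise_sd, 3L)
  tr <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    beta = rep_len(beta, n_genes),
    lambda_r = rep_len(lambda_r, n_genes),
    lambda_p = rep_len(lambda_p, n_genes),
    gamma_r = rep_len(gamma_r, n_genes),
    gamma_p = rep_len(gamma_p, n_genes),
    causal_for_outcome = rep_len(causal_for_outcome, n_genes),
    pleiotropy_effect = rep_len(pleiotropy_effect, n_genes),
    noise_sd_mrna = noise_sd[[1]],
    noise_sd_ribo = noise_sd[[2]],
    noise_sd_protein = noise_sd[[3]]
  )
  tr$slope_mrna <- tr$beta
  tr$slope_ribo <- tr$lambda_r * tr$beta + tr$gamma_r
  tr$slope_protein <- tr$lambda_p * tr$slope_ribo + tr$gamma_p
  for (ly in c("mrna", "ribo", "protein")) {
    attr(tr, paste0("loadings_", ly)) <-
      matrix(rnorm(n_genes * n_factors, sd = factor_sd), n_genes, n_factors)
  }
  attr(tr, "n_factors") <- n_factors
  class(tr) <- c("cascade_truth", class(tr))
  tr
}

#' Simulate a three-layer molecular cascade from genotypes and ground truth
#'
#' Each gene is assigned one causal cis variant (cycling through the variant
#' panel) and an annotation window containing it. A shared latent linear
#' predictor propagates the genetic effect down the layers with the
#' attenuation and specificity structure in `truth` plus shared hidden
#' factors. mRNA and ribosome occupancy are emitted as negative-binomial
#' counts whose log2 mean equals the linear predictor (so log-CPM recovers
#' it); protein is emitted directly on the log2 scale, mirroring mass-spec
#' abundances.
#'
#' @param genotypes A `variant_table`.
#' @param truth A `cascade_truth` with as many genes as should be emitted.
#' @param nb_size Negative-binomial size (inverse overdispersion) for the
#'   count layers.
#' @param base_log2_range Range of per-gene baseline log2 expression.
#' @param gamma_variant_offset Index offset (in variants) of the cis
#'   variant carrying the layer-specific `gamma` effects. The default 0
#'   puts them on the gene's causal variant; a nonzero offset models an
#'   independent cis regulatory variant (e.g. a protein-specific signal in
#'   a different LD block), which is what makes a gene separable as
#'   omics-specific by conditional imputation.
#' @param seed Integer seed.
#' @return A `cascade_sim` list: `$mrna`, `$ribo` (raw-count
#'   [omics_matrix()]s), `$protein` (log2-scale), `$annotation` (tibble of
#'   gene_id/chrom/start/end/strand), `$truth` (realized truth including the
#'   causal `variant_id`), `$factors` (the true hidden-factor scores).
#' @export
simulate_cascade <- function(genotypes, truth, nb_size = 60,
                             base_log2_range = c(8, 13),
                             gamma_variant_offset = 0L, seed = 1L) {
  stopifnot(inherits(genotypes, "variant_table"), inherits(truth, "cascade_truth"))
  set.seed(derive_seed(seed, 1L))
  n_genes <- nrow(truth)
  dosage <- genotypes$dosage
  n <- nrow(dosage)
  n_var <- ncol(dosage)

  # spread genes evenly along the variant panel so neighbouring genes do
  # not share an LD block unless the panel is dense
  spacing <- max(1L, n_var %/% n_genes)
  causal_idx <- (((seq_len(n_genes) - 1L) * spacing) %% n_var) + 1L
  gamma_idx <- ((causal_idx - 1L + gamma_variant_offset) %% n_var) + 1L
  truth$variant_id <- genotypes$variants$variant_id[causal_idx]
  truth$gamma_variant_id <- genotypes$variants$variant_id[gamma_idx]
  cpos <- genotypes$variants$pos[causal_idx]

  annotation <- tibble::tibble(
    gene_id = truth$gene_id,
    chrom = genotypes$variants$chrom[[1]],
    start = pmax(1L, cpos - 1000L),
    end = cpos + 1000L,
    strand = "+"
  )

  k <- attr(truth, "n_factors")
  fac <- matrix(rnorm(n * k), n, k,
                dimnames = list(rownames(dosage), sprintf("F%d", seq_len(k))))
  gc_mat <- scale(dosage[, causal_idx, drop = FALSE], scale = FALSE) # centered dosage
  gg_mat <- scale(dosage[, gamma_idx, drop = FALSE], scale = FALSE)
  base <- runif(n_genes, base_log2_range[[1]], base_log2_range[[2]])
  samp_offset <- rnorm(n, sd = 0.2) # library-size wobble, log2 units

  # each large random block gets its own well-separated RNG state, so no
  # residual cross-stream correlation with the genotype draw can leak a
  # spurious genetic signal into a layer's noise
  layer_pred <- function(slope, loadings, noise_sd, block_seed) {
    set.seed(derive_seed(seed, block_seed))
    sweep(gc_mat, 2, slope, "*") + fac %*% t(loadings) +
      matrix(rnorm(n * n_genes, sd = rep(noise_sd, each = n)), n, n_genes)
  }
  emit_counts <- function(pred, block_seed) {
    set.seed(derive_seed(seed, block_seed))
    mu <- 2^(sweep(sweep(pred, 2, base, "+"), 1, samp_offset, "+"))
    cnt <- matrix(rnbinom(n * n_genes, mu = mu, size = nb_size), n, n_genes,
                  dimnames = list(rownames(dosage), truth$gene_id))
    cnt
  }

  # the lambda-propagated component rides on the causal variant; the
  # layer-specific gamma component rides on the (possibly distinct)
  # gamma variant
  pred_m <- layer_pred(truth$slope_mrna, attr(truth, "loadings_mrna"),
                       truth$noise_sd_mrna, 101L)
  pred_r <- layer_pred(truth$lambda_r * truth$beta, attr(truth, "loadings_ribo"),
                       truth$noise_sd_ribo, 102L) +
    sweep(gg_mat, 2, truth$gamma_r, "*")
  pred_p <- layer_pred(truth$lambda_p * truth$lambda_r * truth$beta,
                       attr(truth, "loadings_protein"),
                       truth$noise_sd_protein, 103L) +
    sweep(gg_mat, 2, truth$lambda_p * truth$gamma_r + truth$gamma_p, "*")

  prot <- sweep(pred_p, 2, base / 2 + 2, "+") # log2 abundances, arbitrary baseline
  dimnames(prot) <- list(rownames(dosage), truth$gene_id)

  structure(
    list(
      mrna = omics_matrix(emit_counts(pred_m, 201L), layer = "mrna", stage = "raw_counts"),
      ribo = omics_matrix(emit_counts(pred_r, 202L), layer = "ribo", stage = "raw_counts"),
      protein = omics_matrix(prot, layer = "protein", stage = "log_cpm"),
      annotation = annotation,
      truth = truth,
      factors = fac
    ),
    class = "cascade_sim"
  )
}

#' Simulate GWAS summary statistics on an independent cohort
#'
#' Draws a fresh genotype cohort with the same allele frequencies and LD
#' structure as `genotypes` (so two-sample MR assumptions hold by
#' construction), builds a continuous liability as the sum of causal genes'
#' protein-layer genetic components plus direct pleiotropy effects, scales
#' environmental noise so the genetic component explains `outcome_h2` of the
#' variance, and returns per-variant marginal regression summary statistics.
#'
#' @param genotypes The QTL-cohort `variant_table` (provides the variant panel).
#' @param truth Realized `cascade_truth` (must carry `variant_id`, i.e. come
#'   from [simulate_cascade()]).
#' @param outcome_h2 Heritability of the liability, in (0, 1).
#' @param n_gwas GWAS cohort size.
#' @param seed Integer seed.
#' @return A `gwas_summary` tibble: variant_id, effect_allele (alt),
#'   other_allele (ref), beta, se, zscore, pvalue, n.
#' @export
simulate_gwas <- function(genotypes, truth, outcome_h2 = 0.3,
                          n_gwas = 5000, seed = 1L) {
  stopifnot(inherits(genotypes, "variant_table"))
  if (outcome_h2 <= 0 || outcome_h2 >= 1) abort("`outcome_h2` must be in (0, 1)")
  if (is.null(truth$variant_id)) {
    abort("`truth` must be the realized truth returned by simulate_cascade()")
  }
  if (!any(truth$causal_for_outcome) && all(truth$pleiotropy_effect == 0)) {
    abort("no gene is causal_for_outcome and no pleiotropy_effect is nonzero: the liability would be pure noise")
  }
  # fresh cohort with the original per-variant MAFs and LD blocks
  sp <- attr(genotypes, "sim_params")
  thr <- qnorm(1 - sp$maf)
  set.seed(derive_seed(seed, 11L))
  hap <- function() {
    z <- matrix(rnorm(n_gwas * length(thr)), n_gwas)
    if (sp$ld_rho > 0 && sp$ld_block_size > 1) {
      shared <- matrix(rnorm(n_gwas * max(sp$block)), n_gwas)
      z <- sqrt(sp$ld_rho) * shared[, sp$block, drop = FALSE] +
        sqrt(1 - sp$ld_rho) * z
    }
    sweep(z, 2, thr, ">") * 1L
  }
  dos <- hap() + hap()
  colnames(dos) <- genotypes$variants$variant_id

  causal <- truth[truth$causal_for_outcome, , drop = FALSE]
  genetic <- rep(0, n_gwas)
  if (nrow(causal) > 0) {
    idx <- match(causal$variant_id, colnames(dos))
    genetic <- genetic +
      scale(dos[, idx, drop = FALSE], scale = FALSE) %*% causal$slope_protein
  }
  pleio <- truth[truth$pleiotropy_effect != 0, , drop = FALSE]
  if (nrow(pleio) > 0) {
    idx <- match(pleio$variant_id, colnames(dos))
    genetic <- genetic +
      scale(dos[, idx, drop = FALSE], scale = FALSE) %*% pleio$pleiotropy_effect
  }
  genetic <- drop(genetic)
  vg <- var(genetic)
  noise_sd <- if (vg > 0) sqrt(vg * (1 - outcome_h2) / outcome_h2) else 1
  y <- genetic + rnorm(n_gwas, sd = noise_sd)

  marginal_summary_stats(dos, y, ptype = "normal") |>
    dplyr::left_join(
      genotypes$variants[, c("variant_id", "ref", "alt")],
      by = "variant_id"
    ) |>
    dplyr::transmute(
      variant_id = .data$variant_id,
      effect_allele = .data$alt, other_allele = .data$ref,
      beta = .data$beta, se = .data$se, zscore = .data$zscore,
      pvalue = .data$pvalue, n = .data$n
    ) |>
    structure(class = c("gwas_summary", class(tibble::tibble())))
}

# vectorized per-variant simple regression of y on each dosage column;
# ptype "normal" matches the convention of GWAS summary files (p is the
# two-sided normal tail of z), "t" gives the finite-sample t test
marginal_summary_stats <- function(dosage, y, ptype = c("t", "normal")) {
  ptype <- match.arg(ptype)
  n <- length(y)
  xc <- scale(dosage, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  z <- beta / se
  p <- if (ptype == "normal") 2 * pnorm(-abs(z)) else t_pvalue(z, n - 2)
  tibble::tibble(
    variant_id = colnames(dosage),
    beta = unname(beta), se = unname(se), zscore = unname(z),
    pvalue = unname(p), n = n
  )
}

#' Subset a variant table to a set of samples
#'
#' @param genotypes A `variant_table`.
#' @param sample_ids Character vector of sample ids to keep (order kept).
#' @return A `variant_table` on those samples.
#' @export
subset_samples <- function(genotypes, sample_ids) {
  stopifnot(inherits(genotypes, "variant_table"))
  missing <- setdiff(sample_ids, rownames(genotypes$dosage))
  if (length(missing) > 0) {
    abort(sprintf("samples absent from genotypes: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  out <- genotypes
  out$dosage <- genotypes$dosage[sample_ids, , drop = FALSE]
  out
}
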