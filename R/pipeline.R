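#' Default pipeline configuration
#'
#' All thresholds of the analysis in one list: QTL FDR 0.1, colocalization
#' PPH4 0.7, TWAS FWER 0.05, rc2 bounds 0.5/0.9, clumping 1000 kb / r2 0.5,
#' permutation counts (QTL mapping and rc2 null) and the master seed from
#' which every stage derives its own seed deterministically.
#'
#' @param seed Master seed.
#' @param n_samples,n_genes,n_variants,n_gwas Synthetic-cohort sizes.
#' @param n_perm_qtl,n_perm_rc2 Permutation counts.
#' @param fdr,pph4,fwer,rc2_shared,rc2_specific,clump_kb,clump_r2 Thresholds.
#' @param stages Character vector of stages to run, in order.
#' @return A named list.
#' @export
pipeline_config <- function(seed = 1L, n_samples = 185, n_genes = 50,
                            n_variants = 400, n_gwas = 5000,
                            n_perm_qtl = 1000, n_perm_rc2 = 50,
                            fdr = 0.1, pph4 = 0.7, fwer = 0.05,
                            rc2_shared = 0.5, rc2_specific = 0.9,
                            clump_kb = 1000, clump_r2 = 0.5,
                            stages = c("simulate", "preprocess", "map_qtl",
                                       "attenuation", "specificity", "coloc",
                                       "twas", "mr")) {
  as.list(environment())
}

#' Run the full cascade analysis on a synthetic cohort
#'
#' Simulates genotypes, the three-layer cascade and a GWAS, preprocesses
#' each layer, maps cis-QTLs, computes the replication/attenuation
#' summaries, calls shared and omics-specific genes, colocalizes the
#' significant QTL genes with the GWAS, runs the TWAS, and the two-sample
#' and one-sample MR cascade. Stage outputs are written as TSV under
#' `out_dir` together with a JSON manifest recording the seed, per-stage
#' row counts and file checksums; reruns with the same config are
#' bit-identical for the deterministic stages.
#'
#' @param config A [pipeline_config()] list.
#' @param out_dir Output directory (created if missing); NULL skips
#'   writing.
#' @return Invisible list of all stage results plus `$manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  ck <- function(stage) stage %in% config$stages
  res <- list()
  seed <- config$seed

  if (!ck("simulate")) abort("the synthetic pipeline needs the simulate stage")
  geno <- simulate_genotypes(config$n_samples, config$n_variants,
                             seed = derive_seed(seed, 1L))
  truth <- cascade_truth(config$n_genes,
                         causal_for_outcome = c(TRUE, rep(FALSE, config$n_genes - 1L)),
                         seed = derive_seed(seed, 2L))
  sim <- simulate_cascade(geno, truth, seed = derive_seed(seed, 3L))
  gwas <- simulate_gwas(geno, sim$truth, n_gwas = config$n_gwas,
                        seed = derive_seed(seed, 4L))
  res$genotypes <- geno; res$sim <- sim; res$gwas <- gwas

  if (!ck("preprocess")) {
    abort("downstream stages need the preprocess stage; enable it in `config$stages`")
  }
  k_fac <- max(1L, min(5L, config$n_samples - 2L, config$n_genes - 2L))
  prep <- purrr::imap(list(mrna = sim$mrna, ribo = sim$ribo, protein = sim$protein),
                      function(m, nm) preprocess_layer(m, n_factors = k_fac))
  layers <- purrr::map(prep, "matrix")
  common <- Reduce(intersect, purrr::map(layers, rownames))
  layers <- purrr::map(layers, function(m) {
    omics_matrix(unclass(m)[common, , drop = FALSE], om_layer(m), om_stage(m))
  })
  geno <- subset_samples(geno, common)
  res$genotypes <- geno
  res$layers <- layers

  if (ck("map_qtl")) {
    res$qtl <- map_cis_qtls(layers, geno, sim$annotation,
                            n_perm = config$n_perm_qtl, fdr = config$fdr,
                            seed = derive_seed(seed, 5L))
  }
  if (ck("attenuation")) {
    if (is.null(res$qtl)) abort("attenuation stage needs map_qtl")
    res$replication <- replication_matrix(res$qtl, layers, geno)
  }
  if (ck("specificity")) {
    res$specificity <- call_specificity(layers, geno, sim$annotation,
                                        n_perm = config$n_perm_rc2,
                                        seed = derive_seed(seed, 6L),
                                        rc2_shared = config$rc2_shared,
                                        rc2_specific = config$rc2_specific)
  }
  if (ck("coloc")) {
    if (is.null(res$qtl)) abort("coloc stage needs map_qtl")
    sig <- res$qtl[res$qtl$significant, ]
    wins <- cis_windows(sim$annotation)
    res$coloc <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
      g <- sig$gene_id[[i]]; ly <- sig$layer[[i]]
      scan <- nominal_scan(wins[wins$gene_id == g, ], geno, layers[[ly]][, g])
      out <- suppressWarnings(
        colocalize_gene(g, scan, gwas, pph4_cutoff = config$pph4)
      )
      dplyr::mutate(out, layer = ly, .after = "gene_id")
    })
  }
  if (ck("twas")) {
    if (is.null(res$specificity)) {
      res$specificity <- call_specificity(layers, geno, sim$annotation,
                                          n_perm = config$n_perm_rc2,
                                          seed = derive_seed(seed, 6L))
    }
    models <- purrr::flatten(attr(res$specificity, "models"))
    res$twas <- run_twas(models, gwas, geno, alpha = config$fwer)
  }
  if (ck("mr")) {
    wins <- cis_windows(sim$annotation)
    expo <- purrr::imap_dfr(layers, function(mat, ly) {
      purrr::map_dfr(intersect(wins$gene_id, colnames(mat)), function(g) {
        sc <- nominal_scan(wins[wins$gene_id == g, ], geno, mat[, g])
        va <- geno$variants[match(sc$variant_id, geno$variants$variant_id), ]
        dplyr::mutate(sc, gene_id = g, layer = ly,
                      effect_allele = va$alt, other_allele = va$ref,
                      beta = .data$slope)
      })
    })
    res$mr_two_sample <- mr_two_sample(expo, gwas, geno,
                                       r2_max = config$clump_r2,
                                       window_kb = config$clump_kb,
                                       fdr_cutoff = config$fdr)
    res$mr_one_sample <- mr_one_sample(layers, geno, sim$annotation,
                                       r2_max = config$clump_r2,
                                       window_kb = config$clump_kb,
                                       fdr_cutoff = config$fdr)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    wr <- function(obj, name) {
      p <- file.path(out_dir, name)
      utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
      files[[name]] <<- unname(tools::md5sum(p))
      nrow(obj)
    }
    counts <- list()
    if (!is.null(res$qtl)) counts$qtl <- wr(res$qtl, "qtl.tsv")
    if (!is.null(res$replication)) {
      counts$replication <- wr(tidy(res$replication), "replication_pi1.tsv")
    }
    if (!is.null(res$specificity)) {
      counts$specificity <- wr(as.data.frame(res$specificity), "specificity.tsv")
    }
    if (!is.null(res$coloc)) counts$coloc <- wr(res$coloc, "coloc.tsv")
    if (!is.null(res$twas)) counts$twas <- wr(as.data.frame(res$twas), "twas.tsv")
    if (!is.null(res$mr_two_sample)) {
      counts$mr_two_sample <- wr(as.data.frame(res$mr_two_sample), "mr_two_sample.tsv")
    }
    if (!is.null(res$mr_one_sample)) {
      counts$mr_one_sample <- wr(res$mr_one_sample$verdicts, "mr_cascade.tsv")
    }
    manifest <- list(package_version = as.character(utils::packageVersion("cascadeQTL")),
                     seed = seed, stages = config$stages,
                     row_counts = counts, checksums = as.list(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
  }
  invisible(res)
}
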