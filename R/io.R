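#' Write genotypes to VCF
#'
#' Emits a VCFv4.2 file with a GT field (dosages rounded to 0/1/2 and coded
#' 0/0, 0/1, 1/1) and a DS field carrying the dosage itself. Positions are
#' 1-based per the VCF dialect.
#'
#' @param genotypes A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  dos <- t(genotypes$dosage) # variants x samples
  gt <- matrix(c("0/0", "0/1", "1/1")[round(dos) + 1L], nrow(dos), ncol(dos))
  body <- matrix(paste0(gt, ":", formatC(dos, format = "g")), nrow(dos), ncol(dos))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes$dosage)), collapse = "\t")
  )
  lines <- apply(cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                       ".", "GT:DS", body), 1, paste, collapse = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Uses `vcfR` (Suggests) to parse; returns a `variant_table`. MAF is the
#' empirical folded alt-allele frequency.
#'
#' @param path VCF path.
#' @return A `variant_table`.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) abort("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  dosage <- t(ds)
  fx <- vcfR::getFIX(v)
  variants <- tibble::tibble(
    variant_id = fx[, "ID"], chrom = fx[, "CHROM"],
    pos = as.integer(fx[, "POS"]), ref = fx[, "REF"], alt = fx[, "ALT"]
  )
  variants$maf <- empirical_maf(dosage)
  structure(list(variants = variants, dosage = dosage), class = "variant_table")
}

#' Write a quantification matrix as TSV (genes in rows, samples in columns)
#' @param x An `omics_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(x, path) {
  df <- data.frame(gene_id = colnames(x), t(unclass(x)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quantification TSV written by [write_quant_tsv()]
#' @param path TSV path.
#' @param layer,stage Metadata for the resulting `omics_matrix`.
#' @return An `omics_matrix`.
#' @export
read_quant_tsv <- function(path, layer, stage) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$gene_id
  omics_matrix(m, layer = layer, stage = stage)
}

#' Write GWAS summary statistics TSV
#' @param gwas A `gwas_summary` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(gwas, path) {
  out <- dplyr::rename(gwas, A1 = "effect_allele", A2 = "other_allele",
                       z = "zscore", p = "pvalue")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics TSV
#' @param path TSV path.
#' @return A `gwas_summary` tibble.
#' @export
read_gwas_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path))
  dplyr::rename(df, effect_allele = "A1", other_allele = "A2",
                zscore = "z", pvalue = "p")
}
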