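# shared small fixtures, built once per test run

tiny_genotypes <- function(n = 150, v = 120, rho = 0.7, seed = 101) {
  simulate_genotypes(n, v, ld_block_size = 6, ld_rho = rho, seed = seed)
}

# small cascade with mixed effect structure; memoised across tests
.fixture_env <- new.env()

fixture_cascade <- function() {
  if (is.null(.fixture_env$sim)) {
    g <- tiny_genotypes(n = 150, v = 120)
    tr <- cascade_truth(40, seed = 102)
    .fixture_env$g <- g
    .fixture_env$sim <- simulate_cascade(g, tr, seed = 103)
  }
  list(g = .fixture_env$g, sim = .fixture_env$sim)
}

# residualized layers of the fixture cascade
fixture_layers <- function() {
  if (is.null(.fixture_env$layers)) {
    fx <- fixture_cascade()
    .fixture_env$layers <- suppressWarnings(purrr::map(
      list(mrna = fx$sim$mrna, ribo = fx$sim$ribo, protein = fx$sim$protein),
      function(m) preprocess_layer(m, n_factors = 5)$matrix
    ))
  }
  c(fixture_cascade(), list(layers = .fixture_env$layers))
}

# one-row cis window covering all variants of a variant_table
whole_window <- function(g, gene_id = "g1") {
  tibble::tibble(gene_id = gene_id, chrom = g$variants$chrom[[1]],
                 start = 1, end = max(g$variants$pos) + 1)
}
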