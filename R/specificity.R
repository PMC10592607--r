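#' Train an elastic-net cis prediction model for one gene
#'
#' Elastic net (mixing parameter `alpha = 0.5`) over the gene's common cis
#' variants, penalty chosen by 10-fold cross-validation. Prediction
#' accuracy R_cv is the Pearson correlation between out-of-fold predictions
#' and observed expression, with its correlation-test p-value; a model is
#' retained only if `r_cv > 0.1` and `r_cv_p < 0.05` and at least one
#' weight is nonzero.
#'
#' @param window One-row cis-window tibble (see [cis_windows()]).
#' @param genotypes A `variant_table`.
#' @param expression Residualized expression vector (samples in dosage
#'   order).
#' @param layer Label stored on the model.
#' @param n_folds Cross-validation folds.
#' @param alpha Elastic-net mixing parameter.
#' @param maf_min Cis-variant MAF filter.
#' @param seed Seed for the fold assignment.
#' @return A `prediction_model` (or NULL if < 2 cis variants): gene_id,
#'   layer, named `weights` (nonzero only), intercept, lambda, r_cv,
#'   r_cv_p, retained, conditional flag.
#' @export
train_prediction_model <- function(window, genotypes, expression,
                                   layer = "mrna", n_folds = 10, alpha = 0.5,
                                   maf_min = 0.05, seed = 1L) {
  idx <- cis_variant_idx(genotypes, window, maf_min)
  if (length(idx) < 2) {
    inform(sprintf("gene %s: fewer than 2 cis variants, no model", window$gene_id))
    return(NULL)
  }
  x <- genotypes$dosage[, idx, drop = FALSE]
  fit_enet_model(x, expression, gene_id = window$gene_id, layer = layer,
                 n_folds = n_folds, alpha = alpha, seed = seed,
                 conditional = FALSE)
}

fit_enet_model <- function(x, y, gene_id, layer, n_folds = 10, alpha = 0.5,
                           seed = 1L, conditional = FALSE, lambda = NULL) {
  n <- length(y)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), n))
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid, keep = TRUE,
                          standardize = TRUE)
  lam <- lambda %||% cv$lambda.min
  li <- which.min(abs(cv$lambda - lam))
  preval <- cv$fit.preval[, li]
  r_cv <- suppressWarnings(cor(preval, y))
  r_cv_p <- if (is.na(r_cv)) 1 else suppressWarnings(cor.test(preval, y)$p.value)
  if (is.na(r_cv)) r_cv <- 0
  w <- as.numeric(coef(cv, s = lam))
  names(w) <- c("(Intercept)", colnames(x))
  nz <- w[-1][w[-1] != 0]
  retained <- length(nz) > 0 && r_cv > 0.1 && r_cv_p < 0.05
  structure(
    list(gene_id = gene_id, layer = layer, weights = nz,
         intercept = w[[1]], lambda = lam, alpha = alpha,
         r_cv = r_cv, r_cv_p = r_cv_p, retained = retained,
         conditional = conditional, n_variants = ncol(x)),
    class = "prediction_model"
  )
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("<prediction_model%s> gene %s layer %s: %d/%d nonzero weights, r_cv=%.3f (p=%.3g)%s\n",
              if (x$conditional) " conditional" else "", x$gene_id, x$layer,
              length(x$weights), x$n_variants, x$r_cv, x$r_cv_p,
              if (x$retained) ", retained" else ", NOT retained"))
  invisible(x)
}

#' Genetically imputed expression
#'
#' `intercept + sum_i w_i * dosage_i` over the model's nonzero-weight
#' variants.
#'
#' @param model A `prediction_model`.
#' @param genotypes A `variant_table` containing every model variant.
#' @return Named numeric vector of per-sample imputed expression.
#' @export
impute_expression <- function(model, genotypes) {
  vars <- names(model$weights)
  missing <- setdiff(vars, colnames(genotypes$dosage))
  if (length(missing) > 0) {
    abort(sprintf("model variants missing from genotypes: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(vars) == 0) {
    return(setNames(rep(model$intercept, nrow(genotypes$dosage)),
                    rownames(genotypes$dosage)))
  }
  drop(genotypes$dosage[, vars, drop = FALSE] %*% model$weights) + model$intercept
}

#' Regress other layers' imputed expression out of an observed layer
#'
#' Multiple regression of the focal layer's observed expression on the
#' genetically imputed expression of the other omics layers; the residual
#' e_k is re-centered at the gene's mean to give the conditional
#' quantification R_k = mean(E_k) + e_k on which the conditional prediction
#' model is trained. Collinear imputed regressors are dropped (later ones
#' first) with a warning.
#'
#' @param expression Observed focal-layer expression vector E_k.
#' @param imputed_others List of imputed expression vectors of the other
#'   layers.
#' @return A `conditional_expression`: list with `$residual` (e_k),
#'   `$reconstructed` (R_k), `$slopes`, `$center`.
#' @export
conditional_residualize <- function(expression, imputed_others) {
  stopifnot(length(imputed_others) >= 1)
  X <- do.call(cbind, imputed_others)
  if (is.null(colnames(X))) colnames(X) <- paste0("Ehat", seq_len(ncol(X)))
  keep <- logical(ncol(X))
  qr_cols <- matrix(1, length(expression), 1)
  for (j in seq_len(ncol(X))) {
    cand <- cbind(qr_cols, X[, j])
    if (qr(cand)$rank == ncol(cand)) {
      qr_cols <- cand
      keep[j] <- TRUE
    }
  }
  if (!all(keep)) {
    warn(sprintf("dropping %d collinear imputed regressor(s)", sum(!keep)))
  }
  fit <- lm.fit(qr_cols, expression)
  e_k <- fit$residuals
  structure(
    list(residual = e_k,
         reconstructed = mean(expression) + e_k,
         slopes = setNames(fit$coefficients[-1], colnames(X)[keep]),
         center = mean(expression)),
    class = "conditional_expression"
  )
}

#' Squared correlation between original and conditional imputations
#'
#' `rc2 = cor(E_hat_original, E_hat_conditional)^2`. Low values mean the
#' genetic signal was absorbed by the other layers' imputed expression
#' (shared regulation); values near 1 mean conditioning changed nothing
#' (omics-specific regulation). A constant imputation on either side gives
#' rc2 = 0 with `degenerate = TRUE`.
#'
#' @param original,conditional Retained `prediction_model`s for the same
#'   gene/layer.
#' @param genotypes A `variant_table`.
#' @return List with `$rc2` and `$degenerate`.
#' @export
compute_rc2 <- function(original, conditional, genotypes) {
  eo <- impute_expression(original, genotypes)
  ec <- impute_expression(conditional, genotypes)
  if (sd(eo) == 0 || sd(ec) == 0) {
    return(list(rc2 = 0, degenerate = TRUE))
  }
  list(rc2 = cor(eo, ec)^2, degenerate = FALSE)
}

# one conditional fit: residualize on (possibly permuted) imputations,
# rebuild the conditional elastic net by cross-validation (the same
# construction the observed conditional model uses), and return rc2
conditional_fit_rc2 <- function(x, expression, imputed_others, original_imputed,
                                alpha = 0.5, n_folds = 4, nlambda = 20) {
  ce <- suppressWarnings(conditional_residualize(expression, imputed_others))
  foldid <- sample(rep_len(seq_len(n_folds), length(expression)))
  cv <- glmnet::cv.glmnet(x, ce$reconstructed, alpha = alpha, foldid = foldid,
                          nlambda = nlambda, standardize = TRUE)
  w <- as.numeric(coef(cv, s = cv$lambda.min))
  pred <- drop(x %*% w[-1]) + w[[1]]
  if (sd(pred) == 0 || sd(original_imputed) == 0) return(0)
  cor(pred, original_imputed)^2
}

#' Permutation null for the sharing statistic rc2
#'
#' Emulates "no real correlation between omics layers": in each permutation
#' one random sample permutation is applied jointly to all other layers'
#' imputed vectors (preserving their mutual correlation), the conditional
#' model is rebuilt from scratch — residualization plus a fresh
#' cross-validated elastic net, the same construction as the observed
#' conditional model — and rc2 recomputed. Rebuilding with CV matters:
#' the observed conditioning removes a direction inside the cis-genotype
#' span while a shuffled vector is mostly outside it, and only the CV
#' refit noise shared by both sides keeps the null comparable. The
#' empirical p-value is the ascending rank of the observed rc2,
#' `p = (#{perm rc2 <= observed} + 1) / (n_perm + 1)`: a small observed rc2
#' (conditioning destroyed the genetic signal) gives a small p, i.e.
#' evidence of cross-layer sharing.
#'
#' @param x Cis dosage matrix used by the conditional model.
#' @param expression Observed focal-layer expression E_k.
#' @param imputed_others List of the other layers' imputed vectors.
#' @param original_imputed The original model's imputation.
#' @param observed_rc2 The observed rc2.
#' @param n_perm Number of permutations (50 by default).
#' @param alpha Elastic-net mixing parameter.
#' @param n_folds CV folds for the per-permutation refits.
#' @param seed Seed.
#' @return List with `$empirical_p` and `$perm_rc2`.
#' @export
permutation_null_rc2 <- function(x, expression, imputed_others, original_imputed,
                                 observed_rc2, n_perm = 50, alpha = 0.5,
                                 n_folds = 4, seed = 1L) {
  n <- length(expression)
  set.seed(seed)
  perm_rc2 <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    pidx <- sample.int(n)
    shuffled <- purrr::map(imputed_others, ~ .x[pidx])
    perm_rc2[b] <- tryCatch(
      conditional_fit_rc2(x, expression, shuffled, original_imputed,
                          alpha = alpha, n_folds = n_folds),
      error = function(e) NA_real_
    )
  }
  if (mean(is.na(perm_rc2)) > 0.5) {
    inform("conditional model failed in more than half of permutations: unclassifiable")
    return(list(empirical_p = NA_real_, perm_rc2 = perm_rc2))
  }
  ok <- perm_rc2[!is.na(perm_rc2)]
  list(empirical_p = (sum(ok <= observed_rc2) + 1) / (length(ok) + 1),
       perm_rc2 = perm_rc2)
}

#' Shared / omics-specific label from FDR and rc2
#'
#' shared iff `fdr < fdr_shared & rc2 < rc2_shared`; specific iff
#' `fdr > fdr_shared & rc2 > rc2_specific`; otherwise unclassified.
#'
#' @param fdr BH-adjusted empirical p-value(s).
#' @param rc2 Observed rc2 value(s).
#' @param fdr_shared FDR threshold (0.1).
#' @param rc2_shared Sharing effect-size bound (0.5).
#' @param rc2_specific Specificity effect-size bound (0.9).
#' @return Character vector in {shared, specific, unclassified}.
#' @export
classify_gene <- function(fdr, rc2, fdr_shared = 0.1,
                          rc2_shared = 0.5, rc2_specific = 0.9) {
  dplyr::case_when(
    is.na(fdr) | is.na(rc2) ~ "unclassified",
    fdr < fdr_shared & rc2 < rc2_shared ~ "shared",
    fdr > fdr_shared & rc2 > rc2_specific ~ "specific",
    TRUE ~ "unclassified"
  )
}

#' Detect shared and omics-specific QTL genes
#'
#' The full conditional-imputation procedure: per layer, train original
#' elastic-net models; for each gene with a retained model in the focal
#' layer and at least one retained model in another layer, regress the
#' other layers' imputations out of the focal expression, train the
#' conditional model, compute rc2, calibrate it against a joint-shuffle
#' permutation null, BH-adjust the empirical p-values per layer, and label
#' each gene shared / specific / unclassified.
#'
#' @param layers Named list of residualized `omics_matrix` objects.
#' @param genotypes A `variant_table` on the same samples.
#' @param annotation Gene annotation tibble.
#' @param n_perm Permutations for the rc2 null (50 by default).
#' @param n_folds CV folds for model training.
#' @param alpha Elastic-net mixing parameter.
#' @param maf_min Cis MAF filter.
#' @param seed Master seed.
#' @param fdr_shared,rc2_shared,rc2_specific Classification thresholds.
#' @param focal_layers Layers to analyse as the focal omics type (all by
#'   default); original models are always trained on every layer since
#'   conditioning needs them.
#' @return A `specificity_result` tibble: gene_id, layer, r_cv, rc2,
#'   empirical_p, fdr, label (plus `degenerate`).
#' @export
call_specificity <- function(layers, genotypes, annotation, n_perm = 50,
                             n_folds = 10, alpha = 0.5, maf_min = 0.05,
                             seed = 1L, fdr_shared = 0.1, rc2_shared = 0.5,
                             rc2_specific = 0.9, focal_layers = names(layers)) {
  wins <- cis_windows(annotation)
  lnames <- names(layers)

  # original models for every gene x layer
  models <- purrr::imap(layers, function(mat, ly) {
    genes <- intersect(wins$gene_id, colnames(mat))
    ms <- purrr::map(seq_along(genes), function(i) {
      win <- wins[wins$gene_id == genes[[i]], ]
      train_prediction_model(win, genotypes, mat[, genes[[i]]], layer = ly,
                             n_folds = n_folds, alpha = alpha,
                             maf_min = maf_min,
                             seed = derive_seed(seed, i * 17L + match(ly, lnames)))
    })
    setNames(ms, genes)
  })

  rows <- list()
  for (ly in intersect(lnames, focal_layers)) {
    mat <- layers[[ly]]
    for (g in names(models[[ly]])) {
      mod <- models[[ly]][[g]]
      if (is.null(mod) || !mod$retained) next
      others <- purrr::compact(purrr::map(setdiff(lnames, ly), function(ol) {
        om <- models[[ol]][[g]]
        if (is.null(om) || !om$retained) NULL else om
      }))
      if (length(others) == 0) next

      imput_others <- purrr::map(others, impute_expression, genotypes = genotypes)
      orig_imp <- impute_expression(mod, genotypes)
      win <- wins[wins$gene_id == g, ]
      idx <- cis_variant_idx(genotypes, win, maf_min)
      x <- genotypes$dosage[, idx, drop = FALSE]
      ek <- mat[, g]

      ce <- suppressWarnings(conditional_residualize(ek, imput_others))
      cond <- fit_enet_model(x, ce$reconstructed, gene_id = g, layer = ly,
                             n_folds = n_folds, alpha = alpha,
                             seed = derive_seed(seed, match(g, names(models[[ly]])) * 29L),
                             conditional = TRUE)
      rc <- compute_rc2(mod, cond, genotypes)
      pn <- permutation_null_rc2(
        x, ek, imput_others, orig_imp, rc$rc2,
        n_perm = n_perm, alpha = alpha,
        seed = derive_seed(seed, match(g, names(models[[ly]])) * 31L + match(ly, lnames))
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = g, layer = ly, r_cv = mod$r_cv, rc2 = rc$rc2,
        degenerate = rc$degenerate, empirical_p = pn$empirical_p
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble::tibble(gene_id = character(), layer = character(),
                          r_cv = numeric(), rc2 = numeric(),
                          degenerate = logical(), empirical_p = numeric(),
                          fdr = numeric(), label = character())
  } else {
    res <- res |>
      dplyr::group_by(.data$layer) |>
      dplyr::mutate(fdr = p.adjust(.data$empirical_p, method = "BH")) |>
      dplyr::ungroup() |>
      dplyr::mutate(label = classify_gene(.data$fdr, .data$rc2, fdr_shared,
                                          rc2_shared, rc2_specific))
  }
  structure(res, class = c("specificity_result", class(res)),
            models = models)
}
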