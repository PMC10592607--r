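#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a prediction model into a variant/weight tibble
#' @param x A `prediction_model`.
#' @param ... Unused.
#' @return Tibble gene_id, layer, variant_id, weight.
#' @method tidy prediction_model
#' @export
tidy.prediction_model <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, layer = x$layer,
                 variant_id = names(x$weights), weight = unname(x$weights))
}

#' One-row model summary
#' @param x A `prediction_model`.
#' @param ... Unused.
#' @return Tibble gene_id, layer, n_variants, n_nonzero, lambda, r_cv,
#'   r_cv_p, retained, conditional.
#' @method glance prediction_model
#' @export
glance.prediction_model <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, layer = x$layer,
                 n_variants = x$n_variants, n_nonzero = length(x$weights),
                 lambda = x$lambda, r_cv = x$r_cv, r_cv_p = x$r_cv_p,
                 retained = x$retained, conditional = x$conditional)
}

#' Tidy a replication matrix into long format
#' @param x A `replication_matrix`.
#' @param ... Unused.
#' @return Tibble discovery, replication, pi1.
#' @method tidy replication_matrix
#' @export
tidy.replication_matrix <- function(x, ...) {
  m <- x$pi1
  tidyr::expand_grid(discovery = rownames(m), replication = colnames(m)) |>
    dplyr::mutate(pi1 = purrr::map2_dbl(.data$discovery, .data$replication,
                                        ~ m[.x, .y]))
}

#' Asymmetry summary of a replication matrix
#' @param x A `replication_matrix`.
#' @param ... Unused.
#' @return The asymmetry tibble (upstream, downstream, asymmetry).
#' @method glance replication_matrix
#' @export
glance.replication_matrix <- function(x, ...) x$asymmetry

#' Tidy an effect profile
#' @param x An `effect_profile`.
#' @param ... Unused.
#' @return The per-layer profile tibble.
#' @method tidy effect_profile
#' @export
tidy.effect_profile <- function(x, ...) x$profile

#' Pairwise layer contrasts of an effect profile
#' @param x An `effect_profile`.
#' @param ... Unused.
#' @return The pairwise t-test tibble.
#' @method glance effect_profile
#' @export
glance.effect_profile <- function(x, ...) x$tests

#' Heatmap of the pi1 replication matrix
#' @param object A `replication_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot replication_matrix
#' @export
autoplot.replication_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replication, y = .data$discovery,
                                   fill = .data$pi1)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$pi1))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "replication layer", y = "discovery layer",
                  fill = expression(pi[1]))
}

#' Point-range plot of per-layer mean absolute effects
#' @param object An `effect_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot effect_profile
#' @export
autoplot.effect_profile <- function(object, ...) {
  df <- tidy(object)
  df$layer <- factor(df$layer, levels = df$layer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$mean_abs_effect)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "mean |per-allele effect| (log2)")
}

#' QQ plot of gene-level empirical p-values per layer
#' @param object A `qtl_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qtl_result
#' @export
autoplot.qtl_result <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$layer) |>
    dplyr::arrange(.data$empirical_p, .by_group = TRUE) |>
    dplyr::mutate(expected = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$expected),
                                   y = -log10(pmax(.data$empirical_p, 1e-300)),
                                   colour = .data$layer)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(-log[10] ~ "expected p"),
                  y = expression(-log[10] ~ "empirical p"))
}

#' Scatter of rc2 against sharing FDR with the classification regions
#' @param object A `specificity_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot specificity_result
#' @export
autoplot.specificity_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rc2, y = .data$fdr,
                                       colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(0.5, 0.9), linetype = 3) +
    ggplot2::geom_hline(yintercept = 0.1, linetype = 3) +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(x = expression(R[c]^2), y = "sharing FDR")
}

#' @importFrom rlang .data
NULL
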