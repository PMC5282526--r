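# ggplot2 displays for the main result types.

#' Scatterplot of two drug enrichment-score profiles
#'
#' The reversal display: each point is a drug passing the permutation-p
#' filter in either query, positioned by its enrichment score under the
#' two queries, with the Pearson coefficient in the subtitle. A cloud
#' along the falling diagonal is the signature-reversal pattern.
#'
#' @param result_a,result_b `connectivity_result` objects.
#' @param p_threshold drug filter (default 0.05).
#' @return a ggplot.
#' @export
plot_profile_correlation <- function(result_a, result_b,
                                     p_threshold = 0.05) {
  pc <- profile_correlation(result_a, result_b,
                            p_threshold = p_threshold)
  drugs <- pc$drugs[[1]]
  df <- tibble::tibble(
    drug = drugs,
    es_a = setNames(result_a$drugs$es, result_a$drugs$drug)[drugs],
    es_b = setNames(result_b$drugs$es, result_b$drugs$drug)[drugs]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$es_a, .data$es_b)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = paste("enrichment score:", result_a$provenance$label),
      y = paste("enrichment score:", result_b$provenance$label),
      subtitle = sprintf("r = %.3f (p = %.2g, %d drugs)",
                         pc$r, pc$p, pc$n_drugs)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot connectivity_result
#' @export
autoplot.connectivity_result <- function(object, ...) {
  df <- dplyr::mutate(object$drugs,
                      drug = factor(.data$drug,
                                    levels = .data$drug[order(.data$es)]),
                      significant = .data$p < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(.data$es, .data$drug,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "drug enrichment score", y = NULL,
                  title = object$provenance$label) +
    ggplot2::theme_minimal()
}

#' @method autoplot pathway_activity_result
#' @export
autoplot.pathway_activity_result <- function(object, q_cutoff = 0.01,
                                             ...) {
  df <- tibble::as_tibble(object)
  df$pathway <- factor(df$pathway,
                       levels = df$pathway[order(df$activity)])
  df$significant <- !is.na(df$q) & df$q < q_cutoff
  ggplot2::ggplot(df, ggplot2::aes(.data$activity, .data$pathway,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "repressor-weighted activity", y = NULL,
                  subtitle = attr(object, "condition")) +
    ggplot2::theme_minimal()
}

#' @method autoplot weighted_ratio_result
#' @export
autoplot.weighted_ratio_result <- function(object, ...) {
  df <- dplyr::mutate(object$w,
                      condition = factor(.data$condition,
                                         levels = .data$condition))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$W, group = 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p < 0.05), size = 2) +
    ggplot2::labs(x = NULL, y = "degree-weighted ratio W",
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @method autoplot set_association
#' @export
autoplot.set_association <- function(object, ...) {
  df <- tibble::tibble(null_sum = object$null_sums)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_sum)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "firebrick") +
    ggplot2::labs(x = "null set sum",
                  subtitle = sprintf("observed = %d, p = %.4g",
                                     object$observed, object$p)) +
    ggplot2::theme_minimal()
}

#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  df <- dplyr::count(object$modules, .data$module)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$module), .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module", y = "genes") +
    ggplot2::theme_minimal()
}
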