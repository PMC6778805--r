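#' Plot GRM principal components
#'
#' First two component scores, the standard population-structure diagnostic.
#'
#' @param object A [grm_pca()] result.
#' @param groups Optional named character vector (`id` -> group) for colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grm_pca <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) df$group <- unname(groups[df$id])
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$prop_var[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$prop_var[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    gg + ggplot2::geom_point(alpha = 0.7)
  } else {
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  }
}

#' Excess mismatch vs relatedness for best-matching parents
#'
#' One panel per parent sex: each offspring's best-candidate relatedness
#' against the pair excess mismatch rate, with the decision thresholds drawn
#' as reference lines. True parents cluster at high relatedness / near-zero
#' EMM; wrong best matches sit low and to the left with elevated EMM.
#'
#' @param object A `parentage_assignments` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parentage_assignments <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- dplyr::bind_rows(
    tibble::tibble(sex = "sire", r = object$sire_r, emm = object$sire_emm,
                   code = object$code),
    tibble::tibble(sex = "dam", r = object$dam_r, emm = object$dam_emm,
                   code = object$code)
  )
  df <- dplyr::filter(df, !is.na(.data$r))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$emm,
                                         colour = .data$code)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = "relatedness to best candidate",
                  y = "excess mismatch rate", colour = "code") +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    gg <- gg +
      ggplot2::geom_vline(xintercept = thr$rel_min, linetype = 2, colour = "grey40") +
      ggplot2::geom_hline(yintercept = thr$emm_max, linetype = 2, colour = "grey40")
  }
  gg
}

#' Fin plot: Hardy-Weinberg disequilibrium against minor allele frequency
#'
#' The characteristic fin-shaped diagnostic for GBS SNP panels: undetected
#' heterozygotes push apparent disequilibrium upward at low depth, while
#' collapsed duplicated loci fall far below zero. The filter threshold is
#' drawn as a reference line.
#'
#' @param filter_table A [filter_snps()] result.
#' @param hwdis_min Threshold line position (default -0.05).
#' @return A ggplot.
#' @export
plot_fin <- function(filter_table, hwdis_min = -0.05) {
  df <- dplyr::filter(filter_table, !is.na(.data$d), !is.na(.data$maf))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_hline(yintercept = hwdis_min, linetype = 2, colour = "red") +
    ggplot2::labs(x = "minor allele frequency",
                  y = "Hardy-Weinberg disequilibrium") +
    ggplot2::theme_minimal()
}

#' Raw vs expected trio mismatch rates
#'
#' Scatter of observed against model-expected trio mismatch rates, one point
#' per trio, with the identity line; systematic elevation above the line on
#' accepted trios is the signature of read overdispersion and motivates
#' refitting with [fit_dispersion()].
#'
#' @param trio_stats A tibble of [trio_mismatch_stats()] rows (optionally
#'   with a `code` column for colouring).
#' @return A ggplot.
#' @export
plot_mismatch_rates <- function(trio_stats) {
  aes <- if ("code" %in% names(trio_stats)) {
    ggplot2::aes(x = .data$expected_rate, y = .data$raw_rate, colour = .data$code)
  } else {
    ggplot2::aes(x = .data$expected_rate, y = .data$raw_rate)
  }
  ggplot2::ggplot(trio_stats, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "expected mismatch rate", y = "raw mismatch rate") +
    ggplot2::theme_minimal()
}
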