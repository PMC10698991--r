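#' Plot a ranked epiallele beta curve
#'
#' Displays per-sample epiallele betas sorted ascending with the rank axis
#' centred at the first epiallele reaching beta 0.5. Mosaic epimutation
#' carriers show a near-vertical step through rank 0: almost every
#' epiallele is either hypomethylated or hypermethylated.
#'
#' @param x A `vef_rank_curve` from [rank_epialleles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rank_curve <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$rank, y = .data$beta,
                                  group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "epiallele rank (centred at beta = 0.5)",
                  y = "per-epiallele beta") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_rank_curve
#' @param object A `vef_rank_curve`.
#' @method autoplot vef_rank_curve
#' @export
autoplot.vef_rank_curve <- function(object, ...) plot_rank_curve(object, ...)

#' Plot per-CpG methylation profiles
#'
#' Smoothed per-CpG mean methylation for the hypermethylated (solid) and
#' hypomethylated (dashed) epiallele partitions over genomic coordinate,
#' with the raw per-CpG means as points.
#'
#' @param x A `vef_cpg_profile` from [cpg_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_cpg_profile <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$pos, colour = .data$partition)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_meth), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed,
                                    linetype = .data$partition)) +
    ggplot2::scale_linetype_manual(values = c(hyper = "solid",
                                              hypo = "dashed")) +
    ggplot2::labs(x = "genomic coordinate", y = "mean CpG methylation",
                  colour = "epialleles", linetype = "epialleles") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_cpg_profile
#' @param object A `vef_cpg_profile`.
#' @method autoplot vef_cpg_profile
#' @export
autoplot.vef_cpg_profile <- function(object, ...) plot_cpg_profile(object, ...)

#' Allelic fold-enrichment quadrant plot
#'
#' Scatter of signed log10 fold enrichment in two matched measurements
#' (e.g. blood on x, tumor on y). Positive values indicate preferential
#' methylation of the reference allele, negative of the alternative
#' allele; points in the upper-right / lower-left quadrants support
#' concordant allelic methylation. Infinite folds (exclusive single-allele
#' methylation) are drawn as triangles at the axis edge.
#'
#' @param pairs Data frame with columns `fe_magnitude_a`, `fe_direction_a`,
#'   `fe_magnitude_b`, `fe_direction_b` (as from two [allele_vef()]
#'   results joined per pair).
#' @param cap Finite plotting position (in log10 fold) for infinite
#'   values; default 1 + the largest finite signed fold.
#' @return A ggplot object.
#' @export
plot_fold_quadrant <- function(pairs, cap = NULL) {
  signed <- function(mag, dir) {
    s <- ifelse(dir == "alt", -1, ifelse(dir == "ref", 1, 0))
    s * log10(pmax(mag, 1))
  }
  x <- signed(pairs$fe_magnitude_a, pairs$fe_direction_a)
  y <- signed(pairs$fe_magnitude_b, pairs$fe_direction_b)
  finite <- c(x[is.finite(x)], y[is.finite(y)])
  cap <- cap %||% (if (length(finite)) max(abs(finite)) + 1 else 2)
  d <- tibble::tibble(
    x = pmin(pmax(x, -cap), cap), y = pmin(pmax(y, -cap), cap),
    infinite = is.infinite(x) | is.infinite(y)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  shape = .data$infinite)) +
    ggplot2::annotate("rect", xmin = 0, xmax = cap, ymin = 0, ymax = cap,
                      alpha = 0.12) +
    ggplot2::annotate("rect", xmin = -cap, xmax = 0, ymin = -cap, ymax = 0,
                      alpha = 0.12) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                labels = c(`FALSE` = "finite",
                                           `TRUE` = "Inf (exclusive)")) +
    ggplot2::labs(x = "signed log10 fold enrichment (a)",
                  y = "signed log10 fold enrichment (b)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}
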