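#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a trained pseudo-variance table
#'
#' Histogram of the per-gene pseudo variances, log10-spaced above zero with
#' the zero-penalty genes shown as their own bar, coloured by provenance
#' (direct minimization vs linear-model imputation). The dashed line marks
#' the moderate/large tranche boundary.
#'
#' @param object An `ebt_pseudovar` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ebt_pseudovar <- function(object, ...) {
  thr <- attr(object, "tranche_threshold")
  floor_val <- 1e-4
  df <- tibble::tibble(
    alpha = pmax(object$alpha, floor_val),
    provenance = object$provenance
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha,
                                   fill = .data$provenance)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "pseudo variance (SD scale, zero shown at 1e-4)",
      y = "genes",
      title = "Trained pseudo variances",
      subtitle = sprintf("dashed line: tranche threshold %g", thr)
    )
}

#' Compare penalized and conventional significance
#'
#' Scatter plot of the conventional t-statistic against the penalized
#' t-statistic for every gene, coloured by pseudo-variance tranche. Genes
#' on the diagonal carried no penalty; genes pulled toward zero were judged
#' poorly translating by the training pair.
#'
#' @param ebt,conventional Translation results tibbles for the same
#'   experiment in the two modes.
#' @param tranche_threshold Boundary between moderate and large penalties;
#'   default `0.25`.
#' @return A ggplot object.
#' @export
plot_penalization <- function(ebt, conventional, tranche_threshold = 0.25) {
  df <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(conventional), "gene_id", t_ct = "t"),
    dplyr::select(tibble::as_tibble(ebt), "gene_id", t_ebt = "t",
                  "alpha"),
    by = "gene_id"
  ) |>
    dplyr::mutate(tranche = dplyr::case_when(
      .data$alpha == 0 ~ "alpha = 0",
      .data$alpha <= tranche_threshold ~ "moderate",
      .default = "large"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ct, y = .data$t_ebt,
                                   colour = .data$tranche)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = "conventional t", y = "penalized t",
                  colour = "pseudo variance",
                  title = "Penalization of test-experiment t-statistics")
}

#' Plot agreement reports side by side
#'
#' Bar chart of agreement fractions by evaluation layer and translation
#' mode, as produced by [benchmark_improvement()] or assembled from
#' individual agreement reports.
#'
#' @param reports Tibble with columns `mode`, `layer`, `fraction`.
#' @return A ggplot object.
#' @export
plot_agreement <- function(reports) {
  ggplot2::ggplot(reports,
                  ggplot2::aes(x = .data$layer, y = .data$fraction,
                               fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "direction agreement",
                  title = "Model-to-target agreement by translation mode")
}
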