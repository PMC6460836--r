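#' Plot maternal and fetal fragment-size distributions
#'
#' @param maternal,fetal size distributions ([size_distribution()]).
#' @param cutoff size-selection cutoff drawn as a vertical line.
#' @return A ggplot.
#' @export
plot_size_distributions <- function(maternal = maternal_size_dist(),
                                    fetal = fetal_size_dist(),
                                    cutoff = 160) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(maternal), origin = "maternal"),
    dplyr::mutate(tibble::as_tibble(fetal), origin = "fetal")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$length, .data$prob,
                                   colour = .data$origin)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "fragment length (bp)", y = "probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname generics_reexports
#' @param object an `ff_foldchange` table from [binwise_ff_foldchange()].
#' @export
autoplot.ff_foldchange <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lo + 5, .data$fold_change)) +
    ggplot2::geom_col(width = 8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "fragment length bin (bp)",
                  y = "chrY-fraction fold change vs pooled") +
    ggplot2::theme_minimal()
}

#' @rdname generics_reexports
#' @export
autoplot.dup_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$complexity, .data$duplication_rate,
                               colour = factor(.data$depth))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "input DNA complexity (genome copies)",
                  y = "duplication rate", colour = "depth") +
    ggplot2::theme_minimal()
}
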