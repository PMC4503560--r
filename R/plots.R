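# ggplot2 views of the result objects.

#' Retention-score histogram of a retention call
#'
#' Superimposed histograms of experimental retention scores for all
#' tested IESs and for the significantly retained subset -- a fully
#' excised genome piles up at 0, while factor-dependent IESs spread
#' across intermediate scores.
#'
#' @param object An `ies_retention_call`.
#' @param binwidth Histogram bin width on the RS axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ies_retention_call <- function(object, binwidth = 0.02, ...) {
  r <- filter(object$results, !is.na(.data$rs_experiment))
  df <- bind_rows(
    mutate(r, set = "all IESs"),
    mutate(filter(r, .data$retained %in% TRUE), set = "significantly retained")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rs_experiment,
                                   fill = .data$set)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::labs(x = "retention score", y = "number of IESs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' IES size distribution per retention-score quartile
#'
#' Box plots of IES length within empirical quartiles of the experimental
#' retention score (log10 size axis).
#'
#' @param call An `ies_retention_call`.
#' @param lengths Tibble with `ies_id` and `length` (e.g. the annotation
#'   table).
#' @return A ggplot object.
#' @export
plot_size_by_rs_quartile <- function(call, lengths) {
  df <- call$results |>
    filter(!is.na(.data$rs_experiment)) |>
    left_join(select(as_tibble(lengths), "ies_id", "length"), by = "ies_id")
  edges <- unique(quantile(df$rs_experiment, seq(0, 1, 0.25), type = 7))
  df$quartile <- cut(df$rs_experiment, edges, right = FALSE,
                     include.lowest = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quartile, y = .data$length)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "retention-score quartile", y = "IES length (bp)") +
    ggplot2::theme_minimal()
}

#' Bar chart of a small-RNA category profile
#'
#' Per-million-normalized read counts per category.
#'
#' @param object An `srna_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srna_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$per_million)) |>
    mutate(category = factor(.data$category, levels = .data$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$per_million)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "reads per million mapped") +
    ggplot2::theme_minimal()
}
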