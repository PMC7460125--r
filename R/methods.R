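# broom-style accessors and ggplot2 autoplot methods for the result
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a correlation report
#'
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return The report as a plain long tibble.
#' @method tidy correlation_report
#' @export
tidy.correlation_report <- function(x, ...) {
  class(x) <- setdiff(class(x), "correlation_report")
  tibble::as_tibble(x)
}

#' One-row summary of a correlation report
#'
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return Tibble with cell counts, reported-cell count and star counts.
#' @method glance correlation_report
#' @export
glance.correlation_report <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_reported = sum(x$reported, na.rm = TRUE),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    n_pearson = sum(x$method == "pearson", na.rm = TRUE),
    n_spearman = sum(x$method == "spearman", na.rm = TRUE))
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Per-group summary tibble with the test attached as columns.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$summary, method = x$method, statistic = x$statistic,
                p_value = x$p_value)
}

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble with method, statistic and p-value.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value)
}

#' Heatmap of a correlation report
#'
#' Tile plot of the coefficient matrix with stars overlaid; unreported
#' cells (|r| below the threshold) are dimmed.
#'
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clinical, y = .data$imaging)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r,
                                    alpha = ifelse(.data$reported, 1, 0.45))) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%s", .data$r,
                                                    .data$stars)), size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::scale_alpha_identity() +
    ggplot2::facet_wrap(~ .data$block, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Axial-slice image of a parameter map
#'
#' @param object A `parameter_map`.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parameter_map
#' @export
autoplot.parameter_map <- function(object, slice = NULL, ...) {
  dm <- dim(object)
  slice <- slice %||% ceiling(dm[3] / 2)
  sl <- object[, , slice]
  df <- tidyr::expand_grid(i = seq_len(dm[1]), j = seq_len(dm[2]))
  df$value <- as.numeric(sl)[(df$j - 1) * dm[1] + df$i]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::labs(title = attr(object, "map_name"),
                  fill = attr(object, "units")) +
    ggplot2::theme_void()
}

#' Export the correlation reports of a cohort study
#'
#' Writes one wide CSV per block in the published matrix layout (cells
#' "r stars") plus a tidy long-format CSV with method and p columns.
#'
#' @param study A `cohort_study` (or a `correlation_report`).
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(study, dir) {
  report <- if (inherits(study, "cohort_study")) study$reports else study
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (bl in unique(report$block)) {
    p <- file.path(dir, paste0("correlations_", bl, ".csv"))
    readr::write_csv(report_matrix(report, bl), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "correlations_long.csv")
  readr::write_csv(tidy(report), p)
  invisible(c(paths, p))
}
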