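# ggplot2 views of fitted objects and simulated sessions.

#' Plot the fitness surface of a grid fit
#'
#' Heat map of fitness over the decay (`d`) x noise (`s`) lattice,
#' faceted by the latency exponent `f`, with the best point marked.
#'
#' @param object An `ibl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ibl_fit
#' @export
autoplot.ibl_fit <- function(object, ...) {
  tr <- object$trace
  best <- tibble::tibble(d = object$params$d, s = object$params$s,
                         f = object$params$f)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$d, y = .data$s,
                                   fill = .data$fitness)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = best,
                        ggplot2::aes(x = .data$d, y = .data$s),
                        inherit.aes = FALSE, shape = 4, size = 2) +
    ggplot2::facet_wrap(~f, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "decay d", y = "noise s", fill = "fitness",
                  title = "Grid-search fitness surface")
}

#' Plot a group MSD comparison
#'
#' Bar chart of the mean square deviation of the fitted model from each
#' group's sheet counts.
#'
#' @param object An `ibl_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ibl_comparison
#' @export
autoplot.ibl_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$msd)) +
    ggplot2::geom_col(width = 0.5, fill = "grey35") +
    ggplot2::labs(x = NULL, y = "mean square deviation",
                  title = "Model fit by group",
                  subtitle = paste("MSD ordering:", attr(object, "ordering")))
}

#' Plot per-sheet counts of a simulated cohort
#'
#' @param cohort A tibble from [simulate_cohort()] (columns `W`, `C`,
#'   `CW`), or several row-bound cohorts with a `group` column.
#' @return A ggplot object: count distributions per sheet (and group,
#'   when present).
#' @export
plot_sheet_counts <- function(cohort) {
  long <- tidyr::pivot_longer(cohort, c("W", "C", "CW"),
                              names_to = "sheet", values_to = "count")
  long$sheet <- factor(long$sheet, levels = c("W", "C", "CW"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sheet, y = .data$count))
  if ("group" %in% names(long)) {
    p <- p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$group))
  } else {
    p <- p + ggplot2::geom_boxplot()
  }
  p + ggplot2::labs(x = "sheet", y = "items completed in 45 s",
                    title = "Simulated Stroop sheet counts")
}
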