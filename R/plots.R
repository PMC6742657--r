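#' Fold-change histogram with Gaussian overlay
#'
#' @param values numeric vector of log2 fold changes.
#' @param fit optional `gaussian_fit` (computed from `values` if NULL).
#' @param bin_width histogram bin width (default 0.1 log2 units).
#' @return a ggplot.
#' @export
plot_fold_change_distribution <- function(values, fit = NULL,
                                          bin_width = 0.1) {
  if (is.null(fit)) fit <- fit_gaussian_to_histogram(values, bin_width)
  grid <- tibble(x = seq(min(fit$histogram$x), max(fit$histogram$x),
                         length.out = 400)) |>
    mutate(y = fit$amplitude *
             exp(-(.data$x - fit$center)^2 / (2 * fit$width^2)))
  ggplot2::ggplot(fit$histogram, ggplot2::aes(x = .data$x, y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey70") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$y),
                       color = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "log2 fold change", y = "count",
                  subtitle = paste0("center ", signif(fit$center, 3),
                                    ", width ", signif(fit$width, 3))) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential results
#'
#' @param object a `differential_tbl` from [test_differential()].
#' @param q_threshold significance threshold on the BH-adjusted value
#'   (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot differential_tbl
#' @export
autoplot.differential_tbl <- function(object, q_threshold = 0.05, ...) {
  dat <- as_tibble(object) |>
    mutate(significant = .data$q < q_threshold)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$p),
                                    color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  color = paste0("q < ", q_threshold)) +
    ggplot2::theme_minimal()
}

#' Cluster centroid profiles
#'
#' @param object a `timecourse_clustering`.
#' @param ... unused.
#' @return a ggplot of centroid time courses.
#' @method autoplot timecourse_clustering
#' @export
autoplot.timecourse_clustering <- function(object, ...) {
  cen <- as_tibble(object$centroids, .name_repair = "minimal")
  tp <- colnames(object$centroids) %||% paste0("t", seq_len(ncol(cen)))
  names(cen) <- tp
  cen$cluster <- factor(seq_len(nrow(cen)))
  long <- cen |>
    pivot_longer(-"cluster", names_to = "timepoint", values_to = "log2fc") |>
    mutate(timepoint = factor(.data$timepoint, levels = tp))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$log2fc,
                                     group = .data$cluster,
                                     color = .data$cluster)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "timepoint", y = "centroid log2 fold change",
                  subtitle = paste0("k = ", object$k_selected)) +
    ggplot2::theme_minimal()
}

#' Per-site occupancy change plot
#'
#' @param object a `ptm_tbl` from [site_occupancy_changes()].
#' @param ... unused.
#' @return a ggplot of occupancy log2 fold changes with 2 se bars.
#' @method autoplot ptm_tbl
#' @export
autoplot.ptm_tbl <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(id = paste(.data$accession, .data$site))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$id,
                                    y = .data$occupancy_log2fc,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$occupancy_log2fc - 2 * .data$se,
                                        ymax = .data$occupancy_log2fc + 2 * .data$se),
                           position = "dodge", width = 0.3) +
    ggplot2::labs(x = NULL, y = "occupancy log2 fold change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
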