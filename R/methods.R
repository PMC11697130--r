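#' Tidy the stored draws of a fit
#'
#' One row per stored iteration with the beta draw and the occupied-cluster
#' count, in broom style.
#'
#' @param x a `"potts_fit"`.
#' @param ... unused.
#' @return A tibble with columns `iteration`, `beta`, `K`.
#' @export
tidy.potts_fit <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    iteration = cfg$burn_in + 1L +
      (seq_along(x$beta_samples) - 1L) * cfg$thin,
    beta = x$beta_samples,
    K = x$K_trace)
}

#' One-row summary of a fit
#'
#' @param x a `"potts_fit"`.
#' @param ... unused.
#' @return A tibble with `n_cells`, `k`, `k_hat`, `beta_mean`,
#'   `accept_rate`, `n_stored`.
#' @export
glance.potts_fit <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, k = x$k,
                 k_hat = if (is.null(x$k_hat)) NA_integer_ else x$k_hat,
                 beta_mean = mean(x$beta_samples),
                 accept_rate = x$accept_rate,
                 n_stored = length(x$beta_samples))
}

#' Trace plots for a fit
#'
#' Beta and occupied-cluster-count traces over stored iterations.
#'
#' @param object a `"potts_fit"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.potts_fit <- function(object, ...) {
  d <- tidy(object)
  long <- rbind(
    data.frame(iteration = d$iteration, value = d$beta,
               what = "beta (spatial interaction)"),
    data.frame(iteration = d$iteration, value = as.numeric(d$K),
               what = "K (occupied clusters)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Map of cell labels in space
#'
#' @param coords coordinate tibble (columns `x`, `y`) or n x 2 matrix.
#' @param labels integer labels, one per cell.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_cell_labels <- function(coords, labels, title = NULL) {
  xy <- coords_matrix(coords)
  d <- data.frame(x = xy[, 1], y = xy[, 2], label = factor(labels))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$label)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, colour = "type") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
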