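#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_line geom_ribbon
#'   geom_col geom_abline scale_fill_viridis_c labs theme_minimal autoplot
#'   coord_fixed facet_wrap position_dodge
NULL

#' Heatmap of a grouped connectivity matrix
#'
#' @param object A `grouped_matrix`.
#' @param trans Transformation applied to the weights for display; default
#'   `log1p` (synapse counts are heavy-tailed).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grouped_matrix
#' @export
autoplot.grouped_matrix <- function(object, trans = log1p, ...) {
  m <- unclass_matrix(object)
  df <- tidyr::expand_grid(pre = rownames(m), post = colnames(m)) |>
    mutate(weight = as.vector(t(m)))
  ggplot(df, aes(x = .data$post, y = .data$pre, fill = trans(.data$weight))) +
    geom_tile() +
    scale_fill_viridis_c(name = "weight\n(transformed)") +
    coord_fixed() +
    labs(x = "postsynaptic group", y = "presynaptic group") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Cell-by-cell scatter of two aligned grouped matrices
#'
#' Off-diagonal cells of the two individuals plotted against each other on
#' log1p axes, with the identity line; tight clustering along the diagonal
#' is what wiring stereotypy looks like.
#'
#' @param object A `stereotypy_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stereotypy_comparison
#' @export
autoplot.stereotypy_comparison <- function(object, ...) {
  cells <- aligned_cells(object$aligned, object$global$zero_policy)
  df <- tibble(a = log1p(cells$a), b = log1p(cells$b))
  ggplot(df, aes(x = .data$a, y = .data$b)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    labs(x = sprintf("%s, log1p grouped weight", object$individuals[1]),
         y = sprintf("%s, log1p grouped weight", object$individuals[2]),
         subtitle = sprintf("Spearman rho = %.2f (p = %.2g, %d cells)",
                            object$global$rho, object$global$p_perm,
                            object$global$n_cells)) +
    theme_minimal()
}

#' Scatter plot with regression line and 95% confidence band
#'
#' @param object A `linear_fit`.
#' @param n_grid Number of grid points for the band.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot linear_fit
#' @export
autoplot.linear_fit <- function(object, n_grid = 100, ...) {
  band <- object$ci_band(seq(min(object$data$x), max(object$data$x),
                             length.out = n_grid))
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_ribbon(data = band, aes(x = .data$x, ymin = .data$lwr,
                                 ymax = .data$upr),
                inherit.aes = FALSE, alpha = 0.2, fill = "red") +
    geom_line(data = band, aes(x = .data$x, y = .data$fit),
              inherit.aes = FALSE) +
    geom_point() +
    labs(subtitle = sprintf("Pearson r = %.2f, p = %.2g, n = %d",
                            object$pearson_r, object$p_value, object$n)) +
    theme_minimal()
}

#' Bar chart of per-cell-type pre/post correlations
#'
#' @param profiles The tibble returned by [per_type_correlations()].
#' @return A ggplot.
#' @export
plot_per_type <- function(profiles) {
  df <- profiles |>
    tidyr::pivot_longer(c("pre_rho", "post_rho"), names_to = "direction",
                        values_to = "rho") |>
    mutate(direction = ifelse(.data$direction == "pre_rho",
                              "presynaptic", "postsynaptic"))
  ggplot(df, aes(x = .data$group, y = .data$rho, fill = .data$direction)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "Spearman rho") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
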