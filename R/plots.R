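#' Plot the abundance of strategies in an evolved population
#'
#' Bar chart of the invariant-distribution weights of the most abundant
#' resident strategies.
#'
#' @param object an [evolve_population()] result.
#' @param top number of strategies shown.
#' @param ... unused.
#' @returns A ggplot object.
#' @export
autoplot.evolved_population <- function(object, top = 12, ...) {
  df <- tidy(object) |> head(top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$strategy, .data$weight),
                                   y = .data$weight, fill = .data$cooperation)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "forestgreen",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "abundance",
                  fill = "self-cooperation",
                  title = sprintf("%s information, q = %s", object$setting,
                                  format_transition_vector(object$q))) +
    ggplot2::theme_minimal()
}

#' Plot the weak-selection classification of deterministic games
#'
#' Bar diagram of the weak-selection value of information for the deterministic
#' transition vectors, colored by neutrality class. The panel is symmetric
#' about zero: the action-relabeling symmetry pairs every game that benefits
#' from information with one that benefits from ignorance.
#'
#' @param object a tibble from [classify_deterministic_games()].
#' @param ... unused.
#' @returns A ggplot object.
#' @export
plot_classification <- function(object, ...) {
  df <- object |> dplyr::arrange(.data$V0) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$V0, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "deterministic transition vectors (sorted)",
                  y = "value of information (weak selection)",
                  fill = "neutrality class") +
    ggplot2::theme_minimal()
}

#' Plot a value-of-information scan over a single-stochastic family
#'
#' @param object a long tibble from [scan_single_stochastic()] evaluated on a
#'   grid.
#' @param ... unused.
#' @returns A ggplot object (one line per family and selection strength).
#' @export
plot_family_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q_value, y = .data$V,
                                       color = factor(.data$beta),
                                       group = interaction(.data$family, .data$beta))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "stochastic transition probability",
                  y = "value of information", color = "beta") +
    ggplot2::theme_minimal()
}
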