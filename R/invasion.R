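#' Invasion graph of a deterministic strategy set
#'
#' Nodes are resident strategies annotated with their invariant-distribution
#' abundance and whether they are fully self-cooperative in the rare-error
#' limit. Directed edges record fixation probabilities relative to the neutral
#' benchmark `1/N`: an edge is `"solid"` when the mutant's fixation probability
#' strictly exceeds `1/N` (selection favors the invasion) and `"dotted"` when
#' it lies strictly between `1/(10N)` and `1/N` (almost-neutral drift). A
#' fixation probability of exactly `1/N` is neutral and draws no edge; smaller
#' values are omitted.
#'
#' @param setting `"full"` or `"none"`.
#' @param q a [transition_vector()].
#' @param params a [game_parameters()] object.
#' @param popparams a [population_parameters()] object.
#' @param top keep only the `top` most abundant strategies as nodes (and edges
#'   among them); `NULL` keeps all.
#' @param self_coop_tol tolerance for flagging a strategy as fully
#'   self-cooperative (limit self-cooperation rate above `1 - self_coop_tol`).
#' @returns An object of class `invasion_graph`: a list with tibbles `nodes`
#'   (`strategy_id`, `strategy`, `weight`, `self_cooperative`) and `edges`
#'   (`from`, `to`, `rho`, `type`), plus the parameters.
#' @export
invasion_graph <- function(setting, q, params = game_parameters(),
                           popparams = population_parameters(),
                           top = NULL, self_coop_tol = 1e-3) {
  ev <- evolve_population(setting, q, params, popparams)
  n <- length(ev$weights)
  keep <- seq_len(n)
  if (!is.null(top)) keep <- head(order(ev$weights, decreasing = TRUE), top)
  setting <- ev$setting
  # self-cooperation in the rare-error limit, per kept strategy
  self_coop <- vapply(keep, function(i) {
    p <- strategy_from_id(i - 1L, setting)
    v <- limit_stationary_distribution(p, p, q)
    cooperation_rate(v)
  }, numeric(1))
  labs <- vapply(keep, function(i) {
    strategy_label(as.numeric(strategy_from_id(i - 1L, setting)))
  }, character(1))
  nodes <- tibble::tibble(strategy_id = keep - 1L, strategy = labs,
                          weight = ev$weights[keep],
                          self_cooperative = self_coop > 1 - self_coop_tol)
  N <- popparams$N
  edges <- tidyr::expand_grid(from = keep, to = keep) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::mutate(rho = ev$rho[cbind(.data$from, .data$to)],
                  type = dplyr::case_when(
                    .data$rho > 1 / N ~ "solid",
                    .data$rho > 1 / (10 * N) & .data$rho < 1 / N ~ "dotted",
                    TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$type)) |>
    dplyr::mutate(from = .data$from - 1L, to = .data$to - 1L)
  structure(list(nodes = nodes, edges = edges, setting = setting,
                 q = transition_vector(q), params = params, popparams = popparams),
            class = "invasion_graph")
}

#' @export
print.invasion_graph <- function(x, ...) {
  cat(sprintf("<invasion graph> %s information, q = %s: %d nodes, %d solid / %d dotted edges\n",
              x$setting, format_transition_vector(x$q), nrow(x$nodes),
              sum(x$edges$type == "solid"), sum(x$edges$type == "dotted")))
  invisible(x)
}

#' Convert an invasion graph to an igraph object
#'
#' @param x an [invasion_graph()].
#' @returns An `igraph` directed graph with node attributes `weight` and
#'   `self_cooperative` and edge attributes `rho` and `type`.
#' @export
as_igraph <- function(x) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for graph export", call. = FALSE)
  }
  verts <- x$nodes |>
    dplyr::transmute(name = as.character(.data$strategy_id),
                     label = .data$strategy, weight = .data$weight,
                     self_cooperative = .data$self_cooperative)
  eds <- x$edges |>
    dplyr::transmute(from = as.character(.data$from), to = as.character(.data$to),
                     rho = .data$rho, type = .data$type)
  igraph::graph_from_data_frame(eds, directed = TRUE, vertices = verts)
}

#' Plot an invasion graph
#'
#' Nodes on a circle, sized by invariant-distribution abundance; fully
#' self-cooperative strategies are ringed. Solid edges mark fixation
#' probabilities above `1/N`, dotted edges almost-neutral drift.
#'
#' @param object an [invasion_graph()].
#' @param ... unused.
#' @returns A ggplot object.
#' @export
autoplot.invasion_graph <- function(object, ...) {
  nd <- object$nodes
  n <- nrow(nd)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nd$x <- cos(theta); nd$y <- sin(theta)
  ed <- object$edges |>
    dplyr::left_join(nd |> dplyr::select("strategy_id", x0 = "x", y0 = "y"),
                     by = c(from = "strategy_id")) |>
    dplyr::left_join(nd |> dplyr::select("strategy_id", x1 = "x", y1 = "y"),
                     by = c(to = "strategy_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linetype = .data$type),
                          color = "grey50",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y, size = .data$weight,
                                     color = .data$self_cooperative)) +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$strategy), size = 2.5) +
    ggplot2::scale_linetype_identity() +
    ggplot2::scale_color_manual(values = c(`TRUE` = "forestgreen", `FALSE` = "grey30")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(size = "abundance", color = "self-cooperative")
}
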