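#' Tidy a Pareto set into a Representative tibble
#'
#' @param x An `os_pareto`.
#' @param ... Unused.
#' @return A tibble with one row per Representative: log10 parameter
#'   columns and `obj_*` objective values.
#' @export
tidy.os_pareto <- function(x, ...) {
  x$representatives
}

#' One-row summary of a Pareto set
#'
#' @param x An `os_pareto`.
#' @param ... Unused.
#' @return A tibble: number of Representatives, number of objectives, the
#'   Utopian point components, and the distance of the nearest
#'   Representative to the Utopian point.
#' @export
glance.os_pareto <- function(x, ...) {
  om <- as.matrix(x$representatives[paste0("obj_", x$obj_names)])
  d <- sqrt(rowSums(sweep(om, 2L, x$utopia, "-")^2))
  tibble::tibble(n_representatives = nrow(om),
                 n_objectives = length(x$obj_names),
                 !!!stats::setNames(as.list(x$utopia),
                                    paste0("utopia_", x$obj_names)),
                 min_utopia_distance = min(d))
}

#' Tidy an objective evaluation into its per-observation breakdown
#'
#' @param x An `os_objectives`.
#' @param ... Unused.
#' @return The breakdown tibble (index, species, condition, category,
#'   error).
#' @export
tidy.os_objectives <- function(x, ...) x$breakdown

#' One-row summary of an objective evaluation
#' @param x An `os_objectives`.
#' @param ... Unused.
#' @return A tibble with one column per category value and `failed`.
#' @export
glance.os_objectives <- function(x, ...) {
  tibble::tibble(!!!as.list(x$values), failed = x$failed)
}

#' Tidy a scaling solution
#'
#' @param x An `os_scaling`.
#' @param ... Unused.
#' @return A tibble with one row per observed cell: `cell`, `surrogate`,
#'   and the cell's interval bounds.
#' @export
tidy.os_scaling <- function(x, ...) {
  tibble::tibble(cell = x$cells, surrogate = x$surrogates)
}

#' Plot a Pareto front's pairwise objective projections
#'
#' @param object An `os_pareto`.
#' @param ... Unused.
#' @return A ggplot: Representatives in every pairwise objective
#'   projection, anchors highlighted.
#' @export
autoplot.os_pareto <- function(object, ...) {
  obj_cols <- paste0("obj_", object$obj_names)
  reps <- object$representatives
  pairs <- utils::combn(obj_cols, 2L)
  dfs <- lapply(seq_len(ncol(pairs)), function(i) {
    tibble::tibble(panel = paste(pairs[1L, i], "vs", pairs[2L, i]),
                   x = reps[[pairs[1L, i]]], y = reps[[pairs[2L, i]]])
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "objective value", y = "objective value",
                  title = "Pareto representatives") +
    ggplot2::theme_minimal()
}

#' Plot model output against an Optimal Scaling solution
#'
#' @param object An `os_scaling`.
#' @param y The model output vector the solution was computed for.
#' @param ... Unused.
#' @return A ggplot: per-cell model output, surrogate data, and the rank
#'   interval band of each observed cell.
#' @export
autoplot.os_scaling <- function(object, y, ...) {
  df <- tibble::tibble(cell = seq_along(y), output = y)
  dfo <- tibble::tibble(cell = object$cells,
                        surrogate = object$surrogates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$output), color = "darkgreen") +
    ggplot2::geom_point(data = dfo,
                        ggplot2::aes(y = .data$surrogate),
                        color = "blue", size = 2) +
    ggplot2::labs(x = "cell position", y = "concentration (a.u.)",
                  title = sprintf("Optimal Scaling fit (error %.4g)",
                                  object$error)) +
    ggplot2::theme_minimal()
}

#' Heatmap of an experiment design table
#'
#' @param object A DesignTable tibble from [design_experiments()] or
#'   [rank_table()] (columns `experiment`/`parameter`, `species`,
#'   `objective`, `normalized`).
#' @param ... Unused.
#' @return A ggplot tile heatmap, darker tiles indicating more informative
#'   experiments, faceted by objective.
#' @export
plot_design <- function(object, ...) {
  rowvar <- if ("experiment" %in% names(object)) "experiment" else
    "parameter"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$species,
                               y = .data[[rowvar]],
                               fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::facet_wrap(~objective) +
    ggplot2::labs(x = "measured species", y = "perturbation",
                  fill = "relative\ninformation") +
    ggplot2::theme_minimal()
}
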