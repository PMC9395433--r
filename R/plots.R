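## ggplot2 visualisation: flat-map projections of per-vertex maps, design
## matrices, event-related averages and alignment traces.

#' Orthographic flat-map tibble of a per-vertex map
#'
#' Projects the occipital hemisphere (vertices with positive component along
#' `pole`) orthographically onto the plane perpendicular to `pole`.
#'
#' @param values per-vertex values.
#' @param mesh the `sphere_mesh`.
#' @param pole viewing direction (default +z, the synthetic occipital pole).
#' @return tibble with columns x, y, value.
#' @export
flatmap_data <- function(values, mesh, pole = c(0, 0, 1)) {
  pole <- pole / sqrt(sum(pole^2))
  up <- if (abs(pole[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- row_cross(matrix(up, 1), matrix(pole, 1))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- row_cross(matrix(pole, 1), e1)
  keep <- as.numeric(mesh$vertices %*% pole) > 0
  V <- mesh$vertices[keep, , drop = FALSE]
  tibble::tibble(
    x = as.numeric(V %*% as.numeric(e1)),
    y = as.numeric(V %*% as.numeric(e2)),
    value = as.numeric(values)[keep]
  )
}

#' Flat-map plot of a per-vertex map
#'
#' @inheritParams flatmap_data
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_surface_map <- function(values, mesh, pole = c(0, 0, 1), title = NULL) {
  df <- flatmap_data(values, mesh, pole)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$value)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(title = title, x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a probability map (occipital flat map)
#' @param object a [probability_map()].
#' @param mesh the `sphere_mesh`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot probability_map
#' @export
autoplot.probability_map <- function(object, mesh, ...) {
  plot_surface_map(object$values, mesh,
                   title = sprintf("Probability of activation overlap (n = %d)",
                                   object$n_subjects)) +
    ggplot2::labs(colour = "%")
}

#' Plot a probability difference map
#' @param object a [probability_difference_map()].
#' @param mesh the `sphere_mesh`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot probability_difference_map
#' @export
autoplot.probability_difference_map <- function(object, mesh, ...) {
  df <- flatmap_data(object$values, mesh)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$value)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey92",
                                    high = "darkorange") +
    ggplot2::labs(title = object$pair_label, colour = "Δ%") +
    ggplot2::theme_minimal()
}

#' Plot the condition regressors of a design matrix
#' @param object a [build_design()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot design_matrix
#' @export
autoplot.design_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object$matrix[, QUADRANTS]),
                  time = object$frame_times),
    -"time", names_to = "condition", values_to = "response"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$response,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "modelled response") +
    ggplot2::theme_minimal()
}

#' Plot the objective trace of a group alignment
#' @param object a `cba_alignment`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cba_alignment
#' @export
autoplot.cba_alignment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~level, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "morph / target-update step", y = "group objective") +
    ggplot2::theme_minimal()
}

#' Plot event-related averages with SEM ribbons
#' @param era the tibble from [event_related_average()].
#' @return a ggplot object.
#' @export
plot_event_related_average <- function(era) {
  ggplot2::ggplot(era, ggplot2::aes(x = .data$time, y = .data$mean,
                                    colour = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "peristimulus time (s)", y = "BOLD (signal units)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
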