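#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained multi-location model
#'
#' @param x A `multiloc_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per learned edge across the q classifiers
#'   (columns `target`, `from`, `to`, `edge_type` -- whether the edge links
#'   two location nodes or a feature to a location). `glance()`: one-row
#'   model summary.
#' @export
tidy.multiloc_model <- function(x, ...) {
  rows <- lapply(x$classifiers, function(cl) tidy.bn_classifier(cl))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      target = character(0), from = character(0), to = character(0),
      edge_type = character(0)
    ))
  }
  out |>
    dplyr::mutate(
      edge_type = dplyr::if_else(
        .data$from %in% x$locations & .data$to %in% x$locations,
        "location-location", "feature-location"
      )
    )
}

#' @rdname tidy.multiloc_model
#' @export
glance.multiloc_model <- function(x, ...) {
  edges <- vapply(
    x$classifiers,
    function(cl) sum(lengths(cl$structure$parents)), numeric(1)
  )
  tibble::tibble(
    n_locations = length(x$locations),
    n_features = length(x$feature_names),
    n_boundaries = sum(lengths(x$cutpoints$cutpoints)),
    total_edges = sum(edges),
    mean_cll = if (is.null(x$cll)) NA_real_ else mean(x$cll),
    alpha = x$classifiers[[1]]$cpts$alpha
  )
}

#' Plot cross-validation metrics
#'
#' Point-and-error-bar display of the run-level Acc, F1, and F1-label for
#' the Bayesian network collection versus the dependency-blind SVM
#' baseline.
#'
#' @param object A `multiloc_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multiloc_cv <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$metric, y = .data$mean, colour = .data$system)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
        ymax = .data$mean + dplyr::coalesce(.data$sd, 0)
      ),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "score (mean ± sd across runs)",
      colour = "system",
      title = "Multi-label performance: location dependencies vs baseline"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the CLL trajectory of a structure search
#'
#' @param object A `hill_climb` result.
#' @param ... Unused.
#' @return A ggplot object showing the conditional log likelihood after each
#'   applied move.
#' @export
autoplot.hill_climb <- function(object, ...) {
  tr <- object$trace
  start <- if (nrow(tr)) tr$cll_before[1] else object$cll
  df <- tibble::tibble(
    iteration = c(0L, tr$iteration),
    cll = c(start, tr$cll_after)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cll)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "iteration", y = "conditional log likelihood",
      title = "Greedy structure search trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a learned network structure
#'
#' Nodes are laid out on a circle (features left, locations right) with
#' directed edges drawn as arrows; the classifier's target location is
#' highlighted.
#'
#' @param classifier A `bn_classifier`.
#' @return A ggplot object.
#' @export
plot_structure <- function(classifier) {
  stopifnot(inherits(classifier, "bn_classifier"))
  s <- classifier$structure
  nn <- length(s$nodes)
  theta <- seq(0, 2 * pi, length.out = nn + 1)[-(nn + 1)]
  pos <- tibble::tibble(
    node = s$nodes,
    x = cos(theta), y = sin(theta),
    role = ifelse(s$is_feature, "feature",
      ifelse(seq_len(nn) == classifier$target, "target", "location")
    )
  )
  edges <- tidy.bn_structure(s)
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(edges)) {
    seg <- dplyr::left_join(edges, pos, by = c("from" = "node")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(pos, by = c("to" = "node")) |>
      dplyr::rename(x1 = "x", y1 = "y")
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      colour = "grey40"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role), size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$node), vjust = -1.2, size = 3) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(
      title = sprintf(
        "Classifier structure for %s", s$nodes[classifier$target]
      ),
      colour = NULL
    ) +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
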