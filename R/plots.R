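#' Plot a frequent-behavior transition matrix
#'
#' Heatmap of the transition probabilities, with states ordered as declared;
#' initial and episode-end probabilities are shown as annotated margins via
#' the axis labels.
#'
#' @param object A `behavior_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(load_fixture("michael_f1"))
#' @method autoplot behavior_model
#' @export
autoplot.behavior_model <- function(object, ...) {
  tr <- object$transitions
  tr$from <- factor(tr$from, levels = object$states)
  tr$to <- factor(tr$to, levels = object$states)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$p)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2g", .data$p)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = "Pr") +
    ggplot2::scale_y_discrete(limits = rev(object$states)) +
    ggplot2::labs(title = sprintf("Transition matrix of '%s'", object$id),
                  x = "to action", y = "from action") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an edit-distance matrix
#'
#' Tile plot of the dynamic-programming grid comparing an observed episode
#' (rows) with a path (columns); cell labels are the minimum modification
#' counts and the bottom-right cell is the episode's modification count.
#'
#' @param object A `distance_matrix` from [build_distance_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_matrix
#' @export
autoplot.distance_matrix <- function(object, ...) {
  d <- object$d
  df <- tidyr::expand_grid(m = 0:(nrow(d) - 1), n = 0:(ncol(d) - 1))
  df$value <- mapply(function(m, n) d[m + 1, n + 1], df$m, df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$m,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = .data$value), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "edits") +
    ggplot2::scale_y_reverse(breaks = 0:(nrow(d) - 1),
                             labels = c("", object$episode)) +
    ggplot2::scale_x_continuous(breaks = 0:(ncol(d) - 1),
                                labels = c("", object$path),
                                position = "top") +
    ggplot2::labs(x = "path", y = "observed episode") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 0))
}

#' Plot a shift report
#'
#' One bar per frequent behavior showing the modification count, filled by
#' the risk factor; anomalous behaviors are outlined.
#'
#' @param object A `shift_report` from [calculate_shifts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shift_report
#' @export
autoplot.shift_report <- function(object, ...) {
  r <- tidy(object)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$behavior_id,
                                  y = .data$modification_count,
                                  fill = .data$risk_factor)) +
    ggplot2::geom_col(ggplot2::aes(color = .data$anomalous), linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = NA, `TRUE` = "red"),
                                name = "anomalous") +
    ggplot2::scale_fill_gradient(low = "grey80", high = "firebrick",
                                 name = "risk factor") +
    ggplot2::labs(
      title = sprintf("Shift report for %s%s", object$episode_id,
                      if (object$matched) " (matches a frequent behavior)" else ""),
      x = NULL, y = "modifications needed") +
    ggplot2::theme_minimal()
}
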