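#' Plot player trajectories
#'
#' Trajectories of the selected players over the pitch, with their role
#' boxes, the ball path, and the pitch outline.
#'
#' @param object A `match_trace`.
#' @param players Player ids to draw (default all 22).
#' @param show_ball Draw the ball path?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_trace
#' @export
autoplot.match_trace <- function(object, players = 1:22, show_ball = TRUE,
                                 ...) {
  pl <- object$players %>% filter(.data$player_id %in% players)
  bx <- object$boxes %>% filter(.data$player_id %in% players)
  pitch <- object$config$pitch
  g <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = -pitch$xmax, xmax = pitch$xmax,
                   ymin = -pitch$ymax, ymax = pitch$ymax),
      fill = NA, colour = "grey30") +
    ggplot2::geom_rect(
      data = bx,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = NA, colour = "grey70", linetype = 2) +
    ggplot2::geom_path(
      data = pl,
      ggplot2::aes(x = .data$x, y = .data$y,
                   group = .data$player_id, colour = .data$team),
      alpha = 0.7, linewidth = 0.3)
  if (show_ball) {
    g <- g + ggplot2::geom_path(
      data = object$ball,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "black", alpha = 0.4, linewidth = 0.2)
  }
  g + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "team") +
    ggplot2::theme_minimal()
}

#' Plot the per-tick action frequency series
#'
#' @param trace A `match_trace`.
#' @param smooth Window (ticks) of the rolling mean applied for legibility;
#'   1 disables smoothing.
#' @return A ggplot object.
#' @export
plot_action_frequencies <- function(trace, smooth = 25) {
  fs <- action_frequency_series(trace)
  if (smooth > 1) {
    fs <- fs %>%
      group_by(.data$action) %>%
      arrange(.data$tick) %>%
      mutate(share = stats::filter(.data$share, rep(1 / smooth, smooth),
                                   sides = 1)) %>%
      ungroup() %>%
      filter(!is.na(.data$share))
  }
  ggplot2::ggplot(fs, ggplot2::aes(x = .data$tick, y = .data$share,
                                   colour = .data$action)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "tick", y = "share of players (%)",
                  colour = "action") +
    ggplot2::theme_minimal()
}

#' Plot a replicate-stabilization curve
#'
#' @param object A `cv_curve` from [cv_stabilization()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_curve
#' @export
autoplot.cv_curve <- function(object, ...) {
  g <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$k, y = .data$cv)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "replicates", y = "aggregated CV") +
    ggplot2::theme_minimal()
  if (!is.na(object$stabilization)) {
    g <- g + ggplot2::geom_vline(xintercept = object$stabilization,
                                 linetype = 2, colour = "red")
  }
  g
}

#' Plot a relative-orientation histogram as a polar rose
#'
#' @param trace A `match_trace`.
#' @param player_id Observing player.
#' @param target `"ball"` or a player id.
#' @return A ggplot object.
#' @export
plot_orientation_rose <- function(trace, player_id, target = "ball") {
  h <- relative_orientation_histogram(trace, player_id, target)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$class, y = .data$share)) +
    ggplot2::geom_col(width = 10, fill = "steelblue", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_x_continuous(breaks = seq(-150, 180, 30),
                                limits = c(-185, 185)) +
    ggplot2::labs(x = "relative orientation (deg; negative = left)",
                  y = "share of ticks (%)") +
    ggplot2::theme_minimal()
}

#' Plot a possession matrix
#'
#' @param object A `possession_matrix`.
#' @param ... Unused.
#' @return A ggplot heat map of completed passes (from row to column).
#' @method autoplot possession_matrix
#' @export
autoplot.possession_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(object$passes))
  names(df) <- c("from", "to", "n")
  df$from <- as.integer(as.character(df$from))
  df$to <- as.integer(as.character(df$to))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen") +
    ggplot2::labs(x = "to player", y = "from player", fill = "passes") +
    ggplot2::theme_minimal()
}
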