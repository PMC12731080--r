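# ggplot2 displays for confusion matrices, LOSO runs and raw sessions.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

confusion_heatmap <- function(m, fill_label) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m, .name_repair = "minimal"),
                  truth = factor(rownames(m), levels = rownames(m))),
    -"truth", names_to = "estimate", values_to = "value"
  )
  df$estimate <- factor(df$estimate, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$value > 0,
                                                   sprintf("%.0f", .data$value), "")),
                       size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 name = fill_label) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::labs(x = "Predicted region", y = "True region") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `brush_confusion` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brush_confusion
#' @export
autoplot.brush_confusion <- function(object, ...) {
  confusion_heatmap(unclass(object), "windows")
}

#' Averaged row-normalised confusion heatmap of a LOSO run
#'
#' Rows are true regions, cells the mean per-fold percentage of that region's
#' windows predicted as each region (each row averages to 100%).
#'
#' @param object A `brush_loso` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brush_loso
#' @export
autoplot.brush_loso <- function(object, ...) {
  confusion_heatmap(object$confusion_avg, "% of true class")
}

#' Plot the signal channels of one simulated or recorded session
#'
#' Acceleration norm, angular-velocity norm and Euler angles over time, with
#' brushing regions shaded — the standard visual check that transitions carry
#' the gyro peaks and regions carry distinct orientations.
#'
#' @param sessions Session tibble.
#' @param session_id Which session to plot (default: first).
#' @param placement `"TB"` or `"WR"`.
#' @return A ggplot object.
#' @export
plot_session <- function(sessions, session_id = NULL, placement = "TB") {
  sessions <- validate_sessions(sessions)
  if (is.null(session_id)) session_id <- sessions$session_id[1]
  s <- sessions[sessions$session_id == session_id &
                  sessions$placement == placement, ]
  if (nrow(s) == 0) stop("no samples for that session/placement", call. = FALSE)
  eu <- quat_to_euler(as.matrix(s[, c("qw", "qx", "qy", "qz")]))
  df <- tibble::tibble(
    t = rep(s$t, 5),
    value = c(sqrt(s$ax^2 + s$ay^2 + s$az^2),
              sqrt(s$gx^2 + s$gy^2 + s$gz^2),
              eu$pitch, eu$roll, eu$yaw),
    channel = rep(c("|a| (m/s^2)", "|g| (rad/s)", "pitch (deg)",
                    "roll (deg)", "yaw (deg)"), each = nrow(s)),
    region = rep(factor(s$label), 5)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$region)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
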