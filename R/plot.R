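#' Plot a recording
#'
#' Acceleration magnitude per channel over time, faceted by placement, with
#' ground-truth label windows shaded.
#'
#' @param object A `pk_recording`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pk_recording <- function(object, ...) {
  spec <- recording_spec(object)
  d <- mutate(as_tibble(object),
              magnitude_g = sqrt(ax^2 + ay^2 + az^2) * spec$lsb_g)
  lab <- recording_labels(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(t, magnitude_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~placement, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "|a| (g)") +
    ggplot2::theme_minimal()
  if (nrow(lab))
    p <- p + ggplot2::geom_rect(
      data = lab,
      ggplot2::aes(xmin = start, xmax = end, ymin = -Inf, ymax = Inf,
                   fill = kind),
      alpha = 0.15, inherit.aes = FALSE)
  p
}

#' Plot tilt streams
#'
#' Pitch, roll and inclination per channel over time.
#'
#' @param object A `pk_tilt` from [transform_tilt()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pk_tilt <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           c(pitch, roll, inclination),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(t, value, colour = series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~placement, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a long-term gait trend
#'
#' The festination-tracking view: monthly mean step symmetry index (line),
#' its standard deviation (bars), and the mean forward-lean angle while
#' walking (second line, right-hand scale labelling).
#'
#' @param object A `pk_trend` from [aggregate_trend()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pk_trend <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = period)) +
    ggplot2::geom_col(ggplot2::aes(y = sd_symmetry, fill = "sd symmetry"),
                      alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = mean_symmetry, group = 1,
                                    colour = "mean symmetry"), na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = mean_lean, group = 1,
                                    colour = "mean forward lean"),
                       na.rm = TRUE) +
    ggplot2::scale_fill_manual(NULL, values = c("sd symmetry" = "seagreen")) +
    ggplot2::scale_colour_manual(NULL, values = c(
      "mean symmetry" = "steelblue", "mean forward lean" = "firebrick")) +
    ggplot2::labs(x = NULL, y = "symmetry (%) / lean (deg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
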