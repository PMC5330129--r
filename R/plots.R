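#' Plot a QRS detection
#'
#' The preprocessed signal with detected complexes shaded and R-peak
#' fiducials marked.
#'
#' @param object A `qrs_detection` from [detect_qrs()].
#' @param window_s Optional length-2 numeric: time window (seconds) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qrs_detection <- function(object, window_s = NULL, ...) {
  df <- as_tibble(object$signal)
  beats <- object$beats
  if (!is.null(window_s)) {
    df <- dplyr::filter(df, .data$time >= window_s[1], .data$time <= window_s[2])
    beats <- dplyr::filter(beats, .data$onset_s <= window_s[2],
                           .data$offset_s >= window_s[1])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3)
  if (nrow(beats)) {
    p <- p +
      ggplot2::geom_rect(
        data = beats, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                     ymin = -Inf, ymax = Inf),
        alpha = 0.15, fill = "firebrick") +
      ggplot2::geom_point(
        data = dplyr::mutate(beats,
                             amp = purrr::map_dbl(.data$r_peak,
                                                  \(i) object$signal[[i + 1L]])),
        inherit.aes = FALSE,
        ggplot2::aes(x = .data$r_peak_s, y = .data$amp),
        colour = "firebrick", size = 1.5)
  }
  p + ggplot2::labs(x = "time (s)", y = "normalized amplitude",
                    title = sprintf("%d detected beats", nrow(object$beats)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SNR robustness sweep
#'
#' Mean sensitivity and specificity (positive predictivity) per SNR level,
#' averaged over seeds.
#'
#' @param sweep A tibble from [snr_sweep()].
#' @return A ggplot object.
#' @export
plot_snr_sweep <- function(sweep) {
  agg <- sweep |>
    dplyr::group_by(.data$snr_db) |>
    dplyr::summarise(Se = mean(.data$se_pct), Sp = mean(.data$sp_pct)) |>
    tidyr::pivot_longer(c("Se", "Sp"), names_to = "rate",
                        values_to = "percent")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$snr_db, y = .data$percent,
                                    colour = .data$rate)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "SNR (dB)", y = "%", colour = NULL)
}
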