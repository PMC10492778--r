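#' Plot a per-soma signal distribution
#'
#' Histogram of the sampled per-soma signals (fixed bin count), annotated with
#' the dip-type unimodality diagnostic.
#'
#' @param x A [signal_histogram()] result.
#' @param fill Bar fill colour.
#' @return A ggplot object.
#' @export
plot_signal_distribution <- function(x, fill = "#3182bd") {
  stopifnot(inherits(x, "signal_histogram"))
  ggplot2::ggplot(x$histogram, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = fill, width = diff(range(x$histogram$mid)) / x$bins) +
    ggplot2::labs(
      x = "per-soma signal (a.u.)", y = "somas",
      subtitle = sprintf(
        "n = %d, %d bins; dip = %.3f (MC p = %.2f)",
        x$n, x$bins, x$dip, x$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot aggregated TES profiles
#'
#' Experiment-level mean and SEM per condition, DIV and compartment pair, on
#' a log scale as customary for transfer efficiencies spanning orders of
#' magnitude.
#'
#' @param tes_summary Output of [aggregate_tes()].
#' @param percent Display TES as percentages.
#' @return A ggplot object.
#' @export
plot_tes <- function(tes_summary, percent = TRUE) {
  f <- if (percent) 100 else 1
  dat <- dplyr::mutate(tes_summary,
    m = .data$mean_tes * f,
    lo = (.data$mean_tes - .data$sem_tes) * f,
    hi = (.data$mean_tes + .data$sem_tes) * f,
    div = factor(.data$div)
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$pair, y = .data$m,
    colour = .data$condition, shape = .data$div
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL,
      y = if (percent) "TES (%)" else "TES (fraction)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a kymograph
#'
#' Time runs downward (acquisition order), position along the channel to the
#' right; moving particles appear as sloped traces.
#'
#' @param object A [build_kymograph()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    frame = seq_len(nrow(object$image)),
    pos = seq_len(ncol(object$image))
  )
  df$intensity <- as.vector(t(object$image))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos * object$pixel_size_um,
    y = .data$frame * object$frame_interval_s,
    fill = .data$intensity
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "position (um)", y = "time (s)", fill = "a.u.") +
    ggplot2::theme_minimal()
}

#' Autoplot detected tracks over speed
#'
#' @param object Track tibble from [detect_tracks()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_track_speeds <- function(object, ...) {
  mv <- dplyr::filter(object, .data$moving)
  ggplot2::ggplot(mv, ggplot2::aes(x = .data$speed_um_s)) +
    ggplot2::geom_histogram(bins = 30, fill = "#31a354") +
    ggplot2::labs(x = "particle speed (um/s)", y = "tracks") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
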