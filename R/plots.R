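# ggplot2 views of episodes and trial results, mirroring the layout of a
# bedside recording: SpO2 over time with the target band, FiO2 set and
# proposed, and the monitor vitals underneath.

#' Plot an episode recording
#'
#' Faceted time-series view: SpO2 with the 92-96% target band shaded, the
#' FiO2 actually set and the controller's proposals, and heart rate /
#' perfusion index from the monitor. Suction and desaturation events are
#' marked.
#'
#' @param object An `oxy_episode` from [run_episode()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oxy_episode
#' @export
autoplot.oxy_episode <- function(object, ...) {
  s <- object$samples
  cfg <- object$meta$policy
  band <- if (inherits(cfg, "oxy_controller_config")) {
    c(cfg$spo2_low, cfg$spo2_high)
  } else {
    c(92, 96)
  }
  long <- dplyr::bind_rows(
    tibble::tibble(t_min = s$t_s / 60, value = as.numeric(s$spo2),
                   signal = "SpO2 (%)"),
    tibble::tibble(t_min = s$t_s / 60, value = 100 * s$fio2_set,
                   signal = "FiO2 set (%)"),
    tibble::tibble(t_min = s$t_s / 60, value = 100 * s$fio2_proposed,
                   signal = "FiO2 proposed (%)"),
    tibble::tibble(t_min = s$t_s / 60, value = s$hr, signal = "Heart rate (/min)"),
    tibble::tibble(t_min = s$t_s / 60, value = s$pi, signal = "Perfusion index (%)")
  )
  long <- long[!is.na(long$value), ]
  long$signal <- factor(long$signal,
                        levels = c("SpO2 (%)", "FiO2 set (%)",
                                   "FiO2 proposed (%)", "Heart rate (/min)",
                                   "Perfusion index (%)"))
  band_df <- tibble::tibble(signal = factor("SpO2 (%)", levels = levels(long$signal)),
                            ymin = band[1], ymax = band[2])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_rect(
      data = band_df,
      ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
      xmin = -Inf, xmax = Inf,
      inherit.aes = FALSE, fill = "seagreen", alpha = 0.15
    ) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL,
                  title = sprintf("Episode recording (policy: %s)",
                                  object$meta$profile)) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot crossover trial outcomes
#'
#' Per-patient normoxemia percentages by profile and severity stratum, with
#' paired patients connected — the crossover trial's primary picture.
#'
#' @param object An `oxy_crossover` from [run_crossover()].
#' @param outcome Summary column to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oxy_crossover
#' @export
autoplot.oxy_crossover <- function(object, outcome = "pct_normoxemia", ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$profile,
                                    y = .data[[outcome]],
                                    group = .data$patient)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(color = .data$matched), size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = "Step-table profile", y = outcome,
                  color = "severity-matched",
                  title = "Crossover outcomes by profile and stratum") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Stacked time-in-range bars
#'
#' Displays one or more range summaries as stacked percentage bars over the
#' five reported categories (hypoxemia / normoxemia / hyperoxemia /
#' no-signal / low-SIQ).
#'
#' @param summaries A tibble of range summaries (rows) as returned by
#'   [time_in_ranges()] or [tidy()] on a crossover, with an optional `label`
#'   column.
#' @return A ggplot object.
#' @export
plot_range_summary <- function(summaries) {
  df <- tibble::as_tibble(summaries)
  if (!"label" %in% names(df)) df$label <- paste0("episode ", seq_len(nrow(df)))
  long <- tidyr::pivot_longer(
    df[, c("label", "pct_hypoxemia", "pct_normoxemia", "pct_hyperoxemia",
           "pct_no_signal", "pct_low_siq")],
    -"label", names_to = "category", values_to = "pct"
  )
  long$category <- factor(
    long$category,
    levels = c("pct_hyperoxemia", "pct_normoxemia", "pct_hypoxemia",
               "pct_no_signal", "pct_low_siq"),
    labels = c("hyperoxemia (>=97%)", "normoxemia (92-96%)",
               "hypoxemia (<=91%)", "no signal", "SIQ <= 0.3")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$pct,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      "hyperoxemia (>=97%)" = "#d95f02", "normoxemia (92-96%)" = "#1b9e77",
      "hypoxemia (<=91%)" = "#7570b3", "no signal" = "grey60",
      "SIQ <= 0.3" = "grey80"
    )) +
    ggplot2::labs(x = NULL, y = "% of recorded time", fill = NULL) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal(base_size = 10)
}
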