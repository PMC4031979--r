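# Pulse-oximeter model: turns the true arterial saturation at the probe into
# the 1-Hz, 2-s-averaged, integer-quantized, quality-annotated SpO2 stream a
# bedside monitor reports.

#' Pulse-oximeter model parameters
#'
#' @param noise_sd Gaussian measurement noise, % SpO2 (default 0.5).
#' @param averaging_window Trailing averaging interval, seconds (default 2,
#'   matching a monitor set to a 2-second averaging mode).
#' @param dropout_rate Signal-loss episodes per hour (default 0.5).
#' @param dropout_duration Duration of each signal-loss episode, seconds.
#' @param low_siq_rate Low-signal-quality episodes per hour (default 0.5),
#'   during which the reported SIQ falls below the 0.30 reliability cutoff
#'   while the displayed SpO2 may be arbitrary.
#' @param low_siq_duration Duration of each low-SIQ episode, seconds.
#'
#' @return An object of class `oxy_sensor` (a named list).
#' @export
sensor_params <- function(noise_sd = 0.5,
                          averaging_window = 2,
                          dropout_rate = 0.5,
                          dropout_duration = 30,
                          low_siq_rate = 0.5,
                          low_siq_duration = 20) {
  if (averaging_window <= 0) abort("`averaging_window` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (dropout_rate < 0 || low_siq_rate < 0) abort("event rates must be non-negative.")
  structure(
    list(
      noise_sd = noise_sd,
      averaging_window = averaging_window,
      dropout_rate = dropout_rate,
      dropout_duration = dropout_duration,
      low_siq_rate = low_siq_rate,
      low_siq_duration = low_siq_duration
    ),
    class = "oxy_sensor"
  )
}

# Poisson-process event intervals [start, end) within [0, n_s), as a tibble.
draw_event_intervals <- function(n_s, rate_per_h, duration_s) {
  if (rate_per_h <= 0 || n_s <= 0) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  n_ev <- rpois(1, rate_per_h * n_s / 3600)
  if (n_ev == 0) return(tibble::tibble(start = numeric(), end = numeric()))
  starts <- sort(runif(n_ev, 0, n_s))
  tibble::tibble(start = starts, end = pmin(starts + duration_s, n_s))
}

in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (t >= intervals$start[i] & t < intervals$end[i])
  }
  out
}

#' Sample the oximeter once
#'
#' Produces one quality-annotated reading at time `t` from a true-saturation
#' history: the trailing `averaging_window` of true SaO2 is averaged, Gaussian
#' noise added, and the result rounded to integer percent and clamped to
#' `[0, 100]`. A gap in the history yields a no-signal sample rather than an
#' error.
#'
#' @param true_sao2_history A data frame with columns `t_s` and `sao2_probe`
#'   (or `sao2`), saturation as fractions at 1-s ticks.
#' @param t Sampling time, seconds.
#' @param params [sensor_params()].
#' @param forced_dropout,forced_low_siq Logical: force a no-signal or low-SIQ
#'   annotation for this sample (used by the stream generator).
#' @return A one-row tibble: `t_s`, `spo2`, `hr`, `pi`, `siq`,
#'   `signal_present`.
#' @export
sample_oximeter <- function(true_sao2_history, t, params = sensor_params(),
                            forced_dropout = FALSE, forced_low_siq = FALSE) {
  sat_col <- if ("sao2_probe" %in% names(true_sao2_history)) "sao2_probe" else "sao2"
  w <- true_sao2_history$t_s > t - params$averaging_window &
    true_sao2_history$t_s <= t
  sats <- true_sao2_history[[sat_col]][w]
  if (length(sats) == 0 || anyNA(sats)) forced_dropout <- TRUE

  if (forced_dropout) {
    return(tibble::tibble(
      t_s = t, spo2 = NA_integer_, hr = NA_real_, pi = NA_real_,
      siq = 0, signal_present = FALSE
    ))
  }
  spo2 <- round(100 * mean(sats) + rnorm(1, 0, params$noise_sd))
  spo2 <- as.integer(min(100, max(0, spo2)))
  siq <- if (forced_low_siq) runif(1, 0, 0.29) else runif(1, 0.7, 1)
  if (forced_low_siq) spo2 <- as.integer(min(100, max(0, spo2 + round(rnorm(1, 0, 5)))))
  tibble::tibble(
    t_s = t,
    spo2 = spo2,
    hr = round(80 + rnorm(1, 0, 2), 1),
    pi = round(2 + abs(rnorm(1, 0, 0.5)), 2),
    siq = round(siq, 3),
    signal_present = TRUE
  )
}

#' Generate the full 1-Hz oximeter stream for an episode
#'
#' Vectorized equivalent of calling [sample_oximeter()] at every second:
#' trailing-window averaging, additive Gaussian noise, integer quantization,
#' plus Poisson-scheduled dropout and low-SIQ episodes. Fully reproducible
#' under `set.seed()`.
#'
#' @param truth Output of [simulate_true_saturation()] (columns `t_s`,
#'   `sao2_probe`).
#' @param params [sensor_params()].
#' @return A list: `samples` (tibble `t_s`, `spo2`, `hr`, `pi`, `siq`,
#'   `signal_present`, one row per second) and `events` (tibble of dropout /
#'   low-SIQ intervals with `kind`, `start`, `end`).
#' @export
oximeter_stream <- function(truth, params = sensor_params()) {
  n <- nrow(truth)
  sat <- truth$sao2_probe
  w <- max(1L, as.integer(round(params$averaging_window)))
  # trailing mean over the last w ticks (incomplete head uses what exists)
  cs <- cumsum(sat)
  avg <- (cs - c(rep(0, w), cs)[seq_len(n)]) / pmin(seq_len(n), w)

  dropouts <- draw_event_intervals(n, params$dropout_rate, params$dropout_duration)
  lowsiq <- draw_event_intervals(n, params$low_siq_rate, params$low_siq_duration)
  t_s <- truth$t_s
  is_drop <- in_intervals(t_s, dropouts)
  is_low <- in_intervals(t_s, lowsiq) & !is_drop

  spo2 <- as.integer(pmin(100, pmax(0, round(100 * avg + rnorm(n, 0, params$noise_sd)))))
  spo2[is_low] <- as.integer(pmin(100, pmax(0, spo2[is_low] + round(rnorm(sum(is_low), 0, 5)))))
  siq <- round(runif(n, 0.7, 1), 3)
  siq[is_low] <- round(runif(sum(is_low), 0, 0.29), 3)
  siq[is_drop] <- 0
  spo2[is_drop] <- NA_integer_

  hr <- round(80 + rnorm(n, 0, 2), 1)
  pi <- round(2 + abs(rnorm(n, 0, 0.5)), 2)
  hr[is_drop] <- NA_real_
  pi[is_drop] <- NA_real_

  events <- dplyr::bind_rows(
    dplyr::mutate(dropouts, kind = "DROPOUT"),
    dplyr::mutate(lowsiq, kind = "LOW_SIQ")
  )
  list(
    samples = tibble::tibble(
      t_s = t_s, spo2 = spo2, hr = hr, pi = pi, siq = siq,
      signal_present = !is_drop
    ),
    events = events[, intersect(c("kind", "start", "end"), names(events))]
  )
}
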