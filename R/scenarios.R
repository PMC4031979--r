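# Closed-loop experiment orchestration: a 1-Hz simulation loop wiring the
# virtual patient, the oximeter model and a policy (the FiO2 controller or a
# usual-care caricature) together, plus the two-profile crossover trial the
# controller was evaluated with.

#' Trial plan
#'
#' Study conditions for simulated episodes and the crossover trial: two
#' 3-hour periods per patient in randomized order, 1-Hz sampling, around two
#' suctioning episodes per period (each preceded by preoxygenation to 100%
#' FiO2 and masked for 15 minutes in profile comparisons), and transient
#' desaturation events modeled as Poisson-arriving shunt-fraction increases.
#'
#' @param n_per_stratum Patients per severity stratum (default 10 + 10).
#' @param period_h Duration of one treatment period, hours.
#' @param suction_per_period Expected suctioning episodes per period.
#' @param suction_duration_s Seconds during which suction (with
#'   preoxygenation) forces FiO2 to 1.0.
#' @param suction_mask_min Minutes excluded per suction episode in
#'   comparisons.
#' @param desat_rate_per_h Poisson rate of transient desaturation events.
#' @param desat_shunt_min,desat_shunt_max Added shunt fraction during an
#'   event (uniform draw).
#' @param desat_dur_min_s,desat_dur_max_s Event duration bounds, seconds.
#' @param sensor [sensor_params()] for the oximeter model.
#' @return An object of class `oxy_trial_plan`.
#' @export
trial_plan <- function(n_per_stratum = 10,
                       period_h = 3,
                       suction_per_period = 2,
                       suction_duration_s = 180,
                       suction_mask_min = 15,
                       desat_rate_per_h = 1,
                       desat_shunt_min = 0.10,
                       desat_shunt_max = 0.25,
                       desat_dur_min_s = 120,
                       desat_dur_max_s = 600,
                       sensor = sensor_params()) {
  if (period_h <= 0) abort("`period_h` must be positive.")
  structure(
    list(
      n_per_stratum = n_per_stratum, period_h = period_h,
      suction_per_period = suction_per_period,
      suction_duration_s = suction_duration_s,
      suction_mask_min = suction_mask_min,
      desat_rate_per_h = desat_rate_per_h,
      desat_shunt_min = desat_shunt_min, desat_shunt_max = desat_shunt_max,
      desat_dur_min_s = desat_dur_min_s, desat_dur_max_s = desat_dur_max_s,
      sensor = sensor
    ),
    class = "oxy_trial_plan"
  )
}

#' Usual-care baseline policy
#'
#' A deliberately simple caricature of manual FiO2 management for the
#' historical-control comparison: the bedside nurse reacts to a low-SpO2
#' alarm by raising FiO2, and lowers it only at periodic checks when SpO2 is
#' clearly high. Not fitted to any real cohort.
#'
#' @param check_interval_min Minutes between routine checks.
#' @param alarm_spo2 Low-SpO2 alarm threshold, %.
#' @param raise_step FiO2 increase on alarm (fraction).
#' @param lower_step FiO2 decrease at a check when SpO2 >= `lower_spo2`.
#' @param lower_spo2 SpO2 at or above which FiO2 is lowered at checks, %.
#' @param alarm_response_s Seconds between alarm evaluations.
#' @return An object of class `oxy_usual_care`.
#' @export
usual_care_policy <- function(check_interval_min = 30,
                              alarm_spo2 = 92,
                              raise_step = 0.10,
                              lower_step = 0.05,
                              lower_spo2 = 98,
                              alarm_response_s = 60) {
  if (check_interval_min <= 0) abort("`check_interval_min` must be positive.")
  structure(
    list(
      check_interval_min = check_interval_min, alarm_spo2 = alarm_spo2,
      raise_step = raise_step, lower_step = lower_step,
      lower_spo2 = lower_spo2, alarm_response_s = alarm_response_s
    ),
    class = "oxy_usual_care"
  )
}

draw_desat_events <- function(n_s, plan) {
  ev <- draw_event_intervals(n_s, plan$desat_rate_per_h,
                             plan$desat_dur_max_s)
  if (nrow(ev) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          magnitude = numeric()))
  }
  dur <- runif(nrow(ev), plan$desat_dur_min_s, plan$desat_dur_max_s)
  tibble::tibble(
    start = ev$start,
    end = pmin(ev$start + dur, n_s),
    magnitude = runif(nrow(ev), plan$desat_shunt_min, plan$desat_shunt_max)
  )
}

draw_suction_events <- function(n_s, plan) {
  k <- plan$suction_per_period
  if (k <= 0) return(numeric())
  # keep events off the very edges so preoxygenation and recovery are observed
  sort(runif(k, 0.05 * n_s, 0.9 * n_s))
}

#' Run one closed-loop episode
#'
#' Simulates one treatment period at 1 Hz: each second the virtual patient is
#' advanced under the currently applied FiO2, the oximeter reports a sample,
#' and the policy reacts — the FiO2 controller checks the rescue rule every
#' second and takes a table-step decision every 30 s, while the usual-care
#' policy reacts at its own check cadence. Suctioning episodes force FiO2 to
#' 1.0 (preoxygenation) for their duration, after which control returns to
#' the policy. Everything is reproducible from `seed`.
#'
#' @param patient [patient_params()].
#' @param policy Either a [controller_config()] (automated controller) or a
#'   [usual_care_policy()].
#' @param plan [trial_plan()].
#' @param seed Integer seed for this episode's disturbances, sensor noise and
#'   event schedules.
#' @param profile Optional [profile()] override; defaults to the profile
#'   named in the controller config (ignored for usual care).
#' @param init_fio2 Starting FiO2; by default the severity-appropriate
#'   baseline (0.40 for shunt >= 0.18, 0.30 otherwise).
#' @return An `oxy_episode`: list with `samples` (the 9-column episode log),
#'   `truth` (true SaO2/PaO2/effective-FiO2 trajectory), `events` (suction,
#'   desaturation, sensor events) and `meta` (patient, policy, plan, seed).
#' @export
run_episode <- function(patient, policy, plan = trial_plan(), seed = 1,
                        profile = NULL, init_fio2 = NULL) {
  set.seed(seed)
  n <- as.integer(round(plan$period_h * 3600))
  if (is.null(init_fio2)) {
    init_fio2 <- if (patient$shunt_fraction >= 0.18) 0.40 else 0.30
  }
  is_controller <- inherits(policy, "oxy_controller_config")
  if (is_controller && is.null(profile)) profile <- oxyloop::profile(policy$profile_id)

  # disturbance schedules drawn up-front so the episode is a pure function of
  # the seed
  desat <- draw_desat_events(n, plan)
  suction_onsets <- draw_suction_events(n, plan)
  suction_iv <- if (length(suction_onsets)) {
    merge_intervals(suction_onsets, suction_onsets + plan$suction_duration_s)
  } else {
    tibble::tibble(start = numeric(), end = numeric())
  }
  sensor <- plan$sensor
  sensor_dropouts <- draw_event_intervals(n, sensor$dropout_rate,
                                          sensor$dropout_duration)
  sensor_lowsiq <- draw_event_intervals(n, sensor$low_siq_rate,
                                        sensor$low_siq_duration)
  noise <- rnorm(n, 0, sensor$noise_sd)
  siq_good <- round(runif(n, 0.7, 1), 3)
  siq_bad <- round(runif(n, 0, 0.29), 3)
  lowsiq_jitter <- round(rnorm(n, 0, 5))
  hr <- round(80 + rnorm(n, 0, 2), 1)
  pi_ <- round(2 + abs(rnorm(n, 0, 0.5)), 2)

  tvec <- seq_len(n) - 1
  # overlapping desaturation events elevate the shunt to the largest event's
  # magnitude (one diseased compartment), not the sum
  shunt <- rep(patient$shunt_fraction, n)
  if (nrow(desat) > 0) {
    elev <- numeric(n)
    for (i in seq_len(nrow(desat))) {
      idx <- tvec >= desat$start[i] & tvec < desat$end[i]
      elev[idx] <- pmax(elev[idx], desat$magnitude[i])
    }
    shunt <- pmin(0.95, shunt + elev)
  }
  in_suction <- in_intervals(tvec, suction_iv)
  is_drop <- in_intervals(tvec, sensor_dropouts)
  is_low <- in_intervals(tvec, sensor_lowsiq) & !is_drop

  # physiology fast path (mirrors simulate_true_saturation, but FiO2 is
  # decided online by the policy)
  alpha <- 1 - exp(-1 / patient$tau_alveolar)
  pb47 <- patient$barometric_pressure - 47
  pc_term <- patient$paco2 / patient$resp_quotient
  hb <- patient$hb
  dav <- patient$av_o2_diff
  n_delay <- max(0L, as.integer(round(patient$circ_delay)))
  w_avg <- max(1L, as.integer(round(sensor$averaging_window)))

  ss0 <- steady_state_oxygenation(init_fio2, patient)
  fe <- init_fio2
  p_prev <- ss0$pao2
  sao2_probe_hist <- rep(ss0$sao2, n_delay + w_avg) # delay line + averaging tail

  fio2_set <- numeric(n)
  fio2_proposed <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  spo2 <- rep(NA_integer_, n)
  siq <- numeric(n)
  sao2_true <- numeric(n)
  pao2_true <- numeric(n)
  fio2_eff <- numeric(n)

  if (is_controller) {
    cstate <- controller_state_init(init_fio2, t = 0, config = policy)
  } else {
    uc_fio2 <- init_fio2
    uc_last_alarm_t <- -Inf
  }
  applied <- init_fio2

  for (i in seq_len(n)) {
    t_now <- tvec[i]

    # --- patient step under the FiO2 applied during this second
    fio2_in <- if (in_suction[i]) 1.0 else applied
    fe <- fe + (fio2_in - fe) * alpha
    pa_alv <- fe * pb47 - pc_term
    g <- pa_alv^3 + 150 * pa_alv
    scc <- g / (g + 23400)
    ca <- 1.34 * hb * scc + 0.003 * pa_alv - shunt[i] * dav / (1 - shunt[i])
    p <- solve_pao2_for_content(ca, hb, start = p_prev)
    p_prev <- p
    g <- p^3 + 150 * p
    s_now <- g / (g + 23400)
    sao2_probe_hist <- c(sao2_probe_hist[-1], s_now)
    s_probe <- sao2_probe_hist[length(sao2_probe_hist) - n_delay]

    sao2_true[i] <- s_now
    pao2_true[i] <- p
    fio2_eff[i] <- fe
    fio2_set[i] <- fio2_in

    # --- oximeter sample (trailing average over the probe signal)
    if (is_drop[i]) {
      spo2[i] <- NA_integer_
      siq[i] <- 0
    } else {
      tail_idx <- seq(length(sao2_probe_hist) - n_delay - w_avg + 1,
                      length(sao2_probe_hist) - n_delay)
      m <- mean(sao2_probe_hist[tail_idx])
      v <- round(100 * m + noise[i])
      if (is_low[i]) {
        v <- v + lowsiq_jitter[i]
        siq[i] <- siq_bad[i]
      } else {
        siq[i] <- siq_good[i]
      }
      spo2[i] <- as.integer(min(100, max(0, v)))
    }

    # --- log the proposal in force during this second, then let the policy
    # react (a new proposal governs from the next second)
    if (in_suction[i]) {
      # clinician override: preoxygenation at 100% FiO2, no controller
      # proposal in force; the controller tracks the actually set FiO2 so it
      # weans down from 100% afterwards
      reason[i] <- "SUCTION"
      if (is_controller) {
        cstate$fio2_current <- 1.0
        cstate$last_valid_fio2 <- 1.0
        cstate$last_change_t <- t_now
        cstate <- update_effective_fio2(cstate, 1, policy)
        applied <- 1.0
      }
      next
    }
    if (is_controller) {
      fio2_proposed[i] <- applied # the standing proposal the nurse executes
      cstate <- update_effective_fio2(cstate, 1, policy)
      smp <- list(spo2 = spo2[i], siq = siq[i], signal_present = !is_drop[i])
      valid <- !is_drop[i] && siq[i] >= policy$siq_min && !is.na(spo2[i])
      on_tick <- t_now %% policy$decision_interval_s == 0
      if ((valid && spo2[i] < policy$rescue_spo2) || on_tick) {
        res <- propose(cstate, smp, t_now, policy, profile)
        cstate <- res$state
        reason[i] <- res$reason
        applied <- res$proposal # dedicated nurse follows every proposal
        if (res$reason == "RESCUE") fio2_proposed[i] <- res$proposal
      }
    } else {
      # usual care emits no controller proposals (fio2_proposed stays NA)
      if (!is_drop[i] && !is.na(spo2[i]) &&
          spo2[i] < policy$alarm_spo2 &&
          t_now - uc_last_alarm_t >= policy$alarm_response_s) {
        uc_fio2 <- min(1, uc_fio2 + policy$raise_step)
        uc_last_alarm_t <- t_now
        reason[i] <- "UC_ALARM"
      } else if (t_now > 0 && t_now %% (policy$check_interval_min * 60) == 0) {
        if (!is_drop[i] && !is.na(spo2[i]) && spo2[i] >= policy$lower_spo2) {
          uc_fio2 <- max(0.21, uc_fio2 - policy$lower_step)
        }
        reason[i] <- "UC_CHECK"
      }
      applied <- uc_fio2
    }
  }

  samples <- tibble::tibble(
    t_s = tvec, spo2 = spo2, hr = ifelse(is_drop, NA_real_, hr),
    pi = ifelse(is_drop, NA_real_, pi_), siq = siq,
    signal_present = !is_drop,
    fio2_set = round(fio2_set, 3),
    fio2_proposed = round(fio2_proposed, 3),
    decision_reason = reason
  )
  events <- dplyr::bind_rows(
    if (length(suction_onsets)) {
      tibble::tibble(kind = "SUCTION", start = suction_onsets,
                     end = suction_onsets + plan$suction_duration_s,
                     magnitude = NA_real_)
    },
    if (nrow(desat) > 0) {
      tibble::tibble(kind = "DESATURATION", start = desat$start,
                     end = desat$end, magnitude = desat$magnitude)
    },
    if (nrow(sensor_dropouts) > 0) {
      tibble::tibble(kind = "DROPOUT", start = sensor_dropouts$start,
                     end = sensor_dropouts$end, magnitude = NA_real_)
    },
    if (nrow(sensor_lowsiq) > 0) {
      tibble::tibble(kind = "LOW_SIQ", start = sensor_lowsiq$start,
                     end = sensor_lowsiq$end, magnitude = NA_real_)
    }
  )
  if (is.null(events)) {
    events <- tibble::tibble(kind = character(), start = numeric(),
                             end = numeric(), magnitude = numeric())
  }
  structure(
    list(
      samples = samples,
      truth = tibble::tibble(t_s = tvec, sao2 = sao2_true, pao2 = pao2_true,
                             fio2_effective = fio2_eff),
      events = events,
      meta = list(
        patient = patient, policy = policy, plan = plan, seed = seed,
        profile = if (is_controller) attr(profile, "name") else "usual_care",
        init_fio2 = init_fio2
      )
    ),
    class = "oxy_episode"
  )
}

#' @export
print.oxy_episode <- function(x, ...) {
  cat("<oxy_episode>\n")
  cat(sprintf("  %d samples at 1 Hz (%.1f h), policy: %s, seed %s\n",
              nrow(x$samples), nrow(x$samples) / 3600,
              x$meta$profile, format(x$meta$seed)))
  s <- summarize_episode(x)
  cat(sprintf("  normoxemia %.1f%% | hypoxemia %.1f%% | hyperoxemia %.1f%% of recorded time\n",
              s$pct_normoxemia, s$pct_hypoxemia, s$pct_hyperoxemia))
  invisible(x)
}

#' Range summary of an episode with its suction windows masked
#'
#' Convenience wrapper: builds the 15-minute suction exclusion mask from the
#' episode's event table and computes [time_in_ranges()].
#'
#' @param episode An `oxy_episode`.
#' @param mask_suction Exclude suction windows (default TRUE)?
#' @return A one-row `oxy_range_summary` tibble.
#' @export
summarize_episode <- function(episode, mask_suction = TRUE) {
  onsets <- episode$events$start[episode$events$kind == "SUCTION"]
  mask <- if (mask_suction && length(onsets)) {
    suction_mask(onsets, episode$meta$plan$suction_mask_min)
  } else {
    exclusion_mask()
  }
  time_in_ranges(episode$samples, mask)
}

#' Draw a virtual cohort for the crossover trial
#'
#' Two severity strata of equal size: severe (shunt fraction uniform on
#' 0.20-0.30) and moderate (uniform on 0.05-0.15). Each patient is randomly
#' allocated an order for the two profiles (the seeded RNG standing in for
#' the sealed envelope) and a private episode seed.
#'
#' @param n_per_stratum Patients per stratum.
#' @param seed Cohort seed.
#' @return A tibble: `patient`, `stratum`, `shunt`, `first_profile`,
#'   `episode_seed`.
#' @export
draw_cohort <- function(n_per_stratum = 10, seed = 1) {
  set.seed(seed)
  n <- n_per_stratum
  tibble::tibble(
    patient = seq_len(2 * n),
    stratum = rep(c("severe", "moderate"), each = n),
    shunt = c(runif(n, 0.20, 0.30), runif(n, 0.05, 0.15)),
    first_profile = sample(c("SH", "MH"), 2 * n, replace = TRUE),
    episode_seed = sample.int(2^31 - 1, 2 * n)
  )
}

#' Run the two-profile crossover trial on a virtual cohort
#'
#' Draws a cohort of virtual patients in two severity strata — severe
#' (shunt fraction uniform on 0.20-0.30, baseline FiO2 0.40) and moderate
#' (uniform on 0.05-0.15, baseline FiO2 0.30) — and runs each patient through
#' two closed-loop periods, one per step-table profile, in randomized order
#' with independent disturbance realizations. Suction windows are masked
#' (15 min per episode) before summarizing, mirroring the clinical protocol.
#'
#' @param plan [trial_plan()].
#' @param seed Cohort seed; every patient/period seed derives from it, so the
#'   whole trial is reproducible from this one integer.
#' @param config [controller_config()] used for both arms (the profile is
#'   swapped per period).
#' @param keep_traces Keep the full episode objects (memory-heavy)?
#' @return An `oxy_crossover`: list with `results` (one row per patient x
#'   period: patient id, stratum, shunt, order, period, profile, matched
#'   profile flag, range-summary columns), `cohort` (patient parameters) and
#'   `meta`. Use [tidy()] / [glance()] on it.
#' @export
run_crossover <- function(plan = trial_plan(), seed = 1,
                          config = controller_config(),
                          keep_traces = FALSE) {
  cohort <- draw_cohort(plan$n_per_stratum, seed)
  matched <- c(severe = "SH", moderate = "MH")

  rows <- list()
  traces <- list()
  for (i in seq_len(nrow(cohort))) {
    pt <- patient_params(shunt_fraction = cohort$shunt[i])
    order_profiles <- if (cohort$first_profile[i] == "SH") c("SH", "MH") else c("MH", "SH")
    for (period in 1:2) {
      prof_name <- order_profiles[period]
      ep_seed <- (cohort$episode_seed[i] + period) %% (2^31 - 1)
      ep <- run_episode(
        pt, policy = config, plan = plan, seed = ep_seed,
        profile = profile(prof_name)
      )
      summ <- summarize_episode(ep)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          patient = cohort$patient[i], stratum = cohort$stratum[i],
          shunt = cohort$shunt[i], period = period, profile = prof_name,
          matched = prof_name == matched[[cohort$stratum[i]]],
          episode_seed = ep_seed
        ),
        summ
      )
      if (keep_traces) traces[[sprintf("p%02d_%s", i, prof_name)]] <- ep
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(rows),
      cohort = cohort,
      traces = if (keep_traces) traces else NULL,
      meta = list(plan = plan, seed = seed, config = config)
    ),
    class = "oxy_crossover"
  )
}

#' @export
print.oxy_crossover <- function(x, ...) {
  cat("<oxy_crossover>\n")
  cat(sprintf("  %d patients x 2 periods, seed %s\n",
              nrow(x$cohort), format(x$meta$seed)))
  g <- glance(x)
  cat(sprintf("  mean normoxemia (matched profile): %.1f%% of recorded time\n",
              g$mean_normoxemia_matched))
  invisible(x)
}

#' @rdname tidy.oxy_crossover
#' @method glance oxy_crossover
#' @export
glance.oxy_crossover <- function(x, ...) {
  res <- x$results
  m <- res[res$matched, ]
  tibble::tibble(
    n_patients = nrow(x$cohort),
    n_episodes = nrow(res),
    mean_normoxemia_matched = mean(m$pct_normoxemia),
    mean_hypoxemia_matched = mean(m$pct_hypoxemia),
    mean_hyperoxemia_matched = mean(m$pct_hyperoxemia),
    mean_normoxemia_all = mean(res$pct_normoxemia),
    seed = x$meta$seed
  )
}

#' Tidy the crossover results
#'
#' `tidy()` returns one row per patient x period with the range-summary
#' percentages; `glance()` returns the cohort-level one-row summary, with
#' `mean_normoxemia_matched` the headline time-in-target when each stratum
#' runs its severity-matched profile.
#'
#' @param x An `oxy_crossover` from [run_crossover()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy oxy_crossover
#' @export
tidy.oxy_crossover <- function(x, ...) {
  x$results
}

#' Paired profile comparison within a stratum
#'
#' Wilcoxon signed-rank comparison of the per-patient normoxemia percentages
#' between the two profiles, within one severity stratum — the crossover
#' trial's primary within-group contrast.
#'
#' @param x An `oxy_crossover`.
#' @param stratum `"severe"` or `"moderate"`.
#' @param outcome Summary column to compare.
#' @return The one-row tibble from [compare_groups()] (SH minus MH effect).
#' @export
compare_profiles <- function(x, stratum = c("severe", "moderate"),
                             outcome = "pct_normoxemia") {
  stratum <- match.arg(stratum)
  res <- x$results[x$results$stratum == stratum, ]
  wide <- tidyr::pivot_wider(res[, c("patient", "profile", outcome)],
                             names_from = "profile",
                             values_from = dplyr::all_of(outcome))
  compare_groups(wide$SH, wide$MH, paired = TRUE)
}
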