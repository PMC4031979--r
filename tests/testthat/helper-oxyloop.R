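# Shared fixture builders. Everything is generated in code; no stored data.

# one oximeter sample row
mk_sample <- function(spo2, siq = 0.9, signal_present = TRUE, t_s = 0) {
  tibble::tibble(
    t_s = t_s, spo2 = as.integer(spo2), hr = 80, pi = 2,
    siq = siq, signal_present = signal_present
  )
}

# a minimal 1-Hz episode log from an SpO2 vector
mk_log <- function(spo2, t_s = seq_along(spo2) - 1, siq = 0.9,
                   signal_present = TRUE) {
  n <- length(spo2)
  tibble::tibble(
    t_s = t_s, spo2 = as.integer(round(spo2)), hr = 80, pi = 2,
    siq = rep_len(siq, n), signal_present = rep_len(signal_present, n)
  )
}

# drive the controller open-loop over a synthetic 1-Hz SpO2/SIQ stream:
# rescue is evaluated every second, table decisions on the decision tick.
# Returns one row per second with the applied FiO2 and the decision reason.
run_controller_trace <- function(spo2, siq = rep(0.9, length(spo2)),
                                 config = controller_config(),
                                 profile = oxyloop::profile(config$profile_id),
                                 init_fio2 = 0.40) {
  n <- length(spo2)
  st <- controller_state_init(init_fio2, t = 0, config = config)
  fio2 <- numeric(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    t <- i - 1
    st <- update_effective_fio2(st, 1, config)
    smp <- list(spo2 = spo2[i], siq = siq[i],
                signal_present = !is.na(spo2[i]))
    valid <- !is.na(spo2[i]) && siq[i] >= config$siq_min
    if ((valid && spo2[i] < config$rescue_spo2) ||
        t %% config$decision_interval_s == 0) {
      res <- propose(st, smp, t, config, profile)
      st <- res$state
      reason[i] <- res$reason
    }
    fio2[i] <- st$fio2_current
  }
  tibble::tibble(t_s = seq_len(n) - 1, fio2 = fio2, reason = reason)
}

# quiet plan for fast closed-loop tests: no disturbances, no sensor events
quiet_plan <- function(period_h = 0.5, noise_sd = 0) {
  trial_plan(
    period_h = period_h, suction_per_period = 0, desat_rate_per_h = 0,
    sensor = sensor_params(noise_sd = noise_sd, dropout_rate = 0,
                           low_siq_rate = 0)
  )
}
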