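# The SpO2-targeted FiO2 controller. Every 30 s it compares the measured SpO2
# with the 94% setpoint (midpoint of the 92-96% target band), looks the signed
# deviation up in a severity-matched step table, and proposes an FiO2 change,
# subject to: an immediate 100% FiO2 rescue when SpO2 < 85%, a hold on the
# last FiO2 when the signal quality index (SIQ) drops below 0.30, and a 30-s
# lockout between consecutive changes. The table step is the proportional term
# of a PI correction that is dampened while the previous change has not yet
# reached the estimated effective (alveolar) FiO2.

#' Controller configuration
#'
#' All printed controller constants with their clinical defaults: target band
#' 92-96% SpO2 (setpoint = the 94% midpoint), rescue to 100% FiO2 strictly
#' below SpO2 85%, 30-s lockout and decision interval, SIQ reliability cutoff
#' 0.30 (strictly below = unreliable), and FiO2 actuation limits 0.21-1.00.
#'
#' @param spo2_low,spo2_high Target band edges, % SpO2.
#' @param rescue_spo2 Severe-hypoxemia threshold, %; a valid sample strictly
#'   below it triggers the rescue.
#' @param rescue_fio2 FiO2 applied on rescue (fraction).
#' @param lockout_s Minimum interval between consecutive non-rescue FiO2
#'   changes, seconds.
#' @param decision_interval_s Controller decision tick, seconds.
#' @param siq_min SIQ below which (strictly) a sample is unreliable.
#' @param fio2_min,fio2_max Actuation limits, fraction.
#' @param profile_id `"SH"` (severely hypoxemic) or `"MH"` (moderately
#'   hypoxemic) default step table.
#' @param ki Integral gain, FiO2 fraction per %-error per decision tick.
#' @param kd Derivative gain, FiO2 fraction per (%/tick); 0 by default since
#'   the 30-s tick and the oximeter averaging already low-pass the signal.
#' @param integrator_cap Anti-windup clamp on the accumulated error, %-ticks.
#' @param tau_effective_s Time constant of the effective-FiO2 estimator used
#'   to dampen successive corrections, seconds.
#' @param dampening_scale FiO2 gap (fraction) at which the correction is fully
#'   suppressed; the correction is scaled by
#'   `max(0, 1 - |fio2_current - fio2_effective_est| / dampening_scale)`.
#'
#' @return An object of class `oxy_controller_config`.
#' @export
controller_config <- function(spo2_low = 92,
                              spo2_high = 96,
                              rescue_spo2 = 85,
                              rescue_fio2 = 1.0,
                              lockout_s = 30,
                              decision_interval_s = 30,
                              siq_min = 0.30,
                              fio2_min = 0.21,
                              fio2_max = 1.0,
                              profile_id = c("SH", "MH"),
                              ki = 0.002,
                              kd = 0,
                              integrator_cap = 25,
                              tau_effective_s = 60,
                              dampening_scale = 0.2) {
  profile_id <- match.arg(profile_id)
  setpoint <- (spo2_low + spo2_high) / 2
  if (!(spo2_low < setpoint && setpoint < spo2_high)) {
    abort("target band must satisfy spo2_low < setpoint < spo2_high.")
  }
  if (rescue_spo2 >= spo2_low) abort("`rescue_spo2` must lie below `spo2_low`.")
  if (fio2_min >= fio2_max) abort("`fio2_min` must be below `fio2_max`.")
  if (lockout_s < 0 || decision_interval_s <= 0) {
    abort("`lockout_s` must be >= 0 and `decision_interval_s` > 0.")
  }
  structure(
    list(
      spo2_low = spo2_low, spo2_high = spo2_high, setpoint = setpoint,
      rescue_spo2 = rescue_spo2, rescue_fio2 = rescue_fio2,
      lockout_s = lockout_s, decision_interval_s = decision_interval_s,
      siq_min = siq_min, fio2_min = fio2_min, fio2_max = fio2_max,
      profile_id = profile_id, ki = ki, kd = kd,
      integrator_cap = integrator_cap,
      tau_effective_s = tau_effective_s, dampening_scale = dampening_scale
    ),
    class = "oxy_controller_config"
  )
}

#' @export
print.oxy_controller_config <- function(x, ...) {
  cat("<oxy_controller_config>\n")
  cat(sprintf("  target band %d-%d%% SpO2 (setpoint %.0f%%), profile %s\n",
              x$spo2_low, x$spo2_high, x$setpoint, x$profile_id))
  cat(sprintf("  rescue: SpO2 < %d%% -> FiO2 %.0f%%; lockout %ds; SIQ cutoff %.2f\n",
              x$rescue_spo2, 100 * x$rescue_fio2, x$lockout_s, x$siq_min))
  invisible(x)
}

#' Deviation-to-step profiles
#'
#' A profile is the step table at the heart of the controller: it maps the
#' signed SpO2 deviation from the setpoint to a signed FiO2 step. Two named
#' instances embody the dual-slope design: `SH` (severely hypoxemic), with
#' larger up-steps because intrapulmonary shunt blunts the SpO2 response to
#' FiO2, and `MH` (moderately hypoxemic), with gentler steps. For every
#' deviation bin `|SH step| >= |MH step|`, the step is zero across the target
#' band, negative deviations map to positive steps, and step magnitude is
#' non-decreasing in deviation magnitude. Down-titration is more cautious
#' than up-titration.
#'
#' Bins are inclusive integer deviation ranges (SpO2 readings are integer
#' percent, so deviations from the integer setpoint band are integers).
#'
#' @param name `"SH"` or `"MH"`.
#' @param table Optional replacement tibble with columns `delta_min`,
#'   `delta_max` (inclusive, may be `-Inf`/`Inf`) and `step` (signed FiO2
#'   fraction); validated against the profile invariants.
#' @return An object of class `oxy_profile`: a tibble of bins with attribute
#'   `name`.
#' @examples
#' profile("SH")
#' table_step(profile("MH"), -4)
#' @export
profile <- function(name = c("SH", "MH"), table = NULL) {
  name <- match.arg(name)
  if (is.null(table)) {
    table <- default_profile_table(name)
  }
  validate_profile_table(table, name)
  structure(tibble::as_tibble(table), name = name,
            class = c("oxy_profile", class(tibble::tibble())))
}

default_profile_table <- function(name) {
  steps <- if (name == "SH") {
    c(0.30, 0.20, 0.10, 0.05, 0, -0.03, -0.05)
  } else {
    c(0.15, 0.10, 0.05, 0.02, 0, -0.02, -0.04)
  }
  tibble::tibble(
    delta_min = c(-Inf, -8, -6, -3, -2, 3, 4),
    delta_max = c(-9, -7, -4, -3, 2, 3, Inf),
    step = steps
  )
}

validate_profile_table <- function(table, name) {
  need <- c("delta_min", "delta_max", "step")
  if (!all(need %in% names(table))) {
    abort("a profile table needs columns delta_min, delta_max, step.")
  }
  tb <- table[order(table$delta_min), ]
  if (any(tb$delta_min > tb$delta_max)) abort("profile bins must have delta_min <= delta_max.")
  if (any(head(tb$delta_max, -1) + 1 != tail(tb$delta_min, -1))) {
    abort("profile bins must tile the integer deviations without gap or overlap.")
  }
  zero_bin <- tb$delta_min <= 0 & tb$delta_max >= 0
  if (!any(zero_bin) || tb$step[zero_bin] != 0) {
    abort("the bin containing deviation 0 must carry step 0.")
  }
  below <- tb$delta_max < 0
  above <- tb$delta_min > 0
  if (any(tb$step[below] <= 0)) abort("below-target bins must carry positive steps.")
  if (any(tb$step[above] >= 0)) abort("above-target bins must carry negative steps.")
  mags <- abs(tb$step)
  if (is.unsorted(rev(mags[below])) || is.unsorted(mags[above])) {
    abort("step magnitude must be non-decreasing in deviation magnitude.")
  }
  invisible(TRUE)
}

#' Look up the FiO2 step for an SpO2 deviation
#'
#' Total over all representable deviations: non-integer deviations are
#' rounded (SpO2 displays are integer percent), then matched to the inclusive
#' bin that contains them.
#'
#' @param profile An [profile()] object.
#' @param delta_spo2 Signed deviation, measured SpO2 minus setpoint, %.
#' @return Signed FiO2 step, fraction (vectorized).
#' @export
table_step <- function(profile, delta_spo2) {
  d <- round(delta_spo2)
  vapply(d, function(x) {
    profile$step[profile$delta_min <= x & x <= profile$delta_max][1]
  }, numeric(1))
}

#' Signed SpO2 error of a valid sample
#'
#' The controller's error signal: measured SpO2 minus the setpoint. Only
#' defined for valid samples; invalid samples (no signal, or SIQ strictly
#' below the cutoff) must be routed to the hold-last-FiO2 fall-back instead.
#'
#' @param sample A one-row oximeter sample (`spo2`, `siq`, `signal_present`).
#' @param config [controller_config()].
#' @return Signed deviation, %.
#' @export
spo2_error <- function(sample, config = controller_config()) {
  if (!sample_valid(sample, config)) {
    abort("`spo2_error()` requires a valid sample; route invalid samples to the fall-back.")
  }
  sample$spo2 - config$setpoint
}

sample_valid <- function(sample, config) {
  isTRUE(sample$signal_present) && !is.na(sample$spo2) &&
    sample$siq >= config$siq_min
}

#' Initialize controller memory
#'
#' @param fio2 Current (initial) FiO2 fraction.
#' @param t Current time, seconds.
#' @param config [controller_config()].
#' @return An object of class `oxy_controller_state`: current FiO2, the
#'   first-order estimate of the FiO2 that has reached the alveoli, the
#'   lockout clock, the PI integrator, the last error (for the optional
#'   derivative term) and the last valid FiO2 for the signal-quality
#'   fall-back.
#' @export
controller_state_init <- function(fio2 = 0.21, t = 0,
                                  config = controller_config()) {
  fio2 <- clamp(fio2, config$fio2_min, config$fio2_max)
  structure(
    list(
      fio2_current = fio2,
      fio2_effective_est = fio2,
      last_change_t = t - config$lockout_s, # free to act at t
      integrator = 0,
      last_error = NA_real_,
      last_valid_fio2 = fio2
    ),
    class = "oxy_controller_state"
  )
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Relax the effective-FiO2 estimate toward the current setting
#'
#' The controller dampens successive corrections while a previous change has
#' not yet reached the alveoli; its internal picture of "what has arrived" is
#' a first-order relaxation of the estimate toward the current setting with
#' time constant `tau_effective_s`.
#'
#' @param state [controller_state_init()] output.
#' @param dt Elapsed time, seconds.
#' @param config [controller_config()].
#' @return Updated `oxy_controller_state`.
#' @export
update_effective_fio2 <- function(state, dt, config = controller_config()) {
  if (dt <= 0) abort("`dt` must be positive.")
  state$fio2_effective_est <- state$fio2_effective_est +
    (state$fio2_current - state$fio2_effective_est) *
      (1 - exp(-dt / config$tau_effective_s))
  state
}

#' One controller decision
#'
#' Applies the decision rules in priority order:
#' 1. a valid sample strictly below the rescue threshold proposes
#'    `rescue_fio2` immediately, bypassing the lockout;
#' 2. an invalid sample (no signal, or SIQ strictly below the cutoff) holds
#'    the last valid FiO2;
#' 3. within the lockout window the current FiO2 is held;
#' 4. otherwise a dampened PI correction is applied: the proportional term is
#'    the profile table step for the SpO2 deviation, the integral term
#'    accumulates the deviation with anti-windup clamping, and the whole
#'    correction is scaled down by how far the effective-FiO2 estimate lags
#'    the current setting, then clamped to the actuation limits.
#'
#' Call on decision ticks (every `decision_interval_s`); the rescue rule may
#' additionally be evaluated on every sample since it reacts immediately.
#'
#' @param state `oxy_controller_state`.
#' @param sample One-row oximeter sample.
#' @param t Time of the decision, seconds.
#' @param config [controller_config()].
#' @param profile [profile()]; defaults to the profile named in `config`.
#' @return A list: `proposal` (FiO2 fraction), `state` (updated), `reason`
#'   (one of `"RESCUE"`, `"STEP"`, `"HOLD_LOCKOUT"`, `"HOLD_SIQ"`,
#'   `"HOLD_IN_TARGET"`).
#' @examples
#' cfg <- controller_config()
#' st <- controller_state_init(0.40, t = 0, config = cfg)
#' s <- tibble::tibble(t_s = 0, spo2 = 84L, hr = 80, pi = 2, siq = 0.9,
#'                     signal_present = TRUE)
#' propose(st, s, t = 0, config = cfg)$proposal # 1.0: rescue
#' @export
propose <- function(state, sample, t, config = controller_config(),
                    profile = oxyloop::profile(config$profile_id)) {
  if (t < state$last_change_t) abort("`t` must not precede the last change.")
  valid <- sample_valid(sample, config)

  # 1. rescue: immediate, bypasses lockout
  if (valid && sample$spo2 < config$rescue_spo2) {
    if (state$fio2_current != config$rescue_fio2) state$last_change_t <- t
    state$fio2_current <- config$rescue_fio2
    state$last_valid_fio2 <- config$rescue_fio2
    state$integrator <- 0 # anti-windup across the discontinuity
    return(list(proposal = config$rescue_fio2, state = state, reason = "RESCUE"))
  }

  # 2. unreliable signal: hold the last valid FiO2
  if (!valid) {
    return(list(proposal = state$last_valid_fio2, state = state,
                reason = "HOLD_SIQ"))
  }

  # 3. lockout
  if (t - state$last_change_t < config$lockout_s) {
    return(list(proposal = state$fio2_current, state = state,
                reason = "HOLD_LOCKOUT"))
  }

  # 4. dampened PI step
  err <- sample$spo2 - config$setpoint
  p_term <- table_step(profile, err)
  if (p_term == 0) {
    # in the target band: no action, bleed the integrator off
    state$integrator <- 0
    state$last_error <- err
    state$last_valid_fio2 <- state$fio2_current
    return(list(proposal = state$fio2_current, state = state,
                reason = "HOLD_IN_TARGET"))
  }
  integ <- clamp(state$integrator + err, -config$integrator_cap,
                 config$integrator_cap)
  d_term <- if (config$kd > 0 && !is.na(state$last_error)) {
    config$kd * (err - state$last_error)
  } else {
    0
  }
  # correction is positive when SpO2 is below target (err < 0)
  correction <- p_term - config$ki * integ + d_term
  damp <- max(0, 1 - abs(state$fio2_current - state$fio2_effective_est) /
                config$dampening_scale)
  proposal <- clamp(state$fio2_current + damp * correction,
                    config$fio2_min, config$fio2_max)
  if (abs(proposal - state$fio2_current) > 1e-12) {
    state$last_change_t <- t
    state$fio2_current <- proposal
    state$integrator <- integ
  }
  state$last_error <- err
  state$last_valid_fio2 <- proposal
  list(proposal = proposal, state = state, reason = "STEP")
}

#' Select the severity-matched profile from the PaO2/FiO2 ratio
#'
#' Uses the classic 200 mm Hg PaO2/FiO2 threshold: below it the severely
#' hypoxemic (`SH`) profile with its steeper steps, at or above it the
#' moderate (`MH`) profile. The boundary itself takes the gentler `MH`
#' profile, since either choice remains safe.
#'
#' @param pf_ratio PaO2/FiO2 ratio, mm Hg (positive).
#' @return An [profile()] object.
#' @examples
#' attr(select_profile(160), "name") # "SH"
#' attr(select_profile(239), "name") # "MH"
#' @export
select_profile <- function(pf_ratio) {
  if (!is.finite(pf_ratio) || pf_ratio <= 0) {
    abort("`pf_ratio` must be a positive PaO2/FiO2 ratio in mm Hg.")
  }
  if (pf_ratio < 200) profile("SH") else profile("MH")
}
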