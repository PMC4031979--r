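# Virtual-patient oxygen transport: a single-compartment lung with a fixed
# intrapulmonary shunt. Delivered FiO2 washes into the alveoli with a
# first-order lag, end-capillary blood equilibrates with alveolar gas, shunted
# venous blood is admixed by mass balance, and the arterial point reaches the
# oximeter probe after a transport delay.

#' Virtual patient parameters
#'
#' Bundles the gas-exchange parameters of a simulated ventilated patient.
#' The single tunable that separates severity strata is `shunt_fraction`:
#' the fraction of cardiac output perfusing unventilated lung. A larger shunt
#' blunts the SpO2 response to FiO2 changes, which is why severely hypoxemic
#' patients need larger FiO2 steps.
#'
#' @param shunt_fraction Intrapulmonary shunt as a fraction of cardiac output,
#'   in `[0, 0.95]`. Default 0.10 (moderate hypoxemia).
#' @param hb Hemoglobin, g/dl.
#' @param paco2 Arterial CO2 tension, mm Hg.
#' @param barometric_pressure Barometric pressure, mm Hg.
#' @param resp_quotient Respiratory quotient (dimensionless).
#' @param av_o2_diff Arteriovenous O2 content difference, ml O2/dl.
#' @param tau_alveolar Alveolar FiO2 wash-in time constant, seconds.
#' @param circ_delay Lung-to-probe circulatory transport delay, seconds.
#'
#' @return An object of class `oxy_patient` (a named list).
#' @examples
#' patient_params(shunt_fraction = 0.25) # severely hypoxemic stratum
#' @export
patient_params <- function(shunt_fraction = 0.10,
                           hb = 12,
                           paco2 = 40,
                           barometric_pressure = 760,
                           resp_quotient = 0.8,
                           av_o2_diff = 5,
                           tau_alveolar = 45,
                           circ_delay = 15) {
  if (shunt_fraction < 0 || shunt_fraction > 0.95) {
    abort("`shunt_fraction` must lie in [0, 0.95].")
  }
  if (hb <= 0) abort("`hb` must be positive.")
  if (tau_alveolar <= 0) abort("`tau_alveolar` must be positive.")
  if (circ_delay < 0) abort("`circ_delay` must be non-negative.")
  if (av_o2_diff <= 0) abort("`av_o2_diff` must be positive.")
  structure(
    list(
      shunt_fraction = shunt_fraction,
      hb = hb,
      paco2 = paco2,
      barometric_pressure = barometric_pressure,
      resp_quotient = resp_quotient,
      av_o2_diff = av_o2_diff,
      tau_alveolar = tau_alveolar,
      circ_delay = circ_delay
    ),
    class = "oxy_patient"
  )
}

#' @export
print.oxy_patient <- function(x, ...) {
  cat("<oxy_patient>\n")
  cat(sprintf("  shunt fraction : %.3f\n", x$shunt_fraction))
  cat(sprintf("  hemoglobin     : %.1f g/dl\n", x$hb))
  cat(sprintf("  PaCO2          : %.0f mm Hg\n", x$paco2))
  cat(sprintf("  wash-in tau    : %.0f s, circulatory delay %.0f s\n",
              x$tau_alveolar, x$circ_delay))
  invisible(x)
}

#' Oxyhemoglobin dissociation curve (Severinghaus closed form)
#'
#' Maps arterial oxygen tension to hemoglobin saturation with the closed-form
#' curve `S = 1 / (1 + 23400 / (P^3 + 150 P))`, accurate to about 0.3%
#' saturation over the clinical range and exactly invertible by root-finding.
#'
#' @param pao2 Oxygen tension, mm Hg (positive; vectorized).
#' @return Saturation as a fraction strictly in (0, 1).
#' @examples
#' severinghaus_sao2(26.8) # P50: about 0.50
#' severinghaus_sao2(60)   # about 0.91
#' @seealso [pao2_from_sao2()] for the inverse.
#' @export
severinghaus_sao2 <- function(pao2) {
  if (any(!is.finite(pao2)) || any(pao2 <= 0)) {
    abort("`pao2` must be positive and finite.")
  }
  g <- pao2^3 + 150 * pao2
  g / (g + 23400)
}

#' Invert the dissociation curve
#'
#' Finds the oxygen tension whose Severinghaus saturation equals `sao2`, by
#' bracketed root-finding (Brent) on `[1, 700]` mm Hg.
#'
#' @param sao2 Saturation fraction in (0, 1); vectorized.
#' @param tol Convergence tolerance on PaO2, mm Hg.
#' @return Oxygen tension, mm Hg.
#' @export
pao2_from_sao2 <- function(sao2, tol = 1e-9) {
  if (any(sao2 <= 0) || any(sao2 >= 1)) abort("`sao2` must lie strictly in (0, 1).")
  lo <- severinghaus_sao2(1)
  hi <- severinghaus_sao2(700)
  if (any(sao2 < lo) || any(sao2 > hi)) {
    abort("`sao2` outside the invertible range for PaO2 in [1, 700] mm Hg.")
  }
  vapply(sao2, function(s) {
    uniroot(function(p) severinghaus_sao2(p) - s,
            lower = 1, upper = 700, tol = tol)$root
  }, numeric(1))
}

#' Alveolar oxygen tension (alveolar gas equation)
#'
#' `PAO2 = FiO2 * (Pb - 47) - PaCO2 / R`, with 47 mm Hg water vapor pressure
#' at body temperature.
#'
#' @param fio2 Inspired oxygen fraction in (0, 1].
#' @param params [patient_params()] supplying `barometric_pressure`, `paco2`
#'   and `resp_quotient`.
#' @return Alveolar PO2, mm Hg.
#' @examples
#' alveolar_po2(0.21, patient_params()) # about 99.7 mm Hg
#' @export
alveolar_po2 <- function(fio2, params) {
  if (any(fio2 <= 0) || any(fio2 > 1)) abort("`fio2` must lie in (0, 1].")
  pao2 <- fio2 * (params$barometric_pressure - 47) -
    params$paco2 / params$resp_quotient
  if (any(pao2 <= 0)) {
    abort("Alveolar PO2 is non-positive: pathological parameter combination.")
  }
  pao2
}

#' Oxygen content of blood
#'
#' `CO2 = 1.34 * Hb * SO2 + 0.003 * PO2` (bound plus dissolved), ml O2/dl.
#'
#' @param pao2 Oxygen tension, mm Hg.
#' @param sao2 Saturation fraction.
#' @param hb Hemoglobin, g/dl.
#' @return Oxygen content, ml O2/dl.
#' @export
o2_content <- function(pao2, sao2, hb) {
  1.34 * hb * sao2 + 0.003 * pao2
}

#' Arterial content after shunt admixture
#'
#' Berggren mass balance: with shunt fraction `s` and arteriovenous content
#' difference `d`, arterial content is `CaO2 = Cc'O2 - s * d / (1 - s)`.
#' This is the mechanism by which high-shunt patients are less sensitive to
#' FiO2: end-capillary content gains are diluted by a fixed venous admixture.
#'
#' @param end_capillary_content End-capillary O2 content, ml O2/dl.
#' @param params [patient_params()].
#' @return Arterial O2 content, ml O2/dl.
#' @export
shunt_arterial_content <- function(end_capillary_content, params) {
  s <- params$shunt_fraction
  if (s >= 1) abort("`shunt_fraction` must be < 1.")
  ca <- end_capillary_content - s * params$av_o2_diff / (1 - s)
  if (any(ca <= 0)) {
    abort("Arterial O2 content is non-positive: shunt too large for the supplied end-capillary content.")
  }
  ca
}

# Solve o2_content(p, severinghaus_sao2(p), hb) = target for p.
# Newton with analytic derivative, warm-started from `start`, guarded by the
# [1, 700] bracket; falls back to uniroot if Newton leaves the bracket.
solve_pao2_for_content <- function(target, hb, start = 80) {
  f <- function(p) 1.34 * hb * severinghaus_sao2(p) + 0.003 * p - target
  flo <- f(1)
  fhi <- f(700)
  if (flo > 0 || fhi < 0) {
    abort(sprintf(
      "Arterial content %.3f ml/dl is outside the PaO2 bracket [1, 700] mm Hg.",
      target
    ))
  }
  p <- min(max(start, 1), 700)
  for (i in seq_len(50)) {
    g <- p^3 + 150 * p
    s <- g / (g + 23400)
    fp <- 1.34 * hb * s + 0.003 * p - target
    if (abs(fp) < 1e-10) return(p)
    ds <- 23400 * (3 * p^2 + 150) / (g + 23400)^2
    dfp <- 1.34 * hb * ds + 0.003
    p_new <- p - fp / dfp
    if (!is.finite(p_new) || p_new < 1 || p_new > 700) {
      return(uniroot(f, lower = 1, upper = 700, tol = 1e-9)$root)
    }
    if (abs(p_new - p) < 1e-9) return(p_new)
    p <- p_new
  }
  uniroot(f, lower = 1, upper = 700, tol = 1e-9)$root
}

#' Steady-state arterial oxygenation at a given FiO2
#'
#' Composes the gas-exchange chain at equilibrium (no wash-in or transport
#' lag): alveolar gas equation, end-capillary equilibration on the
#' dissociation curve, shunt admixture, and joint inversion of
#' content/saturation for arterial PaO2.
#'
#' @param fio2 Inspired oxygen fraction in `[0.21, 1]` (vectorized).
#' @param params [patient_params()].
#' @return A tibble with columns `fio2`, `pao2` (mm Hg), `sao2` (fraction),
#'   and `pf_ratio` (PaO2/FiO2, mm Hg).
#' @examples
#' steady_state_oxygenation(c(0.3, 0.6), patient_params(shunt_fraction = 0.25))
#' @export
steady_state_oxygenation <- function(fio2, params) {
  pao2 <- vapply(fio2, function(f) {
    pa_alv <- alveolar_po2(f, params)
    cc <- o2_content(pa_alv, severinghaus_sao2(pa_alv), params$hb)
    ca <- shunt_arterial_content(cc, params)
    solve_pao2_for_content(ca, params$hb, start = min(pa_alv, 100))
  }, numeric(1))
  tibble::tibble(
    fio2 = fio2,
    pao2 = pao2,
    sao2 = severinghaus_sao2(pao2),
    pf_ratio = pao2 / fio2
  )
}

#' Initialize the dynamic state of a virtual patient
#'
#' Starts the patient at the steady state for `fio2` and fills the circulatory
#' delay line with that equilibrium, so the first `circ_delay` seconds of a
#' simulation reflect the pre-existing condition.
#'
#' @param params [patient_params()].
#' @param fio2 Initial delivered (and equilibrated alveolar) FiO2 fraction.
#' @param t Initial time, seconds.
#' @return An object of class `oxy_patient_state`: a list with elements `t`,
#'   `fio2_effective`, `pao2`, `sao2` (the values seen at the probe) and an
#'   internal transport-delay buffer.
#' @export
patient_state_init <- function(params, fio2 = 0.21, t = 0) {
  ss <- steady_state_oxygenation(fio2, params)
  n_delay <- max(0L, as.integer(ceiling(params$circ_delay)))
  structure(
    list(
      t = t,
      fio2_effective = fio2,
      pao2 = ss$pao2,
      sao2 = ss$sao2,
      # delay line holds (pao2, sao2) pairs computed but not yet at the probe;
      # sized for 1-s steps, resized on the fly for other dt
      buffer_pao2 = rep(ss$pao2, n_delay),
      buffer_sao2 = rep(ss$sao2, n_delay)
    ),
    class = "oxy_patient_state"
  )
}

#' Advance the virtual patient by one time step
#'
#' The delivered `fio2_set` washes into the alveoli with first-order time
#' constant `tau_alveolar`; arterial PaO2/SaO2 are recomputed through the
#' steady gas-exchange chain at the current effective FiO2; the result
#' reaches the probe (`$pao2`, `$sao2`) after `circ_delay` seconds of pure
#' transport delay.
#'
#' @param state An `oxy_patient_state` from [patient_state_init()].
#' @param fio2_set Delivered FiO2 fraction in `[0.21, 1]`.
#' @param dt Time step, seconds (positive).
#' @param params [patient_params()]. Pass a modified copy (e.g. transiently
#'   increased `shunt_fraction`) to impose a disturbance.
#' @return The updated `oxy_patient_state`.
#' @export
step_patient <- function(state, fio2_set, dt, params) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (fio2_set < 0.21 - 1e-12 || fio2_set > 1 + 1e-12) {
    abort("`fio2_set` must lie in [0.21, 1].")
  }
  fe <- state$fio2_effective +
    (fio2_set - state$fio2_effective) * (1 - exp(-dt / params$tau_alveolar))
  pa_alv <- alveolar_po2(fe, params)
  cc <- o2_content(pa_alv, severinghaus_sao2(pa_alv), params$hb)
  ca <- shunt_arterial_content(cc, params)
  pao2_now <- solve_pao2_for_content(ca, params$hb,
                                     start = if (length(state$buffer_pao2)) {
                                       tail(state$buffer_pao2, 1)
                                     } else {
                                       state$pao2
                                     })
  sao2_now <- severinghaus_sao2(pao2_now)

  # FIFO transport delay: push the freshly computed arterial point, pop the
  # value that has finished its transit to the probe
  n_delay <- max(0L, as.integer(round(params$circ_delay / dt)))
  bp <- c(state$buffer_pao2, pao2_now)
  bs <- c(state$buffer_sao2, sao2_now)
  if (length(bp) > n_delay) {
    out_pao2 <- bp[1]
    out_sao2 <- bs[1]
    bp <- tail(bp, n_delay)
    bs <- tail(bs, n_delay)
  } else {
    out_pao2 <- state$pao2
    out_sao2 <- state$sao2
  }

  structure(
    list(
      t = state$t + dt,
      fio2_effective = fe,
      pao2 = out_pao2,
      sao2 = out_sao2,
      buffer_pao2 = bp,
      buffer_sao2 = bs
    ),
    class = "oxy_patient_state"
  )
}

#' Simulate the true saturation trajectory for an FiO2 schedule
#'
#' Runs the gas-exchange model at a fixed 1-second tick over a delivered-FiO2
#' vector, optionally with a time-varying shunt (disturbances), and returns
#' the full true-state trajectory. This is the vectorized work-horse the
#' scenario harness builds on; [step_patient()] is its one-step counterpart.
#'
#' @param fio2_set Numeric vector: delivered FiO2 fraction at each second.
#' @param params [patient_params()].
#' @param shunt Optional numeric vector, same length, of shunt fractions
#'   overriding `params$shunt_fraction` per tick.
#' @param init_fio2 FiO2 at which the patient starts in equilibrium.
#' @return A tibble with columns `t_s`, `fio2_set`, `fio2_effective`, `pao2`,
#'   `sao2` (arterial, at the lung) and `sao2_probe` (after the circulatory
#'   delay).
#' @export
simulate_true_saturation <- function(fio2_set, params, shunt = NULL,
                                     init_fio2 = fio2_set[1]) {
  n <- length(fio2_set)
  if (n == 0) abort("`fio2_set` must be non-empty.")
  if (is.null(shunt)) shunt <- rep(params$shunt_fraction, n)
  if (length(shunt) != n) abort("`shunt` must match `fio2_set` in length.")

  alpha <- 1 - exp(-1 / params$tau_alveolar)
  pb47 <- params$barometric_pressure - 47
  pc_term <- params$paco2 / params$resp_quotient
  hb <- params$hb
  dav <- params$av_o2_diff
  n_delay <- max(0L, as.integer(round(params$circ_delay)))

  ss0 <- steady_state_oxygenation(init_fio2, params)
  fe <- init_fio2
  p_prev <- ss0$pao2

  fio2_eff <- numeric(n)
  pao2 <- numeric(n)
  sao2 <- numeric(n)

  for (i in seq_len(n)) {
    fe <- fe + (fio2_set[i] - fe) * alpha
    pa_alv <- fe * pb47 - pc_term
    g <- pa_alv^3 + 150 * pa_alv
    scc <- g / (g + 23400)
    ca <- 1.34 * hb * scc + 0.003 * pa_alv - shunt[i] * dav / (1 - shunt[i])
    if (ca <= 0) {
      abort(sprintf("Arterial O2 content became non-positive at t = %d s.", i))
    }
    p <- solve_pao2_for_content(ca, hb, start = p_prev)
    p_prev <- p
    fio2_eff[i] <- fe
    pao2[i] <- p
    g <- p^3 + 150 * p
    sao2[i] <- g / (g + 23400)
  }

  probe <- if (n_delay == 0) sao2 else c(rep(ss0$sao2, n_delay), sao2)[seq_len(n)]
  tibble::tibble(
    t_s = seq_len(n) - 1L,
    fio2_set = fio2_set,
    fio2_effective = fio2_eff,
    pao2 = pao2,
    sao2 = sao2,
    sao2_probe = probe
  )
}
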