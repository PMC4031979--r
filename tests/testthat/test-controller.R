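# Controller decision rules: step tables, rescue, signal-quality fall-back,
# lockout, effective-FiO2 dampening, profile selection.

test_that("default config carries the printed clinical constants", {
  cfg <- controller_config()
  expect_equal(cfg$setpoint, 94)
  expect_equal(cfg$spo2_low, 92)
  expect_equal(cfg$spo2_high, 96)
  expect_equal(cfg$rescue_spo2, 85)
  expect_equal(cfg$lockout_s, 30)
  expect_equal(cfg$siq_min, 0.30)
  expect_error(controller_config(spo2_low = 96, spo2_high = 92), "band")
  expect_error(controller_config(rescue_spo2 = 93), "rescue_spo2")
})

test_that("spo2_error is the deviation from the setpoint and rejects invalid samples", {
  cfg <- controller_config()
  expect_equal(spo2_error(mk_sample(94), cfg), 0)
  expect_equal(spo2_error(mk_sample(90), cfg), -4)
  expect_equal(spo2_error(mk_sample(98), cfg), 4)
  expect_error(spo2_error(mk_sample(90, siq = 0.1), cfg), "valid")
  expect_error(spo2_error(mk_sample(90, signal_present = FALSE), cfg), "valid")
})

test_that("step tables obey sign, monotonicity, zero band, and SH/MH dominance", {
  sh <- profile("SH")
  mh <- profile("MH")
  expect_equal(table_step(sh, 0), 0)
  expect_equal(table_step(sh, -2), 0)
  expect_equal(table_step(sh, 2), 0)
  expect_equal(table_step(sh, -4), 0.10)
  expect_equal(table_step(mh, -4), 0.05)
  expect_equal(table_step(sh, 3), -0.03)
  expect_equal(table_step(mh, 4), -0.04)
  d <- -30:30
  for (p in list(sh, mh)) {
    st <- table_step(p, d)
    expect_true(all(st[d < -2] > 0))
    expect_true(all(st[d > 2] < 0))
    expect_true(all(st[abs(d) <= 2] == 0))
    # |step| non-decreasing with |deviation|
    below <- st[d < 0]
    expect_true(all(diff(abs(below)) <= 0))
    above <- st[d > 0]
    expect_true(all(diff(abs(above)) >= 0))
  }
  expect_true(all(abs(table_step(sh, d)) >= abs(table_step(mh, d))))
  expect_silent(check_profile_dominance(sh, mh))
  expect_error(check_profile_dominance(mh, sh), "dominance")
})

test_that("rescue proposes 100% FiO2 immediately, bypassing the lockout", {
  cfg <- controller_config()
  st <- controller_state_init(0.40, t = 0, cfg)
  st$last_change_t <- 95 # a change 5 s ago: inside the lockout
  res <- propose(st, mk_sample(84), t = 100, cfg)
  expect_equal(res$proposal, 1.0)
  expect_equal(res$reason, "RESCUE")
  # but 85 itself is not a rescue (strict less-than)
  st2 <- controller_state_init(0.40, t = 0, cfg)
  st2$last_change_t <- 95
  res2 <- propose(st2, mk_sample(85), t = 100, cfg)
  expect_equal(res2$reason, "HOLD_LOCKOUT")
})

test_that("an unreliable sample holds the last valid FiO2", {
  cfg <- controller_config()
  st <- controller_state_init(0.40, t = 0, cfg)
  res <- propose(st, mk_sample(90, siq = 0.20), t = 100, cfg)
  expect_equal(res$proposal, 0.40)
  expect_equal(res$reason, "HOLD_SIQ")
  # SpO2 below the rescue threshold but with bad SIQ must NOT rescue
  res2 <- propose(st, mk_sample(80, siq = 0.10), t = 100, cfg)
  expect_equal(res2$reason, "HOLD_SIQ")
  expect_equal(res2$proposal, 0.40)
  # no signal at all
  res3 <- propose(st, mk_sample(90, signal_present = FALSE), t = 100, cfg)
  expect_equal(res3$reason, "HOLD_SIQ")
})

test_that("the lockout blocks non-rescue changes and in-target samples hold", {
  cfg <- controller_config()
  st <- controller_state_init(0.40, t = 0, cfg)
  st$last_change_t <- 80
  res <- propose(st, mk_sample(90), t = 100, cfg) # 20 s since change
  expect_equal(res$reason, "HOLD_LOCKOUT")
  expect_equal(res$proposal, 0.40)
  res2 <- propose(st, mk_sample(94), t = 120, cfg) # lockout expired, in band
  expect_equal(res2$reason, "HOLD_IN_TARGET")
  expect_equal(res2$proposal, 0.40)
})

test_that("below-target valid samples step FiO2 up by the table entry", {
  cfg <- controller_config()
  st <- controller_state_init(0.40, t = -1000, cfg)
  st$fio2_effective_est <- 0.40 # fully settled: no dampening
  res <- propose(st, mk_sample(90), t = 0, cfg, profile("SH"))
  expect_equal(res$reason, "STEP")
  # proportional term 0.10 plus a one-tick integral contribution
  expect_gt(res$proposal, 0.40)
  expect_equal(res$proposal, 0.40 + 0.10 + 0.002 * 4, tolerance = 1e-9)
  expect_equal(res$state$last_change_t, 0)
  # proposals always inside the actuation limits
  st$fio2_current <- 0.98
  res2 <- propose(st, mk_sample(86), t = 0, cfg, profile("SH"))
  expect_lte(res2$proposal, 1.0)
})

test_that("dampening shrinks corrections while the estimate lags", {
  cfg <- controller_config()
  st <- controller_state_init(0.40, t = -1000, cfg)
  st$fio2_effective_est <- 0.25 # gap 0.15 -> damp factor 0.25
  res <- propose(st, mk_sample(90), t = 0, cfg, profile("SH"))
  full <- 0.10 + 0.002 * 4
  expect_equal(res$proposal - 0.40, 0.25 * full, tolerance = 1e-9)
  # gap beyond the scale suppresses action entirely
  st2 <- controller_state_init(0.40, t = -1000, cfg)
  st2$fio2_effective_est <- 0.90
  res2 <- propose(st2, mk_sample(90), t = 0, cfg, profile("SH"))
  expect_equal(res2$proposal, 0.40)
})

test_that("effective-FiO2 estimate relaxes first-order toward the setting", {
  cfg <- controller_config() # tau 60 s
  st <- controller_state_init(0.21, t = 0, cfg)
  st$fio2_current <- 1.0
  st1 <- update_effective_fio2(st, dt = 60, cfg)
  expect_equal(st1$fio2_effective_est, 0.21 + (1 - exp(-1)) * 0.79,
               tolerance = 1e-9)
  st2 <- update_effective_fio2(st, dt = 6000, cfg)
  expect_equal(st2$fio2_effective_est, 1.0, tolerance = 1e-6)
  # fixed point
  stf <- controller_state_init(0.5, t = 0, cfg)
  expect_equal(update_effective_fio2(stf, 30, cfg)$fio2_effective_est, 0.5)
})

test_that("profile selection uses the 200 mm Hg PaO2/FiO2 threshold", {
  expect_equal(attr(select_profile(160), "name"), "SH")
  expect_equal(attr(select_profile(239), "name"), "MH")
  expect_equal(attr(select_profile(199.9), "name"), "SH")
  expect_equal(attr(select_profile(200), "name"), "MH") # boundary: gentler profile
  expect_error(select_profile(0), "positive")
  expect_error(select_profile(-5), "positive")
})

test_that("FiO2 never changes while SIQ stays below the cutoff", {
  n <- 600
  tr <- run_controller_trace(rep(88L, n), siq = rep(0.25, n),
                             init_fio2 = 0.35)
  expect_true(all(tr$fio2 == 0.35))
  expect_true(all(stats::na.omit(tr$reason) == "HOLD_SIQ"))
})

test_that("consecutive non-rescue changes are at least the lockout apart", {
  # persistent below-target error, never below the rescue threshold
  tr <- run_controller_trace(rep(89L, 600), init_fio2 = 0.30)
  ch <- tr$t_s[c(FALSE, diff(tr$fio2) != 0)]
  expect_gt(length(ch), 2)
  expect_true(all(diff(ch) >= 30))
  expect_true(all(tr$fio2 >= 0.21 & tr$fio2 <= 1.0))
})

test_that("rescue dominates every other rule in a trace", {
  spo2 <- rep(93L, 300)
  spo2[150] <- 84L # single severe event off the decision tick
  tr <- run_controller_trace(spo2, init_fio2 = 0.30)
  expect_equal(tr$fio2[150], 1.0)
  expect_equal(tr$reason[150], "RESCUE")
  expect_true(all(tr$fio2[1:149] == 0.30))
})

test_that("custom profile tables are validated", {
  bad <- tibble::tibble(delta_min = c(-Inf, -2, 3),
                        delta_max = c(-3, 2, Inf),
                        step = c(-0.1, 0, -0.05)) # wrong sign below target
  expect_error(profile("SH", table = bad), "positive steps")
  gap <- tibble::tibble(delta_min = c(-Inf, 0), delta_max = c(-3, Inf),
                        step = c(0.1, 0))
  expect_error(profile("SH", table = gap), "tile")
})
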