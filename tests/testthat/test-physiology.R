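# Gas-exchange model: dissociation curve, alveolar gas equation, shunt mass
# balance, and the composed dynamic patient model.

test_that("severinghaus curve reproduces its closed-form landmarks", {
  # hand-evaluated: 26.8^3 + 150*26.8 = 23268.832; 1/(1 + 23400/23268.832)
  expect_equal(severinghaus_sao2(26.8), 0.4985947, tolerance = 1e-6)
  # 60^3 + 150*60 = 225000; 1/(1 + 23400/225000)
  expect_equal(severinghaus_sao2(60), 0.9057971, tolerance = 1e-6)
  # asymptote
  expect_gt(severinghaus_sao2(5000), 0.9999)
  expect_lt(severinghaus_sao2(5000), 1)
  # strictly increasing, strictly inside (0,1)
  p <- seq(1, 700, by = 1)
  s <- severinghaus_sao2(p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
  expect_error(severinghaus_sao2(0), "positive")
  expect_error(severinghaus_sao2(-10), "positive")
})

test_that("dissociation curve and its inversion round-trip to 1e-6 mm Hg", {
  p <- seq(20, 600, length.out = 80)
  back <- pao2_from_sao2(severinghaus_sao2(p))
  expect_lt(max(abs(back - p)), 1e-6)
  # P50 recovered from saturation one-half
  expect_equal(pao2_from_sao2(0.5), 26.8, tolerance = 0.1)
})

test_that("alveolar gas equation matches direct evaluation", {
  pp <- patient_params() # Pb 760, PaCO2 40, R 0.8
  expect_equal(alveolar_po2(0.21, pp), 0.21 * 713 - 50, tolerance = 1e-12)
  expect_equal(alveolar_po2(0.30, pp), 163.9, tolerance = 1e-9)
  # degenerate: pure O2, no CO2 -> Pb - 47
  pp0 <- patient_params(paco2 = 1e-12)
  expect_equal(alveolar_po2(1.0, pp0), 713, tolerance = 1e-6)
  # linear and increasing in fio2
  f <- seq(0.21, 1, by = 0.01)
  pa <- alveolar_po2(f, pp)
  expect_true(all(diff(pa) > 0))
  expect_equal(max(abs(diff(pa) - diff(pa)[1])), 0, tolerance = 1e-9)
  expect_error(alveolar_po2(0.05, patient_params(paco2 = 80)), "non-positive")
})

test_that("oxygen content is the bound-plus-dissolved sum", {
  expect_equal(o2_content(100, 1.0, 15), 20.4)
  expect_equal(o2_content(60, 0.9, 10), 12.24)
  expect_lt(o2_content(1e-9, 1e-9, 15), 1e-6)
})

test_that("shunt admixture follows the Berggren mass balance", {
  expect_equal(
    shunt_arterial_content(20, patient_params(shunt_fraction = 0)), 20)
  expect_equal(
    shunt_arterial_content(20, patient_params(shunt_fraction = 0.2)), 18.75)
  expect_equal(
    shunt_arterial_content(20, patient_params(shunt_fraction = 0.5)), 15.0)
  expect_error(
    shunt_arterial_content(1, patient_params(shunt_fraction = 0.9)),
    "non-positive")
})

test_that("shunt admixture equals brute-force venous mixing", {
  # oracle: mixed arterial content = (1-s) * end-capillary + s * venous,
  # with venous = arterial - av_o2_diff
  set.seed(101)
  for (i in 1:50) {
    s <- runif(1, 0, 0.6)
    dav <- runif(1, 2, 8)
    cc <- runif(1, 12, 22)
    pp <- patient_params(shunt_fraction = s, av_o2_diff = dav)
    ca <- shunt_arterial_content(cc, pp)
    cv <- ca - dav
    expect_equal((1 - s) * cc + s * cv, ca, tolerance = 1e-9)
    expect_true(s == 0 || ca < cc)
  }
})

test_that("steady-state saturation is non-decreasing in FiO2 for random patients", {
  set.seed(202)
  for (i in 1:20) {
    pp <- patient_params(
      shunt_fraction = runif(1, 0, 0.45),
      hb = runif(1, 8, 16),
      paco2 = runif(1, 30, 55),
      av_o2_diff = runif(1, 3, 6)
    )
    ss <- steady_state_oxygenation(seq(0.21, 1, by = 0.05), pp)
    expect_true(all(diff(ss$sao2) >= -1e-12))
    expect_true(all(ss$pao2 > 0))
  }
})

test_that("SpO2 sensitivity to FiO2 falls as shunt rises (same operating point)", {
  # quantified sensitivity ordering: pick for each shunt the FiO2 that puts
  # SaO2 at 0.96, then apply the same +0.05 FiO2 step
  sens_at <- function(shunt) {
    pp <- patient_params(shunt_fraction = shunt)
    f_op <- uniroot(
      function(f) steady_state_oxygenation(f, pp)$sao2 - 0.96,
      lower = 0.21, upper = 1
    )$root
    s0 <- steady_state_oxygenation(f_op, pp)$sao2
    s1 <- steady_state_oxygenation(f_op + 0.05, pp)$sao2
    s1 - s0
  }
  d <- vapply(c(0.10, 0.20, 0.30), sens_at, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("patient dynamics: fixed point, monotone step response, transport delay", {
  pp <- patient_params(shunt_fraction = 0.10)
  st <- patient_state_init(pp, fio2 = 0.30)
  s0 <- st$sao2

  # fixed point: constant FiO2 leaves the state unchanged
  st_fp <- st
  for (i in 1:30) st_fp <- step_patient(st_fp, 0.30, 1, pp)
  expect_equal(st_fp$sao2, s0, tolerance = 1e-9)
  expect_equal(st_fp$fio2_effective, 0.30, tolerance = 1e-9)

  # step 0.30 -> 1.0: probe value frozen during the transport delay, then rises
  st_up <- st
  for (i in 1:14) st_up <- step_patient(st_up, 1.0, 1, pp) # inside 15-s delay
  expect_equal(st_up$sao2, s0, tolerance = 1e-12)
  for (i in 1:300) st_up <- step_patient(st_up, 1.0, 1, pp) # t >> tau + delay
  expect_gt(st_up$sao2, s0)
  expect_equal(st_up$fio2_effective, 1.0, tolerance = 1e-3)
  expect_equal(st_up$sao2, steady_state_oxygenation(1.0, pp)$sao2,
               tolerance = 1e-3)
})

test_that("the same FiO2 step moves SaO2 less in a high-shunt patient", {
  dsat <- function(shunt) {
    pp <- patient_params(shunt_fraction = shunt)
    # operate both patients at the same SaO2 by choosing FiO2 accordingly
    f_op <- uniroot(
      function(f) steady_state_oxygenation(f, pp)$sao2 - 0.96,
      lower = 0.21, upper = 1
    )$root
    ss <- steady_state_oxygenation(c(f_op, f_op + 0.1), pp)
    diff(ss$sao2)
  }
  expect_gt(dsat(0.10), dsat(0.30))
})

test_that("parameter invariants are enforced", {
  expect_error(patient_params(shunt_fraction = 0.99), "shunt_fraction")
  expect_error(patient_params(hb = 0), "hb")
  expect_error(patient_params(tau_alveolar = 0), "tau_alveolar")
  expect_error(patient_params(av_o2_diff = -1), "av_o2_diff")
  expect_error(pao2_from_sao2(1.2), "strictly")
})
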