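# Outcome metrics: time-weighted range percentages, exclusion masks,
# aberrant filtering, window extraction, adherence, group comparisons.

test_that("uniformly sampled logs give count-based range percentages", {
  log <- mk_log(c(90, 93, 97, 94, 95, 91, 96, 92, 98, 96))
  s <- time_in_ranges(log)
  expect_equal(s$pct_hypoxemia, 20)
  expect_equal(s$pct_normoxemia, 60)
  expect_equal(s$pct_hyperoxemia, 20)
  expect_equal(s$pct_no_signal, 0)
  expect_equal(s$pct_low_siq, 0)

  all94 <- time_in_ranges(mk_log(rep(94, 20)))
  expect_equal(all94$pct_normoxemia, 100)
})

test_that("irregular sampling is weighted by holding time, not sample count", {
  log <- mk_log(c(91, 94), t_s = c(0, 60))
  s <- time_in_ranges(log)
  expect_equal(s$pct_hypoxemia, 50)
  expect_equal(s$pct_normoxemia, 50)
  expect_equal(s$total_time, 120)
})

test_that("range summaries partition recorded time exactly", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    log <- mk_log(
      sample(80:100, n, replace = TRUE),
      t_s = cumsum(sample(1:120, n, replace = TRUE)),
      siq = sample(c(0.1, 0.9), n, replace = TRUE, prob = c(0.1, 0.9)),
      signal_present = sample(c(TRUE, FALSE), n, replace = TRUE,
                              prob = c(0.95, 0.05))
    )
    mask <- exclusion_mask(min(log$t_s) + 10, min(log$t_s) + 200, "CUSTOM")
    s <- time_in_ranges(log, mask)
    expect_equal(
      s$pct_hypoxemia + s$pct_normoxemia + s$pct_hyperoxemia +
        s$pct_no_signal + s$pct_low_siq,
      100, tolerance = 1e-9
    )
    expect_equal(s$recorded_time + s$excluded_time, s$total_time,
                 tolerance = 1e-9)
  }
})

test_that("summaries are invariant to uniform resampling of a piecewise-constant trace", {
  pattern <- rep(c(90, 94, 98, 95), each = 25) # 100 s, piecewise constant
  a <- time_in_ranges(mk_log(pattern))
  fine <- rep(pattern, each = 2) # 0.5-s sampling of the same trace
  b <- time_in_ranges(mk_log(fine, t_s = (seq_along(fine) - 1) / 2))
  expect_equal(a$pct_hypoxemia, b$pct_hypoxemia, tolerance = 1e-9)
  expect_equal(a$pct_normoxemia, b$pct_normoxemia, tolerance = 1e-9)
  expect_equal(a$pct_hyperoxemia, b$pct_hyperoxemia, tolerance = 1e-9)
})

test_that("masked samples are excluded from numerator and denominator", {
  log <- mk_log(c(rep(94, 50), rep(85, 50)))
  mask <- exclusion_mask(50, 100, "SUCTION")
  s <- time_in_ranges(log, mask)
  expect_equal(s$pct_normoxemia, 100)
  expect_equal(s$excluded_time, 50)
  # fully masked episode: empty summary, no division by zero
  s2 <- time_in_ranges(log, exclusion_mask(0, 1000, "CUSTOM"))
  expect_true(is.na(s2$pct_normoxemia))
  expect_equal(s2$recorded_time, 0)
})

test_that("suction masks span 15 minutes and merge overlaps", {
  expect_equal(nrow(suction_mask(numeric())), 0)
  m <- suction_mask(3600)
  expect_equal(m$start, 3600)
  expect_equal(m$end, 4500)
  # two events 5 minutes apart merge into one 20-minute window
  m2 <- suction_mask(c(0, 300))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$end - m2$start, 1200)
})

test_that("aberrant filtering removes values strictly below the floor", {
  log <- mk_log(70:100)
  out <- filter_aberrant(log)
  expect_equal(min(out$samples$spo2), 80)
  expect_equal(nrow(out$samples), 21)
  expect_true(all(out$mask$reason == "ABERRANT"))

  ident <- filter_aberrant(mk_log(c(80, 90, 95)))
  expect_equal(nrow(ident$samples), 3)
  expect_equal(nrow(ident$mask), 0)

  three <- filter_aberrant(mk_log(c(79, 80, 81)))
  expect_equal(nrow(three$samples), 2)
})

test_that("filter-then-summarize equals summarize-with-aberrant-mask", {
  set.seed(17)
  log <- mk_log(sample(70:100, 200, replace = TRUE))
  out <- filter_aberrant(log)
  a <- time_in_ranges(out$samples, out$mask)
  b <- time_in_ranges(log, out$mask)
  expect_equal(a$pct_hypoxemia, b$pct_hypoxemia, tolerance = 1e-9)
  expect_equal(a$pct_normoxemia, b$pct_normoxemia, tolerance = 1e-9)
  expect_equal(a$pct_hyperoxemia, b$pct_hyperoxemia, tolerance = 1e-9)
})

test_that("audit windows are extracted at the protocol anchors", {
  # 8-day log sampled every 2 minutes
  tt8 <- seq(0, 8 * 24 * 3600, by = 120)
  log8 <- mk_log(rep(95, length(tt8)), t_s = tt8)
  w <- extract_windows(log8)
  expect_length(w$windows, 3)
  expect_equal(nrow(w$omitted), 0)
  expect_true(all(vapply(w$windows, nrow, 1L) <= 181))

  # 2-day log: the day-7 window is omitted with a warning record
  tt2 <- seq(0, 2 * 24 * 3600, by = 120)
  log2 <- mk_log(rep(95, length(tt2)), t_s = tt2)
  expect_warning(w2 <- extract_windows(log2), "omitted")
  expect_length(w2$windows, 2)
  expect_equal(w2$omitted$anchor, "day7")
})

test_that("adherence is the time-weighted agreement of set and proposed FiO2", {
  log <- mk_log(rep(94, 100))
  log$fio2_set <- rep(0.40, 100)
  log$fio2_proposed <- rep(0.40, 100)
  expect_equal(adherence(log), 1.0)
  log$fio2_set[51:52] <- 0.50 # 2 of 100 uniform seconds diverge
  expect_equal(adherence(log), 0.98)
  # missing column -> unavailable
  expect_warning(a <- adherence(mk_log(rep(94, 10))), "unavailable")
  expect_true(is.na(a))
  # no overlapping non-missing rows -> unavailable
  log$fio2_proposed <- NA_real_
  expect_warning(a2 <- adherence(log), "unavailable")
  expect_true(is.na(a2))
})

test_that("group comparisons route to the standard tests", {
  x <- c(95, 96, 94, 97, 95.5, 96.2, 93.8, 95.1, 96.7, 94.9)
  ident <- compare_groups(x, x, paired = TRUE)
  expect_equal(ident$p_value, 1)
  expect_equal(ident$effect, 0)

  # constant +1 shift: all paired differences share one sign ->
  # signed-rank statistic for the negative-shift side is 0
  shift <- compare_groups(x, x + 1, paired = TRUE)
  expect_equal(unname(shift$statistic), 0)
  expect_equal(shift$effect, -1)
  expect_identical(shift$test, "wilcoxon signed-rank")

  # cross-check against stats:: directly
  set.seed(5)
  a <- rnorm(12, 95, 2); b <- rnorm(12, 93, 2)
  ours <- compare_groups(a, b, paired = FALSE, test = "t")
  ref <- t.test(a, b)
  expect_equal(ours$p_value, ref$p.value)
  expect_equal(ours$statistic, unname(ref$statistic))

  expect_warning(nc <- compare_groups(1, 2, paired = FALSE), "fewer than 2")
  expect_true(is.na(nc$p_value))
  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("the category-per-row table mirrors the reporting layout", {
  s1 <- time_in_ranges(mk_log(rep(94, 10)))
  s2 <- time_in_ranges(mk_log(rep(98, 10)))
  tab <- format_range_table(dplyr::bind_rows(s1, s2), labels = c("SH", "MH"))
  expect_equal(nrow(tab), 5)
  expect_equal(names(tab), c("category", "SH", "MH"))
  expect_equal(tab$SH[tab$category == "Time with normoxemia (SpO2 92% to 96%) (%)"], 100)
  expect_equal(tab$MH[tab$category == "Time with hyperoxemia (SpO2 >= 97%) (%)"], 100)
})
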