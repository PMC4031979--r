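# Outcome metrics: time-weighted percentages of recorded time spent in the
# hypoxemia (SpO2 <= 91%), normoxemia (92-96%) and hyperoxemia (>= 97%)
# bands, with no-signal and low-SIQ time reported as separate categories,
# after excluding suction windows and (in audit mode) aberrant values.

#' Build an exclusion mask
#'
#' @param start,end Interval bounds, seconds (half-open `[start, end)`).
#' @param reason One of `"SUCTION"`, `"ABERRANT"`, `"CUSTOM"` per interval.
#' @return A tibble of normalized (sorted, merged-per-reason kept distinct)
#'   intervals with class `oxy_mask`.
#' @export
exclusion_mask <- function(start = numeric(), end = numeric(),
                           reason = character()) {
  if (length(reason) == 1 && length(start) > 1) {
    reason <- rep(reason, length(start))
  }
  stopifnot(length(start) == length(end), length(reason) == length(start))
  if (any(end < start)) abort("mask intervals need start <= end.")
  bad <- !reason %in% c("SUCTION", "ABERRANT", "CUSTOM")
  if (any(bad)) abort("mask reasons must be SUCTION, ABERRANT or CUSTOM.")
  m <- tibble::tibble(start = as.numeric(start), end = as.numeric(end),
                      reason = reason)
  m <- m[order(m$start), ]
  structure(m, class = c("oxy_mask", class(tibble::tibble())))
}

# merge overlapping [start,end) intervals; returns matrix-like tibble
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(tibble::tibble(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Exclusion mask for endotracheal suctioning episodes
#'
#' Each suctioning episode (with its preoxygenation to 100% FiO2) perturbs
#' SpO2 and FiO2 so strongly that profile comparisons exclude a fixed window
#' starting at the preoxygenation onset; the clinical protocol removes 15
#' minutes per episode. Overlapping windows are merged.
#'
#' @param events Numeric vector of preoxygenation onset times, seconds.
#' @param window_min Window width per episode, minutes (default 15).
#' @return An `oxy_mask` with reason `"SUCTION"`.
#' @examples
#' suction_mask(3600) # one window [3600, 4500)
#' @export
suction_mask <- function(events, window_min = 15) {
  if (length(events) == 0) {
    return(exclusion_mask())
  }
  merged <- merge_intervals(events, events + window_min * 60)
  exclusion_mask(merged$start, merged$end, "SUCTION")
}

#' Remove aberrant SpO2 values from an audit log
#'
#' Historical bedside recordings contain very low SpO2 values that are almost
#' certainly artifacts; values strictly below `floor` (default 80%) are
#' treated as erroneous and removed. Intended for usual-care audit logs only,
#' never for controller-trace evaluation.
#'
#' @param log Episode samples (tibble with `t_s` and `spo2`).
#' @param floor Aberrant-value floor, % SpO2, in (0, 100).
#' @return A list: `samples` (the retained rows) and `mask` (an `oxy_mask`
#'   with reason `"ABERRANT"` covering the removed samples' holding
#'   intervals).
#' @examples
#' log <- tibble::tibble(t_s = 0:30, spo2 = 70:100)
#' min(filter_aberrant(log)$samples$spo2) # 80
#' @export
filter_aberrant <- function(log, floor = 80) {
  if (floor <= 0 || floor >= 100) abort("`floor` must lie in (0, 100).")
  bad <- !is.na(log$spo2) & log$spo2 < floor
  if (!any(bad)) {
    return(list(samples = log, mask = exclusion_mask()))
  }
  ends <- sample_interval_ends(log$t_s)
  merged <- merge_intervals(log$t_s[bad], ends[bad])
  list(
    samples = log[!bad, ],
    mask = exclusion_mask(merged$start, merged$end, "ABERRANT")
  )
}

# each sample holds [t_i, t_{i+1}); the last holds one median gap
sample_interval_ends <- function(t) {
  n <- length(t)
  if (n == 1) return(t + 1)
  gaps <- diff(t)
  c(t[-1], t[n] + median(gaps))
}

#' Time-weighted SpO2 range summary
#'
#' Computes the percentage of recorded time spent in each SpO2 category:
#' hypoxemia (rounded SpO2 <= 91), normoxemia (92-96), hyperoxemia (>= 97),
#' plus no-signal and low-SIQ (SIQ <= 0.3) time, which are reported as their
#' own categories and excluded from the oxygenation bands. Each sample holds
#' from its timestamp to the next sample's (the final sample holds one median
#' inter-sample gap), so irregularly sampled audit logs are weighted by time,
#' not by sample count. Masked intervals are excluded from numerator and
#' denominator alike.
#'
#' @param log Episode samples: tibble with `t_s`, `spo2` and optionally
#'   `siq`, `signal_present`.
#' @param mask An `oxy_mask` from [exclusion_mask()], [suction_mask()] or
#'   [filter_aberrant()]; intervals to exclude.
#' @param siq_cut Low-SIQ cutoff for the reporting category (inclusive,
#'   `SIQ <= siq_cut`).
#' @return A one-row tibble (class `oxy_range_summary`): `pct_hypoxemia`,
#'   `pct_normoxemia`, `pct_hyperoxemia`, `pct_no_signal`, `pct_low_siq`
#'   (percentages of recorded time), `recorded_time`, `excluded_time`,
#'   `total_time` (seconds).
#' @examples
#' log <- tibble::tibble(t_s = 0:9,
#'                       spo2 = c(90, 93, 97, 94, 95, 91, 96, 92, 98, 96))
#' time_in_ranges(log)
#' @export
time_in_ranges <- function(log, mask = exclusion_mask(), siq_cut = 0.3) {
  if (nrow(log) == 0) abort("`log` must be non-empty.")
  t <- log$t_s
  if (is.unsorted(t, strictly = TRUE)) {
    abort("`log` timestamps must be strictly increasing.")
  }
  ends <- sample_interval_ends(t)
  w <- ends - t
  total <- sum(w)

  # subtract mask overlap from each sample's holding interval
  if (nrow(mask) > 0) {
    for (i in seq_len(nrow(mask))) {
      ov <- pmax(0, pmin(ends, mask$end[i]) - pmax(t, mask$start[i]))
      w <- w - ov
    }
    w <- pmax(w, 0)
  }
  recorded <- sum(w)
  if (recorded <= 0) {
    return(empty_range_summary(total))
  }

  signal <- if ("signal_present" %in% names(log)) {
    log$signal_present & !is.na(log$spo2)
  } else {
    !is.na(log$spo2)
  }
  siq <- if ("siq" %in% names(log)) log$siq else rep(1, nrow(log))

  no_sig <- !signal
  low_siq <- signal & !is.na(siq) & siq <= siq_cut
  spo2 <- round(log$spo2)
  valid <- signal & !low_siq
  hypo <- valid & spo2 <= 91
  normo <- valid & spo2 >= 92 & spo2 <= 96
  hyper <- valid & spo2 >= 97

  pct <- function(sel) 100 * sum(w[sel]) / recorded
  structure(
    tibble::tibble(
      pct_hypoxemia = pct(hypo),
      pct_normoxemia = pct(normo),
      pct_hyperoxemia = pct(hyper),
      pct_no_signal = pct(no_sig),
      pct_low_siq = pct(low_siq),
      recorded_time = recorded,
      excluded_time = total - recorded,
      total_time = total
    ),
    class = c("oxy_range_summary", class(tibble::tibble()))
  )
}

empty_range_summary <- function(total) {
  structure(
    tibble::tibble(
      pct_hypoxemia = NA_real_, pct_normoxemia = NA_real_,
      pct_hyperoxemia = NA_real_, pct_no_signal = NA_real_,
      pct_low_siq = NA_real_,
      recorded_time = 0, excluded_time = total, total_time = total
    ),
    class = c("oxy_range_summary", class(tibble::tibble()))
  )
}

#' Category-per-row view of range summaries
#'
#' Reshapes one or more range summaries into the conventional reporting
#' layout: one row per SpO2 category (no signal, low SIQ, hypoxemia,
#' normoxemia, hyperoxemia), one column per episode/group.
#'
#' @param summaries A tibble of range summaries (one row each), e.g. from
#'   [time_in_ranges()] or [tidy()] on a crossover result.
#' @param labels Optional column labels, one per summary row.
#' @return A tibble with a `category` column and one numeric column per
#'   summary.
#' @export
format_range_table <- function(summaries, labels = NULL) {
  df <- tibble::as_tibble(summaries)
  if (is.null(labels)) labels <- paste0("episode_", seq_len(nrow(df)))
  rows <- c(
    "Time with no signal (%)" = "pct_no_signal",
    "Time with SIQ <= 0.3 (%)" = "pct_low_siq",
    "Time with hypoxemia (SpO2 <= 91%) (%)" = "pct_hypoxemia",
    "Time with normoxemia (SpO2 92% to 96%) (%)" = "pct_normoxemia",
    "Time with hyperoxemia (SpO2 >= 97%) (%)" = "pct_hyperoxemia"
  )
  out <- tibble::tibble(category = names(rows))
  for (j in seq_along(labels)) {
    out[[labels[j]]] <- vapply(rows, function(cl) df[[cl]][j], numeric(1),
                               USE.NAMES = FALSE)
  }
  out
}

#' Extract fixed-width audit windows at protocol anchors
#'
#' Audit comparisons use three windows per patient stay: at admission, after
#' 24 hours and at day 7, each 6 hours wide by default. Windows whose anchor
#' lies entirely outside the log are omitted and reported.
#'
#' @param log Episode samples with `t_s` in seconds from admission.
#' @param anchors Window start times, seconds (default admission, +24 h,
#'   +7 days).
#' @param width_h Window width, hours.
#' @return A list: `windows` (named list of sample tibbles) and `omitted`
#'   (tibble of anchors outside the log, with a message).
#' @export
extract_windows <- function(log,
                            anchors = c(admission = 0,
                                        h24 = 24 * 3600,
                                        day7 = 7 * 24 * 3600),
                            width_h = 6) {
  if (is.null(names(anchors))) names(anchors) <- paste0("w", seq_along(anchors))
  t_max <- max(log$t_s)
  windows <- list()
  omitted <- tibble::tibble(anchor = character(), start_s = numeric(),
                            message = character())
  for (nm in names(anchors)) {
    a <- anchors[[nm]]
    sel <- log$t_s >= a & log$t_s < a + width_h * 3600
    if (a > t_max || !any(sel)) {
      omitted <- dplyr::bind_rows(omitted, tibble::tibble(
        anchor = nm, start_s = a,
        message = "window outside the recorded log; omitted"
      ))
      warn(sprintf("window '%s' (start %.0f s) lies outside the log; omitted.", nm, a))
    } else {
      windows[[nm]] <- log[sel, ]
    }
  }
  list(windows = windows, omitted = omitted)
}

#' Fraction of time the executed FiO2 followed the proposals
#'
#' Time-weighted fraction of the episode during which the FiO2 actually set
#' equals the controller's proposal to within `tol` (open-loop adherence: a
#' nurse executes the proposals and may deviate).
#'
#' @param log Episode samples with columns `fio2_set` and `fio2_proposed`.
#' @param tol Equality tolerance, FiO2 fraction.
#' @return Fraction in `[0, 1]`, or `NA` with a warning when the columns are
#'   missing or never overlap.
#' @export
adherence <- function(log, tol = 0.005) {
  if (!all(c("fio2_set", "fio2_proposed") %in% names(log))) {
    warn("adherence unavailable: log lacks fio2_set and/or fio2_proposed.")
    return(NA_real_)
  }
  ok <- !is.na(log$fio2_set) & !is.na(log$fio2_proposed)
  if (!any(ok)) {
    warn("adherence unavailable: no rows with both fio2_set and fio2_proposed.")
    return(NA_real_)
  }
  lg <- log[ok, ]
  w <- sample_interval_ends(lg$t_s) - lg$t_s
  sum(w[abs(lg$fio2_set - lg$fio2_proposed) <= tol]) / sum(w)
}

#' Compare outcome summaries between two groups
#'
#' Thin wrapper over the standard tests used for time-in-range outcomes:
#' Wilcoxon signed-rank for paired (crossover) comparisons, Mann-Whitney U
#' for unpaired baseline comparisons, and Welch's t test for the
#' study-versus-historical contrast. Not a contribution of this package;
#' it simply routes to `stats::wilcox.test()` / `stats::t.test()`.
#'
#' @param a,b Numeric vectors of per-patient outcome values (e.g.
#'   `pct_normoxemia`), one per group.
#' @param paired Paired comparison (requires equal lengths)?
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `effect`
#'   (mean of differences for paired, difference of means otherwise), `n_a`,
#'   `n_b`. With fewer than 2 observations per group, returns the row with
#'   `NA` statistics and a warning.
#' @export
compare_groups <- function(a, b, paired = FALSE, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (paired && length(a) != length(b)) {
    abort("paired comparison requires equal-length groups.")
  }
  effect <- if (paired) mean(a - b) else mean(a) - mean(b)
  if (length(a) < 2 || length(b) < 2) {
    warn("not computable: fewer than 2 observations per group.")
    return(tibble::tibble(test = test, statistic = NA_real_,
                          p_value = NA_real_, effect = effect,
                          n_a = length(a), n_b = length(b)))
  }
  if (paired && all(a == b)) {
    # degenerate: no non-zero differences; no evidence of any effect
    return(tibble::tibble(test = test, statistic = 0, p_value = 1,
                          effect = 0, n_a = length(a), n_b = length(b)))
  }
  ht <- if (test == "wilcoxon") {
    suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
  } else {
    t.test(a, b, paired = paired)
  }
  tibble::tibble(
    test = if (test == "wilcoxon" && paired) "wilcoxon signed-rank"
           else if (test == "wilcoxon") "mann-whitney"
           else "welch t",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    effect = effect,
    n_a = length(a), n_b = length(b)
  )
}
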