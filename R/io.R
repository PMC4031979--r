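# Episode-log and configuration I/O. Logs are plain CSV (small, auditable,
# matching the clinical provenance of bedside recordings): a samples file
# with a fixed column order, an events file, and a YAML metadata sidecar
# carrying the seed and the effective configuration so any record can be
# regenerated exactly.

LOG_COLUMNS <- c("t_s", "spo2", "hr", "pi", "siq", "signal_present",
                 "fio2_set", "fio2_proposed", "decision_reason")

#' Write an episode record to CSV files
#'
#' Writes `<stem>_samples.csv` (fixed column order: t_s, spo2, hr, pi, siq,
#' signal_present, fio2_set, fio2_proposed, decision_reason; times in seconds
#' from episode start, FiO2 as fraction with 3 decimals, SpO2 as integer
#' percent), `<stem>_events.csv`, and `<stem>_meta.yaml` with the seed,
#' patient parameters and the effective policy configuration.
#'
#' @param episode An `oxy_episode` from [run_episode()], or any list with
#'   `samples`, `events` and `meta` elements.
#' @param stem Path prefix for the three files.
#' @return The three paths, invisibly.
#' @seealso [read_log()] for the lossless round-trip.
#' @export
write_log <- function(episode, stem) {
  samples <- episode$samples[, LOG_COLUMNS]
  samples$fio2_set <- sprintf("%.3f", samples$fio2_set)
  samples$fio2_proposed <- ifelse(is.na(samples$fio2_proposed), "",
                                  sprintf("%.3f", samples$fio2_proposed))
  paths <- paste0(stem, c("_samples.csv", "_events.csv", "_meta.yaml"))
  readr::write_csv(samples, paths[1], na = "")
  readr::write_csv(episode$events, paths[2], na = "")
  meta <- episode$meta
  yaml::write_yaml(list(
    seed = meta$seed,
    profile = meta$profile,
    init_fio2 = meta$init_fio2,
    patient = unclass(meta$patient),
    policy = unclass(meta$policy),
    plan = serialize_plan(meta$plan),
    config_hash = config_hash(meta)
  ), paths[3])
  invisible(paths)
}

serialize_plan <- function(plan) {
  if (is.null(plan)) return(NULL)
  p <- unclass(plan)
  p$sensor <- unclass(p$sensor)
  p
}

# a cheap stable digest of the effective configuration (no external deps):
# serialize deterministically and fold into hex
config_hash <- function(meta) {
  s <- paste(deparse(list(patient = unclass(meta$patient),
                          policy = unclass(meta$policy),
                          plan = serialize_plan(meta$plan),
                          seed = meta$seed)),
             collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

#' Read an episode record back from CSV files
#'
#' Lossless counterpart of [write_log()]. Malformed numeric cells raise an
#' error naming the offending line; unknown extra columns are preserved with
#' a warning; a missing optional `fio2_proposed` column leaves the record
#' readable (adherence is then reported unavailable).
#'
#' @param stem Path prefix used when writing.
#' @return A list with `samples`, `events`, `meta` (class `oxy_episode_log`).
#' @export
read_log <- function(stem) {
  paths <- paste0(stem, c("_samples.csv", "_events.csv", "_meta.yaml"))
  if (!file.exists(paths[1])) abort(sprintf("no samples file at '%s'.", paths[1]))
  samples <- readr::read_csv(paths[1], show_col_types = FALSE,
                             progress = FALSE)
  validate_samples(samples, paths[1])
  extra <- setdiff(names(samples), LOG_COLUMNS)
  if (length(extra)) {
    warn(sprintf("unknown column(s) preserved opaquely: %s",
                 paste(extra, collapse = ", ")))
  }
  events <- if (file.exists(paths[2])) {
    readr::read_csv(paths[2], show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      kind = readr::col_character(),
                      start = readr::col_double(),
                      end = readr::col_double(),
                      magnitude = readr::col_double(),
                      .default = readr::col_guess()
                    ))
  } else {
    tibble::tibble(kind = character(), start = numeric(), end = numeric())
  }
  meta <- if (file.exists(paths[3])) yaml::read_yaml(paths[3]) else list()
  structure(list(samples = samples, events = events, meta = meta),
            class = "oxy_episode_log")
}

validate_samples <- function(samples, path) {
  need <- c("t_s", "spo2")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("'%s' lacks required column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c("t_s", "spo2", "hr", "pi", "siq",
                          "fio2_set", "fio2_proposed"), names(samples))) {
    v <- samples[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        abort(sprintf("'%s': non-numeric value '%s' in column '%s' at line %d.",
                      path, v[bad[1]], col, bad[1] + 1L)) # +1 for the header
      }
      samples[[col]] <- conv
    }
  }
  if (is.unsorted(samples$t_s, strictly = TRUE)) {
    abort(sprintf("'%s': sample timestamps must be strictly increasing.", path))
  }
  invisible(samples)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration with optional top-level sections `controller`,
#' `patient`, `plan`, `sensor` and `profiles`, applies the package defaults
#' for everything omitted (an empty file yields the full defaults: target
#' band 92-96%, lockout 30 s, SIQ cutoff 0.30, rescue below 85% to 100%
#' FiO2), and checks every invariant at load time, naming the violated field.
#' Custom profile tables are validated per bin, including the requirement
#' that the severe profile's step dominates the moderate one's in magnitude
#' in every bin.
#'
#' @param path Path to a YAML file.
#' @return A list: `controller` ([controller_config()]), `patient`
#'   ([patient_params()]), `plan` ([trial_plan()]), `profiles` (named list
#'   with `SH` and `MH` [profile()]s). Echo this into every output for audit
#'   reproducibility.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  controller <- do.call(controller_config,
                        raw$controller %||% list())
  patient <- do.call(patient_params, raw$patient %||% list())
  sensor <- do.call(sensor_params, raw$sensor %||% list())
  plan_args <- raw$plan %||% list()
  plan_args$sensor <- sensor
  plan <- do.call(trial_plan, plan_args)

  profiles <- list(
    SH = load_profile(raw$profiles$SH, "SH"),
    MH = load_profile(raw$profiles$MH, "MH")
  )
  check_profile_dominance(profiles$SH, profiles$MH)

  list(controller = controller, patient = patient, plan = plan,
       profiles = profiles)
}

load_profile <- function(bins, name) {
  if (is.null(bins)) return(profile(name))
  num_or <- function(x, default) {
    x <- suppressWarnings(as.numeric(x %||% default))
    if (is.na(x)) default else x # a YAML .na bound means unbounded
  }
  tb <- tibble::tibble(
    delta_min = vapply(bins, function(b) num_or(b$delta_min, -Inf), 1),
    delta_max = vapply(bins, function(b) num_or(b$delta_max, Inf), 1),
    step = vapply(bins, function(b) as.numeric(b$step), 1)
  )
  profile(name, table = tb)
}

#' Check that the severe profile dominates the moderate one
#'
#' For every integer SpO2 deviation, the severely-hypoxemic profile's step
#' magnitude must be at least the moderately-hypoxemic profile's. Errors
#' naming the first violating deviation.
#'
#' @param sh,mh [profile()] objects.
#' @return `TRUE`, invisibly.
#' @export
check_profile_dominance <- function(sh, mh) {
  deltas <- -30:30
  s_sh <- abs(table_step(sh, deltas))
  s_mh <- abs(table_step(mh, deltas))
  bad <- which(s_sh < s_mh)
  if (length(bad)) {
    abort(sprintf(
      "profile dominance violated at deviation %+d: |SH step| = %.3f < |MH step| = %.3f.",
      deltas[bad[1]], s_sh[bad[1]], s_mh[bad[1]]
    ))
  }
  invisible(TRUE)
}
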