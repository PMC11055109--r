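# Reading and writing the plain-text formats the pipeline exchanges:
# CSV channel matrices for EEG, CSV KSS tables, YAML manifests and
# scenario files.

#' Write an EEG recording to CSV
#'
#' Comma-separated channel matrix with a header row of channel names and
#' a leading `time` column in seconds.  Floats are serialized with 6
#' significant digits.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- nrow(recording$samples)
  df <- data.table::data.table(
    time = signif((seq_len(n) - 1) / recording$sampling_rate, 10)
  )
  for (ch in recording$channel_labels) {
    df[[ch]] <- signif(recording$samples[, ch], 6)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an EEG recording from CSV
#'
#' Expects a comma-separated file with a header of channel names; a
#' leading time column (in seconds) is auto-detected by the label
#' `time` and used to infer the sampling rate.  Without a time column,
#' `sampling_rate` must be supplied.
#'
#' @param path File path.
#' @param sampling_rate Sampling rate in Hz; required when the file has
#'   no `time` column.
#' @param events Named numeric vector of event minutes to attach.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, sampling_rate = NULL,
                         events = c(task_start = 0)) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- data.table::fread(path, showProgress = FALSE)
  if (!nrow(df) || !ncol(df)) abort("empty EEG CSV: ", path)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort("non-numeric or missing cell in ", path, " at data row ",
            bad[1], ", column '", names(df)[j], "'")
    }
    df[[j]] <- v
  }
  has_time <- tolower(names(df)[1]) == "time"
  if (has_time) {
    tt <- df[[1]]
    dt <- diff(tt)
    if (any(dt <= 0)) abort("time column in ", path, " is not strictly increasing")
    sampling_rate <- 1 / median(dt)
    df <- df[, -1]
  } else if (is.null(sampling_rate)) {
    abort("unknown sampling rate: ", path,
          " has no 'time' column and sampling_rate was not supplied")
  }
  eeg_recording(as.matrix(df), sampling_rate, names(df), events)
}

#' Write a KSS table to CSV
#'
#' @param kss Data frame with columns `subject_id`, `group`, `time_min`,
#'   `score`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kss_csv <- function(kss, path) {
  need <- c("subject_id", "group", "time_min", "score")
  if (!all(need %in% names(kss))) {
    abort("KSS table must have columns ", paste(need, collapse = ", "))
  }
  data.table::fwrite(kss[need], path)
  invisible(path)
}

#' Read and validate a KSS table
#'
#' Scores are coerced to integers and must lie on the ordinal 1-9 scale.
#'
#' @param path File path.
#' @return Data frame with columns `subject_id`, `group`, `time_min`,
#'   `score`.
#' @export
read_kss_csv <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- data.table::fread(path, showProgress = FALSE)
  need <- c("subject_id", "group", "time_min", "score")
  if (!all(need %in% names(df))) {
    abort("KSS file ", path, " must have columns ",
          paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  score <- suppressWarnings(as.integer(df$score))
  bad <- which(is.na(score) | score < 1 | score > 9)
  if (length(bad)) {
    abort("invalid KSS score ", df$score[bad[1]], " for subject ",
          df$subject_id[bad[1]], " at minute ", df$time_min[bad[1]],
          " in ", path, " (scores must be integers in 1..9)")
  }
  df$score <- score
  df
}

#' Write a cohort to a directory
#'
#' One EEG CSV per subject/condition, a single `kss.csv` and a
#' `manifest.yaml` describing the dataset (paths, groups, event
#' minutes).  [load_dataset()] reads the directory back.
#'
#' @param cohort A `fatigue_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(seq_len(nrow(cohort$meta)), function(i) {
    key <- cohort$meta$key[i]
    rec <- cohort$recordings[[key]]
    file <- paste0(key, ".csv")
    write_eeg_csv(rec, file.path(dir, file))
    list(key = key, subject_id = cohort$meta$subject_id[i],
         group = cohort$meta$group[i], eeg = file, format = "csv",
         events = as.list(rec$events))
  })
  write_kss_csv(cohort$kss, file.path(dir, "kss.csv"))
  manifest <- list(study = cohort$study, kss = "kss.csv",
                   subjects = subjects)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' Validates that all referenced files exist and that groups come from
#' the four condition labels.
#'
#' @param path Path to a `manifest.yaml`.
#' @return The manifest as a list, with an attribute `dir` holding its
#'   directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  if (is.null(m$subjects) || !length(m$subjects)) {
    abort("manifest ", path, " lists no subjects")
  }
  for (s in m$subjects) {
    if (!s$group %in% scent_groups()) {
      abort("manifest group '", s$group, "' is not one of: ",
            paste(scent_groups(), collapse = ", "))
    }
    f <- file.path(dir, s$eeg)
    if (!file.exists(f)) abort("EEG file referenced by manifest is missing: ", f)
  }
  if (!is.null(m$kss) && !file.exists(file.path(dir, m$kss))) {
    abort("KSS file referenced by manifest is missing: ",
          file.path(dir, m$kss))
  }
  attr(m, "dir") <- dir
  m
}

#' Load a cohort dataset from a manifest
#'
#' @param path Path to a `manifest.yaml` written by [write_cohort()] (or
#'   assembled by hand in the same layout).
#' @return A `fatigue_cohort`.
#' @export
load_dataset <- function(path) {
  m <- read_manifest(path)
  dir <- attr(m, "dir")
  recordings <- list()
  meta <- list()
  for (s in m$subjects) {
    key <- if (!is.null(s$key)) s$key else paste0(s$subject_id, ".", s$group)
    events <- if (!is.null(s$events)) unlist(s$events) else c(task_start = 0)
    recordings[[key]] <- read_eeg_csv(file.path(dir, s$eeg), events = events)
    meta[[key]] <- data.frame(key = key, subject_id = s$subject_id,
                              group = s$group, stringsAsFactors = FALSE)
  }
  kss <- if (!is.null(m$kss)) read_kss_csv(file.path(dir, m$kss)) else NULL
  structure(
    list(study = if (!is.null(m$study)) m$study else "identification",
         recordings = recordings,
         meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         kss = kss),
    class = "fatigue_cohort"
  )
}

#' Write / read a scenario configuration file
#'
#' Scenario files are YAML: scalar fields plus nested per-band envelope
#' tables and an optional intervention multiplier table.
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `path` invisibly (`write_scenario`); a [scenario_config()]
#'   (`read_scenario`).
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$band_envelopes <- lapply(x$band_envelopes, as.list)
  if (!is.null(x$intervention_effect)) {
    x$intervention_effect <- as.list(x$intervention_effect)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort("scenario file not found: ", path)
  x <- yaml::read_yaml(path)
  env <- lapply(x$band_envelopes, function(e) {
    data.frame(minute = unlist(e$minute), amp = unlist(e$amp))
  })
  eff <- if (!is.null(x$intervention_effect)) {
    as.data.frame(lapply(x$intervention_effect, unlist))
  } else NULL
  scenario_config(
    group = x$group, duration_min = x$duration_min,
    sampling_rate = x$sampling_rate, n_subjects = x$n_subjects,
    intervention_minute = x$intervention_minute,
    band_envelopes = env, intervention_effect = eff,
    noise_sd = x$noise_sd, kss = x$kss, study = x$study,
    channel_labels = unlist(x$channel_labels), seed = x$seed
  )
}
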