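# The two study pipelines: fatigue identification and scent
# intervention.

.subject_index_series <- function(cohort, groups = NULL) {
  meta <- cohort$meta
  if (!is.null(groups)) meta <- meta[meta$group %in% groups, , drop = FALSE]
  out <- lapply(seq_len(nrow(meta)), function(i) {
    s <- compute_index_series(cohort$recordings[[meta$key[i]]])
    s$subject_id <- meta$subject_id[i]
    s$condition <- meta$group[i]
    s
  })
  do.call(rbind, out)
}

.value_at <- function(series, minute, column) {
  v <- series[[column]][series$start_min == minute]
  if (!length(v)) {
    abort("no epoch starting at minute ", minute, " (available: ",
          paste(range(series$start_min), collapse = "-"), ")")
  }
  v
}

#' Run the fatigue identification study
#'
#' For each subject, the per-minute fatigue indices are computed over a
#' single continuous drive; each index at an early-drive reference
#' minute is compared with its value at the end of the drive by a
#' paired t-test (with a Shapiro-Wilk normality screen on the paired
#' differences), together with the pre/post KSS scores.  Also returns
#' cohort-mean 2-min series of the four band activities and three
#' indices (each 2-min value is the mean of two consecutive 1-min
#' epochs).
#'
#' @param cohort A `fatigue_cohort` (one recording per subject).
#' @param pre_min Reference minute of the early-drive epoch; the value
#'   "at `pre_min` minutes" is the single 1-min epoch starting there
#'   (default 5).
#' @param post_min Start minute of the late-drive epoch; default the
#'   last complete epoch (minute `duration - 1`, i.e. the epoch running
#'   into the end of a 30-min drive).
#' @return Object of class `study_result` with elements `study`,
#'   `tests` (one row per variable: normality p, means, pre-minus-post
#'   difference, t, p), `series_2min`, `n`, `excluded`.
#' @export
#' @examples
#' coh <- simulate_cohort("identification", n_subjects = 3, seed = 1,
#'                        duration_min = 8)
#' res <- run_identification_study(coh, pre_min = 1, post_min = 7)
#' res$tests
run_identification_study <- function(cohort, pre_min = 5, post_min = NULL) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  durations <- vapply(cohort$recordings, recording_minutes, numeric(1))
  if (is.null(post_min)) post_min <- floor(max(durations)) - 1
  usable <- durations >= (post_min + 1) - 1e-9
  excluded <- cohort$meta$key[!usable[cohort$meta$key]]
  if (length(excluded)) {
    warning("excluding recording(s) shorter than ", post_min + 1,
            " min: ", paste(excluded, collapse = ", "), call. = FALSE)
    cohort$meta <- cohort$meta[!cohort$meta$key %in% excluded, , drop = FALSE]
  }
  if (nrow(cohort$meta) < 2) {
    abort("fewer than 2 usable subjects after exclusions")
  }

  series <- .subject_index_series(cohort)
  subjects <- unique(cohort$meta$subject_id)
  index_cols <- c("R_ab", "R_t_ab", "R_at_ab")
  tests <- lapply(index_cols, function(col) {
    pre <- vapply(subjects, function(s) {
      .value_at(series[series$subject_id == s, ], pre_min, col)
    }, numeric(1))
    post <- vapply(subjects, function(s) {
      .value_at(series[series$subject_id == s, ], post_min, col)
    }, numeric(1))
    .test_row(col, pre, post)
  })

  if (!is.null(cohort$kss)) {
    times <- sort(unique(cohort$kss$time_min))
    kpre <- .kss_at(cohort$kss, subjects, times[1])
    kpost <- .kss_at(cohort$kss, subjects, times[length(times)])
    tests <- c(tests, list(.test_row("KSS", kpre, kpost)))
  }
  tests <- do.call(rbind, tests)

  structure(
    list(study = "identification",
         tests = tests,
         series_2min = .two_minute_series(series),
         pre_min = pre_min, post_min = post_min,
         n = length(subjects), excluded = excluded),
    class = "study_result"
  )
}

.test_row <- function(variable, pre, post) {
  pt <- paired_t(pre, post)
  d <- pre - post
  norm_p <- if (length(d) >= 3 && sd(d) > 0) normality_p(d) else NA_real_
  cbind(data.frame(variable = variable, normality_p = norm_p),
        as.data.frame(pt))
}

.kss_at <- function(kss, subjects, minute) {
  vapply(subjects, function(s) {
    v <- kss$score[kss$subject_id == s & kss$time_min == minute]
    if (!length(v)) abort("no KSS record for subject ", s, " at minute ", minute)
    as.numeric(v[1])
  }, numeric(1))
}

# cohort-mean series on a 2-min grid: mean of two consecutive 1-min
# epochs per subject, then mean over subjects
.two_minute_series <- function(series) {
  cols <- intersect(c("G_theta", "G_alpha", "G_beta", "G_gamma",
                      "R_ab", "R_t_ab", "R_at_ab"), names(series))
  series$block <- 2 * (series$start_min %/% 2)
  per_subject <- stats::aggregate(series[cols],
                                  by = list(block = series$block,
                                            subject_id = series$subject_id),
                                  FUN = mean)
  out <- stats::aggregate(per_subject[cols],
                          by = list(block_start_min = per_subject$block),
                          FUN = mean)
  out[order(out$block_start_min), , drop = FALSE]
}

#' Run the scent intervention study
#'
#' Requires all four conditions (control, peppermint, grapefruit,
#' lavender), KSS at minutes 28 and 40, and recordings covering the
#' 40-min analysis window (driving continues to 45 min, but the
#' analysis stops at 40).  Produces:
#' * per-condition paired t-tests of KSS at 28 vs 40 min
#'   (`kss_within`, diff = 28-min minus 40-min);
#' * each scent's 40-min KSS against the control 40-min KSS, paired
#'   across subjects since every subject experienced every condition
#'   (`kss_between`, diff = control minus scent);
#' * a one-way ANOVA across the three scents' KSS improvements
#'   (`kss_anova`);
#' * per scent, paired t-tests of R(alpha/beta) at the 28-min baseline
#'   epoch versus each of minutes 32, 34, 36, 38, 40 (`rab_tests`);
#' * a two-way repeated-measures ANOVA of R(alpha/beta) over the three
#'   scents and five post-release minutes (`rm_anova`);
#' * cohort-mean per-minute R(alpha/beta) trajectories per condition
#'   (`rab_series`).
#'
#' @param cohort A `fatigue_cohort` from [simulate_cohort()] or
#'   [load_dataset()].
#' @param baseline_min Baseline epoch start minute (default 28; the
#'   single 1-min epoch starting there).
#' @param test_minutes Post-release epoch start minutes (default
#'   `c(32, 34, 36, 38, 40)`).
#' @return Object of class `study_result`.
#' @export
run_intervention_study <- function(cohort, baseline_min = 28,
                                   test_minutes = c(32, 34, 36, 38, 40)) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  groups <- scent_groups()
  missing_g <- setdiff(groups, unique(cohort$meta$group))
  if (length(missing_g)) {
    abort("missing condition(s): ", paste(missing_g, collapse = ", "))
  }
  if (is.null(cohort$kss)) abort("cohort has no KSS records")
  kss_times <- c(28, 40)
  for (g in groups) {
    have <- unique(cohort$kss$time_min[cohort$kss$group == g])
    lack <- setdiff(kss_times, have)
    if (length(lack)) {
      abort("KSS records missing for group ", g, " at minute(s) ",
            paste(lack, collapse = ", "))
    }
  }
  need_min <- max(test_minutes) + 1
  durations <- vapply(cohort$recordings, recording_minutes, numeric(1))
  short <- names(durations)[durations < need_min - 1e-9]
  if (length(short)) {
    abort("recording(s) shorter than the ", need_min,
          "-min analysis window: ", paste(short, collapse = ", "))
  }

  series <- .subject_index_series(cohort)
  subjects <- sort(unique(cohort$meta$subject_id))
  scents <- setdiff(groups, "control")

  rab_at <- function(group, minute) {
    vapply(subjects, function(s) {
      .value_at(series[series$subject_id == s & series$condition == group, ],
                minute, "R_ab")
    }, numeric(1))
  }

  kss_within <- do.call(rbind, lapply(groups, function(g) {
    sub <- cohort$kss[cohort$kss$group == g, ]
    row <- .test_row(g, .kss_at(sub, subjects, 28), .kss_at(sub, subjects, 40))
    names(row)[1] <- "group"
    row
  }))

  control40 <- .kss_at(cohort$kss[cohort$kss$group == "control", ], subjects, 40)
  kss_between <- do.call(rbind, lapply(scents, function(g) {
    g40 <- .kss_at(cohort$kss[cohort$kss$group == g, ], subjects, 40)
    row <- .test_row(g, control40, g40)
    names(row)[1] <- "group"
    row
  }))

  deltas <- lapply(scents, function(g) {
    sub <- cohort$kss[cohort$kss$group == g, ]
    .kss_at(sub, subjects, 28) - .kss_at(sub, subjects, 40)
  })
  kss_anova <- one_way_anova(deltas)

  rab_tests <- do.call(rbind, lapply(scents, function(g) {
    base <- rab_at(g, baseline_min)
    do.call(rbind, lapply(test_minutes, function(m) {
      row <- .test_row(g, base, rab_at(g, m))
      names(row)[1] <- "group"
      cbind(row[1], minute = m, row[-1])
    }))
  }))

  rm_data <- do.call(rbind, lapply(scents, function(g) {
    do.call(rbind, lapply(test_minutes, function(m) {
      data.frame(subject = subjects, treatment = g, time = m,
                 value = rab_at(g, m), stringsAsFactors = FALSE)
    }))
  }))
  rm_res <- rm_anova(rm_data)

  minutes <- sort(unique(series$start_min))
  rab_series <- do.call(rbind, lapply(groups, function(g) {
    sub <- series[series$condition == g, ]
    agg <- stats::aggregate(sub["R_ab"], by = list(minute = sub$start_min),
                            FUN = mean)
    cbind(group = g, agg)
  }))

  structure(
    list(study = "intervention",
         kss_within = kss_within,
         kss_between = kss_between,
         kss_anova = kss_anova,
         rab_tests = rab_tests,
         rm_anova = rm_res,
         rab_series = rab_series,
         baseline_min = baseline_min, test_minutes = test_minutes,
         n = length(subjects)),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", x$study, "study, n =", x$n, "\n")
  if (x$study == "identification") {
    print(x$tests, digits = 4)
  } else {
    cat("KSS within-condition (28 vs 40 min):\n")
    print(x$kss_within, digits = 4)
    cat("R(alpha/beta) baseline vs post-release minutes:\n")
    print(x$rab_tests[c("group", "minute", "diff", "t", "p")], digits = 4)
    cat("Repeated-measures ANOVA:\n")
    print(x$rm_anova, digits = 4)
  }
  invisible(x)
}
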