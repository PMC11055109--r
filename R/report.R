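# Tabular report rendering: CSV tables shaped like the standard
# fatigue-study summaries, a JSON overview, and the time-series CSVs.

# All printed floats use 3 decimals; printed differences are recomputed
# from the printed (rounded) means so every table is internally
# consistent after rounding.
.r3 <- function(x) round(x, 3)
.printed_diff <- function(pre, post) .r3(.r3(pre) - .r3(post))

.fmt_df <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .r3)
  df
}

#' Write study result tables to a directory
#'
#' Renders a `study_result` as CSV tables (3-decimal floats, differences
#' under the pre-minus-post sign convention, recomputed from the rounded
#' means so each file is internally consistent), a JSON summary and the
#' cohort-mean time-series CSVs.  Rerunning on the same result produces
#' identical files.
#'
#' @param result A `study_result` from [run_identification_study()] or
#'   [run_intervention_study()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(result, out_dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(.fmt_df(df), path)
    files <<- c(files, path)
  }

  if (result$study == "identification") {
    tests <- result$tests
    tests$diff <- .printed_diff(tests$mean_pre, tests$mean_post)
    w(tests[c("variable", "n", "normality_p", "mean_pre", "mean_post",
              "diff", "t", "p")], "identification_tests.csv")
    w(result$series_2min, "series_2min.csv")
    summary <- list(
      study = "identification", n = result$n,
      pre_min = result$pre_min, post_min = result$post_min,
      excluded = as.list(result$excluded),
      tests = .fmt_df(tests)
    )
  } else {
    kw <- result$kss_within
    kb <- result$kss_between
    tab2 <- data.frame(
      group = kw$group,
      m_28 = .r3(kw$mean_pre), sd_28 = .r3(kw$sd_pre),
      m_40 = .r3(kw$mean_post), sd_40 = .r3(kw$sd_post),
      diff = .printed_diff(kw$mean_pre, kw$mean_post),
      t = .r3(kw$t), p = .r3(kw$p)
    )
    bi <- match(tab2$group, kb$group)
    tab2$diff_vs_control <- .printed_diff(kb$mean_pre, kb$mean_post)[bi]
    tab2$t_vs_control <- .r3(kb$t)[bi]
    tab2$p_vs_control <- .r3(kb$p)[bi]
    w(tab2, "kss_tests.csv")

    rt <- result$rab_tests
    rt$diff <- .printed_diff(rt$mean_pre, rt$mean_post)
    w(rt[c("group", "minute", "n", "mean_pre", "mean_post", "diff",
           "t", "p")], "rab_tests.csv")
    w(as.data.frame(result$rm_anova), "rm_anova.csv")
    w(result$rab_series, "rab_series.csv")
    w(data.frame(F = result$kss_anova$F, df1 = result$kss_anova$df1,
                 df2 = result$kss_anova$df2, p = result$kss_anova$p),
      "kss_anova.csv")
    summary <- list(
      study = "intervention", n = result$n,
      baseline_min = result$baseline_min,
      test_minutes = result$test_minutes,
      kss_within = .fmt_df(result$kss_within),
      kss_between = .fmt_df(result$kss_between),
      kss_anova = lapply(result$kss_anova, .r3),
      rab_tests = .fmt_df(result$rab_tests),
      rm_anova = .fmt_df(as.data.frame(result$rm_anova))
    )
  }
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, path)
  invisible(files)
}
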