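# Statistical machinery for the study pipelines: normality screening,
# paired t-tests, one-way ANOVA and two-way within-subjects
# (repeated-measures) ANOVA with Greenhouse-Geisser correction.

#' Shapiro-Wilk normality p-value
#'
#' Normality screen applied to paired differences before each paired
#' t-test (the standard small-sample choice).
#'
#' @param x Numeric vector, `3 <= length(x) <= 5000`.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_p <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) abort("normality_p needs at least 3 observations")
  if (sd(x) == 0) abort("degenerate input: all values are identical")
  shapiro.test(x)$p.value
}

#' Paired-samples t-test
#'
#' Classical paired t with `df = n - 1` and a two-sided p-value.  The
#' reported difference follows the pre-minus-post convention used in
#' fatigue tables: `diff = mean_pre - mean_post`, so an index or KSS
#' score that *rises* over the drive yields a negative difference (and a
#' negative t).
#'
#' @param pre,post Numeric vectors of equal length (`n >= 2`), paired by
#'   subject.
#' @return Object of class `paired_test`: list with `mean_pre`,
#'   `mean_post`, `sd_pre`, `sd_post`, `diff`, `t`, `df`, `p`, `n`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 4), c(2, 4, 4, 7))
paired_t <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post)) abort("pre and post must have equal length")
  n <- length(pre)
  if (n < 2) abort("paired_t needs at least 2 pairs")
  d <- pre - post
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(structure(list(mean_pre = mean(pre), mean_post = mean(post),
                            sd_pre = sd(pre), sd_post = sd(post),
                            diff = 0, t = 0, df = n - 1, p = 1, n = n),
                       class = "paired_test"))
    }
    abort("degenerate input: paired differences have zero variance")
  }
  ht <- t.test(pre, post, paired = TRUE)
  structure(
    list(mean_pre = mean(pre), mean_post = mean(post),
         sd_pre = sd(pre), sd_post = sd(post),
         diff = mean(pre) - mean(post),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, n = n),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "<paired_test> n=%d  pre=%.3f  post=%.3f  diff=%.3f  t=%.3f  df=%d  p=%.4g\n",
    x$n, x$mean_pre, x$mean_post, x$diff, x$t, x$df, x$p))
  invisible(x)
}

#' @export
as.data.frame.paired_test <- function(x, ...) {
  data.frame(n = x$n, mean_pre = x$mean_pre, mean_post = x$mean_post,
             sd_pre = x$sd_pre, sd_post = x$sd_post,
             diff = x$diff, t = x$t, df = x$df, p = x$p)
}

#' One-way between-groups ANOVA
#'
#' Classical F-test with `df = (k - 1, N - k)` assuming equal variances.
#'
#' @param groups List of numeric vectors (>= 2 groups, each `n >= 2`).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' one_way_anova(list(rnorm(5), rnorm(5), rnorm(5)))
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("one_way_anova needs a list of at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("each group needs at least 2 observations")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (sd(values) == 0) abort("degenerate input: all values are identical")
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic),
       df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
       p = ht$p.value)
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subjects two-way ANOVA: every subject is observed in
#' every treatment x time cell (complete balanced table; missing cells
#' are an error, never imputed).  Reports the uncorrected F and p for
#' the treatment main effect, the time main effect and their
#' interaction, plus Greenhouse-Geisser-corrected p-values (`p_gg`) as
#' an auxiliary column since sphericity is rarely credible for
#' trajectories sampled minutes apart.  The uncorrected values are the
#' headline results.
#'
#' @param data Data frame in long format.
#' @param value,subject,treatment,time Column names.
#' @return Object of class `rm_anova`: data frame with one row per
#'   effect (`treatment`, `time`, `treatment:time`) and columns `df1`,
#'   `df2`, `F`, `p`, `epsilon`, `p_gg`.
#' @export
#' @examples
#' d <- expand.grid(subject = 1:5, treatment = c("a", "b"), time = 1:3)
#' d$value <- rnorm(nrow(d))
#' rm_anova(d)
rm_anova <- function(data, value = "value", subject = "subject",
                     treatment = "treatment", time = "time") {
  need <- c(value, subject, treatment, time)
  if (!all(need %in% names(data))) {
    abort("data must have columns ", paste(need, collapse = ", "))
  }
  d <- data.frame(
    value = as.numeric(data[[value]]),
    subject = factor(data[[subject]]),
    treatment = factor(data[[treatment]]),
    time = factor(data[[time]])
  )
  if (any(!is.finite(d$value))) abort("values must be finite")
  tab <- table(d$subject, d$treatment, d$time)
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    if (nrow(miss)) {
      cells <- apply(miss, 1, function(i) {
        paste0(dimnames(tab)[[1]][i[1]], "/", dimnames(tab)[[2]][i[2]],
               "/", dimnames(tab)[[3]][i[3]])
      })
      abort("incomplete design; missing subject/treatment/time cells: ",
            paste(cells, collapse = ", "))
    }
    abort("design must have exactly one observation per subject/treatment/time cell")
  }

  fit <- aov(value ~ treatment * time + Error(subject / (treatment * time)),
             data = d)
  sm <- summary(fit)
  pick <- function(stratum, effect) {
    tb <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(effect, trimws(rownames(tb)))
    j <- match("Residuals", trimws(rownames(tb)))
    ss_e <- tb[i, "Sum Sq"]; ss_r <- tb[j, "Sum Sq"]
    f <- tb[i, "F value"]; p <- tb[i, "Pr(>F)"]
    if (ss_e < 1e-12 * max(ss_r, 1)) { f <- 0; p <- 1 }   # degenerate: no effect
    list(df1 = tb[i, "Df"], df2 = tb[j, "Df"], F = f, p = p)
  }
  eff <- list(
    treatment = pick("subject:treatment", "treatment"),
    time = pick("subject:time", "time"),
    `treatment:time` = pick("subject:treatment:time", "treatment:time")
  )

  eps <- .gg_epsilon(d)
  out <- do.call(rbind, lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    epsilon <- eps[[nm]]
    data.frame(effect = nm, df1 = e$df1, df2 = e$df2, F = e$F, p = e$p,
               epsilon = epsilon,
               p_gg = if (e$F == 0) 1 else
                 pf(e$F, epsilon * e$df1, epsilon * e$df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("rm_anova", "data.frame")
  out
}

# Greenhouse-Geisser epsilon per within-subject effect: project the
# subject x cell matrix onto orthonormal effect contrasts C, then
# eps = tr(S)^2 / (df * tr(S^2)) with S = cov of the projected scores.
.gg_epsilon <- function(d) {
  a <- nlevels(d$treatment); b <- nlevels(d$time)
  d <- d[order(d$subject, d$treatment, d$time), ]
  Y <- matrix(d$value, nrow = nlevels(d$subject), ncol = a * b, byrow = TRUE)
  orth <- function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  }
  ones <- function(k) matrix(1 / sqrt(k), k, 1)
  eps_for <- function(M) {
    S <- stats::cov(Y %*% M)
    df <- ncol(M)
    if (sum(diag(S)) <= 0) return(1)
    min(1, sum(diag(S))^2 / (df * sum(S^2)))
  }
  list(
    treatment = eps_for(kronecker(orth(a), ones(b))),
    time = eps_for(kronecker(ones(a), orth(b))),
    `treatment:time` = eps_for(kronecker(orth(a), orth(b)))
  )
}
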