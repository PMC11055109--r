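# Normality screening, paired t, one-way ANOVA, repeated-measures ANOVA.

test_that("normality screen behaves like Shapiro-Wilk should", {
  expect_error(normality_p(c(1, 2)), "at least 3")
  expect_error(normality_p(rep(1, 10)), "degenerate")

  # p-values approximately uniform under normality
  withr::with_seed(21, {
    ps <- vapply(1:500, function(i) normality_p(rnorm(50)), numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  # strong power against heavy skew
  withr::with_seed(22, {
    rej <- vapply(1:200, function(i) normality_p(exp(rnorm(50))) < 0.05,
                  logical(1))
  })
  expect_gte(mean(rej), 0.9)
})

test_that("paired t matches its closed form and sign convention", {
  r <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(r$t, r$p, r$diff), c(0, 1, 0))

  # differences {1,2,3}: t = mean/sd * sqrt(n) = 2 / (1/sqrt(3))
  r2 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r2$df, 2)

  # pre-minus-post convention: rising scores give a negative difference
  pre <- 2.929 + c(-0.5, 0, 0.5, -0.25, 0.25)
  post <- 4.929 + c(0.5, -0.5, 0, 0.25, -0.25)
  expect_equal(paired_t(pre, post)$diff, -2, tolerance = 1e-12)

  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("paired t equals the one-sample t on the differences", {
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(4:20, 1)
      pre <- rnorm(n); post <- rnorm(n)
      r <- paired_t(pre, post)
      d <- pre - post
      t_oracle <- mean(d) / (sd(d) / sqrt(n))
      p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 1)
      expect_equal(r$t, t_oracle, tolerance = 1e-10)
      expect_equal(r$p, p_oracle, tolerance = 1e-10)
      expect_equal(sign(r$t), sign(r$diff))
    }
  })
})

test_that("one-way ANOVA matches the two-group t-squared identity", {
  x <- c(1.2, 1.9, 2.4, 3.1)
  expect_equal(one_way_anova(list(x, x, x))$F, 0, tolerance = 1e-12)

  withr::with_seed(24, {
    a <- rnorm(8); b <- rnorm(9, 0.5)
  })
  r <- one_way_anova(list(a, b))
  t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(r$F, unname(t2), tolerance = 1e-10)
  expect_equal(r$df1, 1); expect_equal(r$df2, 15)

  expect_error(one_way_anova(list(a)), "at least 2")
  expect_error(one_way_anova(list(a, 1)), "at least 2 obs")
})

test_that("paired t and one-way ANOVA hold their nominal type-I rate", {
  withr::with_seed(25, {
    rej <- vapply(1:2000, function(i) {
      g <- list(rnorm(8), rnorm(8), rnorm(8))
      one_way_anova(g)$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rej), 0.03); expect_lte(mean(rej), 0.07)
})

test_that("repeated-measures ANOVA agrees with brute-force sums of squares", {
  withr::with_seed(26, {
    for (rep in 1:5) {
      d <- expand.grid(subject = factor(1:3),
                       treatment = factor(c("p", "g", "l")),
                       time = factor(c(32, 34, 36, 38, 40)))
      d$value <- rnorm(nrow(d))
      r <- rm_anova(d)
      o <- brute_rm(d)
      expect_equal(r$F[r$effect == "treatment"], o$F_treatment, tolerance = 1e-8)
      expect_equal(r$F[r$effect == "time"], o$F_time, tolerance = 1e-8)
      expect_equal(r$F[r$effect == "treatment:time"], o$F_interaction,
                   tolerance = 1e-8)
    }
  })
})

test_that("repeated-measures ANOVA handles structure and degenerate input", {
  d <- expand.grid(subject = factor(1:11),
                   treatment = factor(c("p", "g", "l")),
                   time = factor(c(32, 34, 36, 38, 40)))

  # identical values in every cell: no effects anywhere
  d$value <- 1
  r0 <- rm_anova(d)
  expect_true(all(r0$F == 0) && all(r0$p == 1))

  # purely additive time effect: treatment F ~ 0, time F enormous
  d$value <- as.numeric(d$time) + rep(rnorm(11, sd = 0.1), times = 15)
  r1 <- rm_anova(d)
  expect_equal(r1$F[r1$effect == "treatment"], 0, tolerance = 1e-8)
  expect_gt(r1$F[r1$effect == "time"], 100)

  # 3 x 5 within design: interaction df = (3-1)(5-1) = 8
  withr::with_seed(27, d$value <- rnorm(nrow(d)))
  r2 <- rm_anova(d)
  i <- r2$effect == "treatment:time"
  expect_equal(r2$df1[i], 8)
  expect_equal(r2$df2[i], 80)
  expect_true(all(r2$epsilon >= 1 / r2$df1 - 1e-9 & r2$epsilon <= 1))

  # missing cell is an error naming the cell, never imputed
  expect_error(rm_anova(d[-1, ]), "missing subject/treatment/time")
})
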