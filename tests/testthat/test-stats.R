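test_that("paired t-test matches the closed form", {
  r <- paired_ttest(c(2, 3, 4), c(1, 1, 1))   # differences 1, 2, 3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  set.seed(24)
  # mean-zero symmetric differences give a small statistic
  d <- rnorm(40)
  r0 <- paired_ttest(d - mean(d) + 1, rep(1, 40))
  expect_lt(abs(r0$t), 1e-8)
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  # agreement with the closed form on random data
  for (i in 1:50) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(length(a))
    r <- paired_ttest(a, b)
    d <- a - b
    t_ref <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    expect_equal(r$t, t_ref, tolerance = 1e-10)
    expect_equal(r$p, 2 * stats::pt(-abs(t_ref), length(d) - 1),
                 tolerance = 1e-10)
  }
})

test_that("mixed RM-ANOVA agrees with an independent split-plot fit", {
  set.seed(25)
  n <- 10
  d <- expand.grid(subject = sprintf("s%02d", 1:n),
                   measure = c("m1", "m2", "m3"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(substr(d$subject, 2, 3)) <= 5, "I", "Diff")
  d$value <- rnorm(nrow(d)) +
    0.8 * (d$group == "I") + 0.5 * (d$measure == "m3")
  res <- rm_anova_mixed(d, "value", "subject", "measure", "group")
  # oracle: classical split-plot ANOVA through aov error strata
  d$subject <- factor(d$subject); d$measure <- factor(d$measure)
  d$group <- factor(d$group)
  oracle <- summary(stats::aov(value ~ group * measure +
                                 Error(subject / measure), data = d))
  btw <- oracle[["Error: subject"]][[1]]
  wth <- oracle[["Error: subject:measure"]][[1]]
  expect_equal(res$F[res$effect == "between"], btw["group", "F value"],
               tolerance = 1e-6)
  expect_equal(res$p[res$effect == "between"], btw["group", "Pr(>F)"],
               tolerance = 1e-6)
  expect_equal(res$F[res$effect == "within"], wth["measure", "F value"],
               tolerance = 1e-6)
  expect_equal(res$F[res$effect == "within:between"],
               wth["group:measure", "F value"], tolerance = 1e-6)
  expect_equal(res$p[res$effect == "within"], wth["measure", "Pr(>F)"],
               tolerance = 1e-6)
})

test_that("RM-ANOVA output is invariant to subject order", {
  set.seed(26)
  d <- expand.grid(subject = sprintf("s%02d", 1:8),
                   measure = c("m1", "m2", "m3", "m4"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(substr(d$subject, 2, 3)) %% 2 == 0, "A", "B")
  d$value <- rnorm(nrow(d))
  r1 <- rm_anova_mixed(d, "value", "subject", "measure", "group")
  r2 <- rm_anova_mixed(d[sample(nrow(d)), ], "value", "subject",
                       "measure", "group")
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
})

test_that("sphericity handling: epsilon near 1 under compound symmetry, 1 for k = 2", {
  set.seed(27)
  n <- 300; k <- 4
  subj <- rnorm(n, sd = 1.2)
  d <- expand.grid(subject = seq_len(n), measure = paste0("m", 1:k))
  d$value <- subj[d$subject] + rnorm(nrow(d))
  res <- rm_anova_mixed(d, "value", "subject", "measure")
  expect_gt(res$epsilon_gg[res$effect == "within"], 0.97)
  expect_true(res$epsilon_gg[res$effect == "within"] <= 1)
  # two repeated measures: sphericity is vacuous
  d2 <- expand.grid(subject = 1:9, measure = c("m1", "m2"))
  d2$value <- rnorm(18)
  res2 <- rm_anova_mixed(d2, "value", "subject", "measure")
  expect_identical(res2$epsilon_gg, 1)
  expect_identical(res2$mauchly_p, 1)
  expect_equal(res2$p_gg, res2$p)
})

test_that("epsilon bounds and the Mauchly gate are respected", {
  set.seed(28)
  n <- 12; k <- 4
  # strongly non-spherical covariance: one dominant component
  base <- rnorm(n)
  d <- expand.grid(subject = seq_len(n), measure = paste0("m", 1:k))
  scale <- c(0.2, 0.5, 1, 4)[match(d$measure, paste0("m", 1:k))]
  d$value <- base[d$subject] * scale + rnorm(nrow(d), sd = 0.3)
  res <- rm_anova_mixed(d, "value", "subject", "measure")
  eps <- res$epsilon_gg[res$effect == "within"]
  expect_gte(eps, 1 / (k - 1))
  expect_lte(eps, 1)
  w <- res[res$effect == "within", ]
  if (!is.na(w$mauchly_p) && w$mauchly_p < 0.05) {
    expect_equal(w$p_adj, w$p_gg)
    expect_equal(w$df1_adj, eps * w$df1)
  } else {
    expect_equal(w$p_adj, w$p)
  }
  expect_error(rm_anova_mixed(d[-1, ], "value", "subject", "measure"),
               "incomplete")
})
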