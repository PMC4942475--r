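test_that("global switch cost is the correct-trial block RT difference", {
  tr <- function(bt, rt, correct = TRUE, responded = TRUE) {
    data.frame(block_type = bt, rt = rt, correct = correct,
               responded = responded)
  }
  # identical distributions
  t0 <- rbind(tr("single", 0.5), tr("switch", 0.5))
  expect_equal(compute_global_switch_cost(t0), 0)
  # young group mean reproduced from exact arithmetic
  t1 <- rbind(tr("single", c(0.50, 0.50)), tr("switch", c(0.72, 0.72)))
  expect_equal(compute_global_switch_cost(t1), 0.22)
  # incorrect trials are excluded: 0.75 - 0.50
  t2 <- rbind(tr("single", c(0.4, 0.5, 0.6), correct = c(TRUE, FALSE, TRUE)),
              tr("switch", c(0.7, 0.8)))
  expect_equal(compute_global_switch_cost(t2), 0.25)
})

test_that("switch cost ignores trial order, rest trials, and no-go trials", {
  base <- data.frame(
    block_type = c("single", "single", "switch", "switch"),
    rt = c(0.4, 0.6, 0.7, 0.9), correct = TRUE, responded = TRUE)
  cost <- compute_global_switch_cost(base)
  shuffled <- base[c(3, 1, 4, 2), ]
  expect_equal(compute_global_switch_cost(shuffled), cost)
  withrest <- rbind(base, data.frame(block_type = "rest", rt = 5,
                                     correct = TRUE, responded = TRUE))
  expect_equal(compute_global_switch_cost(withrest), cost)
  nogo <- rbind(base, data.frame(block_type = "switch", rt = 0.01,
                                 correct = TRUE, responded = FALSE))
  expect_equal(compute_global_switch_cost(nogo), cost)
})

test_that("switch cost fails without correct trials in both conditions", {
  bad <- data.frame(block_type = c("single", "switch"), rt = c(0.5, 0.7),
                    correct = c(TRUE, FALSE), responded = TRUE)
  expect_error(compute_global_switch_cost(bad), "insufficient trials")
})

test_that("nWBV is (gm+wm)/(gm+wm+csf), scale invariant, boundary 1", {
  expect_equal(compute_nwbv(100, 100, 100), 2 / 3)
  expect_equal(compute_nwbv(600, 500, 300), 1100 / 1400)
  expect_equal(compute_nwbv(700, 400, 0), 1)
  expect_equal(compute_nwbv(6, 5, 3), compute_nwbv(600, 500, 300))
  expect_error(compute_nwbv(0, 0, 0), "positive")
})

test_that("group total effect equals mean difference and pooled t", {
  # hand-derived: young {0.2, 0.3}, old {0.4, 0.5}
  st <- subject_table(group = c(0, 0, 1, 1),
                      switch_cost = c(0.2, 0.3, 0.4, 0.5))
  r <- group_total_effect(st)
  expect_equal(r$beta, 0.2)
  expect_equal(r$t, 0.2 / sqrt(0.005 * (1 / 2 + 1 / 2)))
  expect_equal(r$df, 2)
  # identical groups
  st0 <- subject_table(group = c(0, 0, 1, 1),
                       switch_cost = c(0.1, 0.3, 0.1, 0.3))
  r0 <- group_total_effect(st0)
  expect_equal(r0$beta, 0)
  expect_equal(r0$t, 0)
  # property on random data: beta = mean difference, t = pooled two-sample t
  set.seed(42)
  for (i in 1:5) {
    g <- rep(c(0, 1), c(8, 11))
    p <- rnorm(19, 0.25, 0.1)
    rr <- group_total_effect(subject_table(group = g, switch_cost = p))
    expect_equal(rr$beta, mean(p[g == 1]) - mean(p[g == 0]))
    tt <- t.test(p[g == 1], p[g == 0], var.equal = TRUE)
    expect_equal(rr$t, unname(tt$statistic))
    expect_equal(rr$p, tt$p.value)
  }
})

test_that("covariate-adjusted total effect matches an lm oracle", {
  set.seed(7)
  st <- subject_table(group = rep(c(0, 1), c(12, 15)),
                      switch_cost = rnorm(27, 0.25, 0.1),
                      sex = rbinom(27, 1, 0.5),
                      nwbv = runif(27, 0.7, 0.85))
  r <- group_total_effect(st, with_covariates = TRUE)
  m <- lm(switch_cost ~ group + scale(sex) + scale(nwbv), st)
  expect_equal(r$beta, unname(coef(m)["group"]))
  expect_equal(r$t, unname(summary(m)$coefficients["group", "t value"]))
  expect_equal(r$df, m$df.residual)
})

test_that("rank-deficient designs fail naming the collinear column", {
  st <- subject_table(group = rep(c(0, 1), each = 4),
                      switch_cost = rnorm(8, 0.25, 0.05),
                      sex = rep(1, 8), nwbv = runif(8, 0.7, 0.8))
  expect_error(group_total_effect(st, with_covariates = TRUE), "sex")
})

test_that("Levene test matches brute-force ANOVA on absolute deviations", {
  st <- subject_table(group = c(0, 0, 0, 0, 0, 1, 1, 1, 1),
                      switch_cost = c(0, 0, 2, 2, 3, 1, 1, 1, 2))
  r <- levene_test(st)
  dev <- abs(st$switch_cost - ave(st$switch_cost, st$group))
  a <- anova(lm(dev ~ factor(st$group)))
  expect_equal(r$F, a$`F value`[1])
  expect_equal(r$p, a$`Pr(>F)`[1])
  expect_equal(c(r$df1, r$df2), a$Df)
})

test_that("Levene test agrees with car::leveneTest for both centers", {
  skip_if_not_installed("car")
  set.seed(11)
  st <- subject_table(group = rep(c(0, 1), c(20, 30)),
                      switch_cost = c(rnorm(20, 0.22, 0.08),
                                      rnorm(30, 0.30, 0.15)))
  for (ctr in c("mean", "median")) {
    r <- levene_test(st, center = ctr)
    cv <- car::leveneTest(st$switch_cost, factor(st$group), center = ctr)
    expect_equal(r$F, cv$`F value`[1])
    expect_equal(r$p, cv$`Pr(>F)`[1])
  }
})

test_that("Levene handles degenerate and unequal-spread groups", {
  # both groups constant: F = 0, not an error
  st0 <- subject_table(group = c(0, 0, 1, 1), switch_cost = c(1, 1, 2, 2))
  expect_equal(levene_test(st0)$F, 0)
  # {-1, 1} vs {-2, 2}: deviations {1,1} vs {2,2}, zero within-group spread
  st1 <- subject_table(group = c(0, 0, 1, 1), switch_cost = c(-1, 1, -2, 2))
  r1 <- levene_test(st1)
  expect_true(is.infinite(r1$F) && r1$F > 0)
})

test_that("subject and trial tables round-trip through TSV", {
  st <- subject_table(group = c(0, 1, 1), switch_cost = c(0.2, 0.3, 0.25),
                      sex = c(0, 1, 0), nwbv = c(0.8, 0.75, 0.77))
  f <- tempfile(fileext = ".tsv")
  write_subject_table(st, f)
  expect_equal(read_subject_table(f), st)
  tr <- generate_trials(0.1, seed = 3)
  f2 <- tempfile(fileext = ".tsv")
  write_trials(tr, f2)
  expect_equal(read_trials(f2), tr, tolerance = 1e-12)
})
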