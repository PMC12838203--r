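test_that("defection rates count defect choices per condition cell", {
  tr <- make_count_trials()
  r <- defection_rates(tr)
  expect_equal(r$p_def_U, 0.5)
  expect_equal(r$p_def_D, 0.75)
  expect_equal(r$p_def_C, 0.25)
  # all-defect subject
  tr2 <- tr; tr2$choice <- "defect"
  expect_equal(unlist(defection_rates(tr2)[, -1], use.names = FALSE),
               c(1, 1, 1))
  # random table vs a hand count
  set.seed(31)
  tr3 <- data.frame(subject_id = "A",
                    condition = sample(c("U", "D", "C"), 30, TRUE),
                    choice = sample(c("defect", "cooperate"), 30, TRUE),
                    rt = runif(30, 0.4, 2))
  r3 <- defection_rates(tr3)
  hand <- sum(tr3$choice == "defect" & tr3$condition == "D") /
    sum(tr3$condition == "D")
  expect_equal(r3$p_def_D, hand)
  # a subject missing a condition is dropped with a warning
  expect_warning(r4 <- defection_rates(tr3[tr3$condition != "C" |
                                             tr3$subject_id != "A", ]),
                 "dropping")
  expect_equal(nrow(r4), 0L)
})

test_that("EOD identity holds exactly, including the published group means", {
  expect_equal(eod(0.5, 0.5, 0.5), 0)
  # per-subject identity EOD = [(p_D - p_U) + (p_C - p_U)] / 2
  set.seed(8)
  pu <- runif(20); pd <- runif(20); pc <- runif(20)
  expect_equal(eod(pd, pc, pu), ((pd - pu) + (pc - pu)) / 2,
               tolerance = 1e-15)
  # published group variation means reproduce the published EODs
  expect_equal(eod(0.085, -0.007), 0.039)
  expect_equal(eod(0.178, 0.072), 0.125)
})

test_that("repeated-measures ANOVA matches a brute-force SS decomposition", {
  set.seed(99)
  y <- matrix(rnorm(24, mean = rep(c(0, 0.4, 0.1), each = 8)), ncol = 3)
  res <- rm_anova(y, gg = "off")
  # independent oracle: explicit sums
  n <- 8; k <- 3
  gm <- mean(y)
  ss_cond <- 0; ss_subj <- 0; ss_tot <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(y[, j]) - gm)^2
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(y[i, ]) - gm)^2
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (y[i, j] - gm)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  F_hand <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$F, F_hand, tolerance = 1e-12)
  expect_equal(res$partial_eta_sq, ss_cond / (ss_cond + ss_err),
               tolerance = 1e-12)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 14)
  # cross-check against stats::aov
  dat <- data.frame(y = as.vector(y),
                    cond = factor(rep(1:3, each = n)),
                    subj = factor(rep(1:n, 3)))
  aov_tab <- summary(stats::aov(y ~ cond + Error(subj), dat))
  F_aov <- aov_tab[["Error: Within"]][[1]]["cond", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-10)
})

test_that("ANOVA edge cases: identical columns, epsilon bounds, k = 2 identity", {
  set.seed(5)
  base <- rnorm(10)
  same <- cbind(base, base, base)
  res <- rm_anova(same, gg = "off")
  expect_equal(res$F, 0)
  expect_true(res$degenerate)
  # k = 2: F equals the squared paired t
  y2 <- cbind(rnorm(12), rnorm(12, 0.5))
  res2 <- rm_anova(y2, gg = "off")
  t2 <- t.test(y2[, 1], y2[, 2], paired = TRUE)$statistic
  expect_equal(res2$F, unname(t2)^2, tolerance = 1e-10)
  # GG epsilon within its theoretical bounds; within-subject centering invariance
  y3 <- matrix(rnorm(60), ncol = 3)
  r3 <- rm_anova(y3)
  expect_gte(r3$gg_epsilon, 0.5)
  expect_lte(r3$gg_epsilon, 1)
  r3b <- rm_anova(y3 + rnorm(20), gg = "off")
  expect_equal(rm_anova(y3, gg = "off")$F, r3b$F, tolerance = 1e-10)
})

test_that("GG correction multiplies both degrees of freedom by epsilon", {
  set.seed(17)
  y <- matrix(rnorm(45), ncol = 3)
  on_ <- rm_anova(y, gg = "on")
  off_ <- rm_anova(y, gg = "off")
  expect_equal(on_$df1, off_$df1 * on_$gg_epsilon)
  expect_equal(on_$df2, off_$df2 * on_$gg_epsilon)
  expect_equal(on_$F, off_$F)  # F itself is unchanged
})

test_that("Bonferroni pairwise tests multiply p by the comparison count", {
  set.seed(4)
  y <- matrix(rnorm(36), ncol = 3)
  pw <- bonferroni_pairwise(y)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_bonferroni, pmin(1, 3 * pw$p))
  # against the textbook paired-t formula by explicit sums
  d <- y[, 1] - y[, 2]
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(pw$t[1], t_hand, tolerance = 1e-12)
  expect_equal(pw$df[1], 11)
  # identical columns: t = 0; zero-variance nonzero difference flagged
  pw0 <- bonferroni_pairwise(cbind(y[, 1], y[, 1]))
  expect_equal(pw0$t, 0)
  pw1 <- bonferroni_pairwise(cbind(1:12, 2:13))
  expect_true(pw1$zero_variance)
  expect_true(is.infinite(pw1$t))
})

test_that("summary t statistics reproduce the published values", {
  # M = SD with n = 12 gives t = sqrt(12)
  expect_equal(t_from_summary(0.167, 0.167, 12)$t, sqrt(12))
  # published group-level paired t values from their printed M, SD, n
  expect_equal(t_from_summary(-0.060, 0.099, 12)$t, -2.101, tolerance = 0.01)
  expect_equal(t_from_summary(-0.147, 0.080, 48)$t, -12.789,
               tolerance = 0.005)
  expect_equal(t_from_summary(0, 1, 10)$t, 0)
  expect_true(t_from_summary(0.5, 0, 10)$flagged)
})

test_that("logit transform is monotone, centered, and flags boundary values", {
  expect_equal(logit_transform(0.5), 0)
  z <- c(0.2, 0.35, 0.6, 0.81)
  expect_equal(order(logit_transform(z)), order(z))
  expect_equal(logit_transform(z), log(z / (1 - z)))
  expect_warning(lt <- logit_transform(c(0, 0.5, 1)), "clamped")
  expect_true(all(is.finite(lt)))
  expect_error(logit_transform(1.2), "outside")
  # ANOVA on raw and logit bias agrees in pairwise sign pattern on
  # generator-style cohorts
  set.seed(12)
  zmat <- cbind(U = runif(30, 0.4, 0.6), D = runif(30, 0.25, 0.45),
                C = runif(30, 0.4, 0.6))
  raw <- rm_anova(zmat, gg = "off")$pairwise
  trans <- rm_anova(apply(zmat, 2, logit_transform), gg = "off")$pairwise
  expect_equal(sign(raw$t), sign(trans$t))
})
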