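make_cohort <- function(n, b = c(da = 0, dv = 0.6, dz = -0.8),
                        noise = 0.3, seed = 1) {
  with_seed_local(seed, {
    X <- matrix(rnorm(3 * n), ncol = 3,
                dimnames = list(NULL, c("da", "dv", "dz")))
    y <- drop(X %*% b) + rnorm(n, sd = noise)
    list(X = X, y = y)
  })
}

test_that("variation regression recovers exact and planted structure", {
  set.seed(2)
  da <- rnorm(40); dv <- rnorm(40); dz <- rnorm(40)
  # outcome = -dz exactly: beta_z = -1, R^2 = 1
  r <- variation_regression(-dz, da, dv, dz)
  expect_equal(unname(r$beta["dz"]), -1, tolerance = 1e-10)
  expect_equal(abs(unname(r$beta[c("da", "dv")])), c(0, 0),
               tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  # permutation invariance
  perm <- sample(40)
  r2 <- variation_regression(-dz[perm], da[perm], dv[perm], dz[perm])
  expect_equal(r$beta, r2$beta, tolerance = 1e-12)
  # planted coefficients recovered within 3 SE
  co <- make_cohort(200, seed = 7)
  rr <- variation_regression(co$y, co$X[, 1], co$X[, 2], co$X[, 3])
  perm2 <- sample(200)
  rr2 <- variation_regression(co$y[perm2], co$X[perm2, 1], co$X[perm2, 2],
                              co$X[perm2, 3])
  expect_equal(rr$F, rr2$F, tolerance = 1e-9)
  expect_equal(rr$beta, rr2$beta, tolerance = 1e-12)
  b_std <- c(0, 0.6, -0.8) / sd(co$y) * apply(co$X, 2, sd)
  expect_true(all(abs(rr$beta - b_std) < 3 * rr$se))
  # collinearity guard
  expect_error(variation_regression(co$y, co$X[, 1], co$X[, 1], co$X[, 3]),
               "collinear")
  expect_error(variation_regression(1:5, 1:5, 2:6, 3:7), ">= 10")
})

test_that("PMVD equals squared-correlation shares for orthogonal predictors", {
  # orthogonal design columns: shares must equal r_j^2 / R^2 and match LMG
  n <- 48
  X <- cbind(x1 = rep(c(-1, 1), n / 2),
             x2 = rep(c(-1, -1, 1, 1), n / 4),
             x3 = rep(c(-1, 1, 1, -1), n / 4))
  y <- drop(X %*% c(0.5, 0.3, -0.2)) + with_seed_local(3, rnorm(n, sd = 0.4))
  pm <- pmvd_shares(X, y)
  lm_ <- lmg_shares(X, y)
  r2j <- drop(cor(X, y))^2
  expect_equal(unname(pm$shares), unname(r2j / sum(r2j)), tolerance = 1e-10)
  expect_equal(pm$shares, lm_$shares, tolerance = 1e-10)
})

test_that("PMVD matches a brute-force enumeration with explicit weights", {
  co <- make_cohort(60, seed = 11)
  pm <- pmvd_shares(co$X, co$y)
  # independent oracle: subset R^2 via lm(), all 6 orderings, explicit
  # reciprocal-remaining-variance weights
  r2 <- function(cols) summary(stats::lm(co$y ~ co$X[, cols]))$r.squared
  full <- r2(1:3)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  L <- numeric(6); contrib <- matrix(0, 6, 3)
  for (r in 1:6) {
    ord <- perms[r, ]
    prev <- 0
    w <- 1
    for (i in 1:3) {
      cur <- r2(sort(ord[1:i]))
      contrib[r, ord[i]] <- cur - prev
      if (i < 3) w <- w / (full - cur)
      prev <- cur
    }
    L[r] <- w
  }
  wts <- L / sum(L)
  oracle <- drop(crossprod(wts, contrib)) / full
  expect_equal(unname(pm$shares), oracle, tolerance = 1e-10)
  # shares are a decomposition of R^2
  expect_equal(sum(pm$raw), pm$r_squared, tolerance = 1e-10)
  expect_equal(sum(pm$shares), 1, tolerance = 1e-10)
  expect_true(all(pm$shares > -1e-12))
  # invariance to predictor rescaling
  pm2 <- pmvd_shares(sweep(co$X, 2, c(10, 0.1, 3), "*"), co$y)
  expect_equal(unname(pm2$shares), unname(pm$shares), tolerance = 1e-9)
})

test_that("PMVD excludes a zero-coefficient predictor as n grows", {
  co <- make_cohort(10000, b = c(da = 0, dv = 0.6, dz = -0.8), seed = 13)
  pm <- pmvd_shares(co$X, co$y)
  lm_ <- lmg_shares(co$X, co$y)
  expect_lt(pm$shares[["da"]], 0.005)       # exclusion property
  expect_gt(lm_$shares[["da"]], pm$shares[["da"]])  # LMG does not exclude
})

test_that("LMG has its closed form for two predictors", {
  with_seed_local(19, {
    X <- matrix(rnorm(120), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
    y <- X[, 1] * 0.7 + X[, 2] * 0.2 + rnorm(60, sd = 0.5)
  })
  lm_ <- lmg_shares(X, y)
  r2 <- function(cols) summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
  full <- r2(1:2)
  # average of the two orderings' sequential contributions
  s1 <- (r2(1) + (full - r2(2))) / 2
  expect_equal(lm_$raw[["x1"]], s1, tolerance = 1e-12)
  expect_equal(lm_$raw[["x2"]], full - s1, tolerance = 1e-12)
})

test_that("a null boundary-variation predictor gets the smallest share", {
  # cohorts mimicking the decomposition table's structure: strong drift and
  # bias effects, null boundary effect
  smallest <- vapply(1:40, function(s) {
    co <- make_cohort(72, b = c(da = 0, dv = 0.6, dz = -0.8), noise = 0.35,
                      seed = 400 + s)
    pm <- pmvd_shares(co$X, co$y)
    which.min(pm$shares) == 1
  }, logical(1))
  expect_gte(mean(smallest), 0.95)
})

test_that("degenerate outcomes are flagged", {
  X <- matrix(rnorm(60), ncol = 3)
  w <- testthat::capture_warnings(pm <- pmvd_shares(X, rep(1, 20)))
  expect_true(any(grepl("undefined", w)))
  expect_true(all(is.na(pm$shares)))
})
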