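test_that("QP summary quantiles match hand-computed order statistics", {
  # RTs 1..100: type-7 interpolation at p gives 1 + 99 p exactly
  tr <- data.frame(condition = "U", choice = "defect", rt = sample(1:100))
  qp <- compute_qp(tr, probs = c(0.1, 0.5, 0.9))
  def <- qp[qp$response == "defect", ]
  expect_equal(as.numeric(def[, c("q10", "q50", "q90")]),
               c(10.9, 50.5, 90.1))
  expect_equal(def$proportion, 1)
  expect_equal(def$n, 100L)
  # identical RTs: every quantile equals that RT
  tr2 <- data.frame(condition = "U", choice = "defect", rt = rep(0.7, 10))
  qp2 <- compute_qp(tr2)
  expect_true(all(qp2[qp2$response == "defect",
                      paste0("q", c(10, 30, 50, 70, 90))] == 0.7))
  # all-defect condition: cooperate cell empty and flagged
  coop <- qp2[qp2$response == "cooperate", ]
  expect_equal(coop$proportion, 0)
  expect_true(coop$degraded)
  expect_true(all(is.na(coop[, paste0("q", c(10, 30, 50, 70, 90))])))
  expect_error(compute_qp(tr[0, ]), "empty")
})

test_that("QP chi-square is zero when observed counts equal model-implied masses", {
  # v = 0, z = 0.5 makes P(defect) exactly 1/2, so with 40 trials the
  # expected bin counts (2,4,4,4,4,2) per response are integers; placing
  # observations at predicted bin midpoints reproduces them exactly.
  p <- ddm_params(0, 1.5, 0.5, t_er = 0.3)
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mid_probs <- c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95)
  counts <- c(2, 4, 4, 4, 4, 2)
  mids <- rt_quantiles(p, mid_probs, "defect")  # symmetric: same for both
  rts <- rep(mids, counts)
  tr <- data.frame(condition = "U",
                   choice = rep(c("defect", "cooperate"), each = 20),
                   rt = c(rts, rts))
  stat <- qp_chisq(compute_qp(tr, probs), list(U = p))
  expect_equal(stat, 0, tolerance = 1e-10)
})

test_that("QP chi-square is linear in trial counts", {
  tr <- make_subject_trials(n = 40, seed = 300)
  params <- list(U = ddm_params(0.4, 1.5, 0.50, 0.35),
                 D = ddm_params(0.55, 1.5, 0.353, 0.35),
                 C = ddm_params(0.55, 1.5, 0.49, 0.35))
  s1 <- qp_chisq(compute_qp(tr), params)
  s2 <- qp_chisq(compute_qp(rbind(tr, tr)), params)
  expect_gt(s1, 0)
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
})

test_that("QP chi-square discriminates the true model from a wrong-bias model", {
  p_true <- ddm_params(0.5, 1.5, 0.45, 0.3)
  p_wrong <- ddm_params(0.5, 1.5, 0.60, 0.3)
  wins <- vapply(1:100, function(r) {
    sim <- simulate_trials(p_true, 200, dt = 1e-3, seed = 5000 + r)
    tr <- data.frame(condition = "U", choice = as.character(sim$choice),
                     rt = sim$rt)
    qp <- compute_qp(tr)
    qp_chisq(qp, list(U = p_wrong)) > qp_chisq(qp, list(U = p_true))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("QP chi-square validates its inputs", {
  tr <- make_subject_trials(n = 20, seed = 44)
  qp <- compute_qp(tr)
  mismatched <- list(U = ddm_params(0, 1, 0.5, 0.3),
                     D = ddm_params(0, 1, 0.5, 0.4),
                     C = ddm_params(0, 1, 0.5, 0.3))
  expect_error(qp_chisq(qp, mismatched), "share one t_er")
  expect_error(qp_chisq(qp, list(U = ddm_params(0, 1, 0.5))), "cover")
})

test_that("subject fits are deterministic under a fixed seed", {
  tr <- make_subject_trials(n = 20, seed = 70)
  ctl <- de_control(pop_factor = 5, maxiter = 12)
  f1 <- fit_subject(tr, control = ctl, seed = 31)
  f2 <- fit_subject(tr, control = ctl, seed = 31)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective, f2$objective)
  expect_equal(length(f1$params), 3L)
  expect_named(f1$params, c("U", "D", "C"))
  # shared non-decision time across the three conditions
  ters <- vapply(f1$params, function(p) p$t_er, numeric(1))
  expect_equal(unname(diff(range(ters))), 0)
  expect_true(f1$t_er < min(tr$rt))
})

test_that("zero response variability warns and widens bias bounds, not fails", {
  tr <- make_subject_trials(n = 15, seed = 80)
  tr$choice[tr$condition == "D"] <- "defect"
  expect_warning(
    fit <- fit_subject(tr, control = de_control(pop_factor = 5, maxiter = 4),
                       seed = 9),
    "zero response variability")
  expect_s3_class(fit, "subject_fit")
  expect_error(fit_subject(tr[tr$condition != "C", ],
                           control = de_control(pop_factor = 5, maxiter = 2),
                           seed = 1),
               ">= 10 trials")
})

test_that("fit report tabulates observed vs predicted quantiles per cell", {
  tr <- make_subject_trials(n = 30, seed = 90)
  fit <- fit_subject(tr, control = de_control(pop_factor = 6, maxiter = 25),
                     seed = 17)
  rep <- fit_report(fit, tr)
  expect_true(all(rep$condition %in% c("U", "D", "C")))
  expect_lte(nrow(rep) / 5, 6)  # at most 3 conditions x 2 responses
  expect_true(all(c("observed", "predicted", "prob", "n") %in% names(rep)))
  # predicted quantiles increase within every cell
  for (key in unique(paste(rep$condition, rep$response))) {
    sub <- rep[paste(rep$condition, rep$response) == key, ]
    expect_true(all(diff(sub$predicted) > 0))
  }
})

test_that("differential evolution never worsens the best member and converges on a smooth bowl", {
  sphere <- function(m) rowSums((m - 0.3)^2)
  res <- disjunctDDM:::de_optimize(sphere, lower = rep(-2, 4), upper = rep(2, 4),
                     control = de_control(pop_factor = 10, maxiter = 200,
                                          tol = 1e-10), seed = 5)
  expect_true(res$converged)
  expect_equal(res$par, rep(0.3, 4), tolerance = 1e-3)
  # elitist contract: rerunning with more generations never increases the optimum
  res2 <- disjunctDDM:::de_optimize(sphere, lower = rep(-2, 4), upper = rep(2, 4),
                      control = de_control(pop_factor = 10, maxiter = 30,
                                           tol = 0), seed = 5)
  expect_gte(res2$value, res$value)
})
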