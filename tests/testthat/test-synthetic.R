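test_that("payoff generation respects the PD ordering and the prototype", {
  proto <- default_payoff_prototype()
  expect_true(proto$T > proto$R && proto$R > proto$P && proto$P > proto$S)
  m <- generate_payoff_matrices(proto, jitter = 10, n = 150, seed = 1)
  expect_equal(nrow(m), 150L)
  expect_true(all(m$T > m$R & m$R > m$P & m$P > m$S))
  expect_identical(m, generate_payoff_matrices(proto, 10, 150, seed = 1))
  # zero jitter reproduces the prototype exactly
  m0 <- generate_payoff_matrices(proto, jitter = 0, n = 5, seed = 2)
  expect_true(all(m0$T == proto$T & m0$S == proto$S))
  # an invalid prototype is rejected outright
  expect_error(
    generate_payoff_matrices(list(T = 3, R = 4, P = 2, S = 1), jitter = 10,
                             n = 50, seed = 3),
    "prototype")
})

test_that("payoff gap summary is additive and matches simulated prototypes", {
  m <- generate_payoff_matrices(jitter = 0, n = 5, seed = 4)
  gs <- payoff_gap_summary(m)
  expect_equal(gs$sd, rep(0, 4))
  proto <- default_payoff_prototype()
  expect_equal(gs$mean, c(proto$T - proto$R, proto$R - proto$P,
                          proto$P - proto$S, proto$T - proto$S))
  # additivity of means is an identity
  m2 <- generate_payoff_matrices(jitter = 10, n = 150, seed = 5)
  gs2 <- payoff_gap_summary(m2)
  expect_equal(gs2$mean[4], sum(gs2$mean[1:3]), tolerance = 1e-12)
  # across seeds, mean gaps track the prototype gaps
  means <- t(vapply(1:40, function(s)
    payoff_gap_summary(generate_payoff_matrices(jitter = 10, n = 150,
                                                seed = 100 + s))$mean,
    numeric(4)))
  avg <- colMeans(means)
  se <- apply(means, 2, sd) / sqrt(40)
  proto_gaps <- c(19, 12, 18, 49)
  # rejection of inverted orderings pushes gaps slightly above the prototype
  expect_true(all(abs(avg - proto_gaps) < pmax(3 * se, 1.5)))
  expect_error(payoff_gap_summary(m2[1, ]), ">= 2")
})

test_that("generated populations encode the configured group structure", {
  cfg <- group_param_defaults()
  # degenerate SDs: every subject carries exactly its group means
  cfg0 <- cfg
  cfg0[grep("_sd$", names(cfg0))] <- 0
  pop0 <- generate_population(30, config = cfg0, seed = 6)
  for (g in cfg0$group) {
    sub <- pop0[pop0$group == g, ]
    row <- cfg0[cfg0$group == g, ]
    expect_equal(unique(sub$z_U), row$z_U_mean)
    expect_equal(unique(round(sub$z_D - sub$z_U, 10)), row$dz_D_mean)
    expect_equal(unique(sub$a), row$a_mean)
  }
  expect_identical(generate_population(20, seed = 7),
                   generate_population(20, seed = 7))
  expect_error(generate_population(4, seed = 8), "degenerate")
})

test_that("default cohorts show the condition-level parameter pattern", {
  # z_D < z_U, z_C ~ z_U, v_U < min(v_D, v_C) at the sample level
  hits <- vapply(1:100, function(s) {
    pop <- generate_population(72, seed = 2000 + s)
    mz <- colMeans(pop[, c("z_U", "z_D", "z_C")])
    mv <- colMeans(pop[, c("v_U", "v_D", "v_C")])
    mz["z_D"] < mz["z_U"] && abs(mz["z_C"] - mz["z_U"]) < 0.05 &&
      mv["v_U"] < min(mv["v_D"], mv["v_C"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # intermediates carry the largest U->D bias drop by construction
  pop <- generate_population(72, seed = 42)
  dz <- tapply(pop$z_D - pop$z_U, pop$group, mean)
  expect_lt(dz[["intermediate"]], dz[["proself"]])
  expect_lt(dz[["intermediate"]], dz[["prosocial"]])
})

test_that("simulated experiments have the declared shape and RT floor", {
  pop <- generate_population(8, seed = 9)
  mats <- generate_payoff_matrices(jitter = 10, n = 150, seed = 10)
  tr <- generate_experiment(pop, mats, n_trials_per_condition = 20, seed = 11)
  expect_equal(nrow(tr), 8 * 3 * 20)
  expect_equal(as.vector(table(tr$condition)), rep(8L * 20L, 3))
  expect_true(all(tr$matrix_id %in% mats$id))
  ter <- pop$t_er[match(tr$subject_id, pop$subject_id)]
  expect_true(all(tr$rt_s > ter))
  expect_identical(tr, generate_experiment(pop, mats, 20, seed = 11))
})

test_that("defection is more frequent under D than U on average", {
  diffs <- vapply(1:40, function(s) {
    pop <- generate_population(10, seed = 3000 + s)
    mats <- generate_payoff_matrices(jitter = 10, n = 30, seed = 1)
    tr <- generate_experiment(pop, mats, 15, dt = 2e-3, seed = 4000 + s)
    rates <- defection_rates(tr)
    mean(rates$p_def_D - rates$p_def_U)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("QC filters flag planted deviant subjects and only them", {
  pop <- generate_population(6, seed = 12)
  mats <- generate_payoff_matrices(jitter = 10, n = 30, seed = 13)
  tr <- generate_experiment(pop, mats, 10, dt = 2e-3, seed = 14)
  # plant a fully consistent defector and a fast guesser
  consistent <- tr[tr$subject_id == "S001", ]
  consistent$subject_id <- "S998"
  consistent$choice <- "defect"
  guesser <- tr[tr$subject_id == "S002", ]
  guesser$subject_id <- "S999"
  guesser$rt_s <- ifelse(seq_len(nrow(guesser)) %% 5 == 0, 0.5, 0.15)
  tr2 <- rbind(tr, consistent, guesser)
  # planted consistent subject has share 1.0 > 0.98; fast guesser has only
  # 20% of RTs above the fast threshold < 50% required
  res <- apply_qc_filters(tr2, consistency_threshold = 0.98,
                          fast_rt_threshold_s = 0.2,
                          min_valid_fraction = 0.5)
  expect_setequal(res$exclusions$subject_id, c("S998", "S999"))
  expect_equal(res$exclusions$rule[res$exclusions$subject_id == "S998"],
               "response_consistency")
  expect_equal(res$exclusions$rule[res$exclusions$subject_id == "S999"],
               "fast_rt")
  expect_false(any(c("S998", "S999") %in% res$kept$subject_id))
  # permissive thresholds exclude nobody
  res0 <- apply_qc_filters(tr2, consistency_threshold = 1,
                           fast_rt_threshold_s = 0,
                           min_valid_fraction = 1e-9)
  expect_equal(nrow(res0$exclusions), 0L)
  expect_error(apply_qc_filters(tr2, consistency_threshold = 1.2), "range")
})
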