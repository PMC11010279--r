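test_that("pain classification follows the OKS-PS threshold", {
  expect_equal(classify_pain(c(0, 14, 15, 28)), c("CP", "CP", "NCP", "NCP"))
  expect_equal(classify_pain(10, threshold = 9), "NCP")
  expect_error(classify_pain(-1), "0..28")
  expect_error(classify_pain(29), "0..28")
})

test_that("transition matrices are estimated by row-wise relative frequency", {
  panel <- tiny_trial_panel()
  m <- estimate_transition_matrix(panel, 0, 12, missing_origin = "identity")
  expect_equal(unname(m["CP", ]), c(0.4, 0.6))
  expect_equal(unname(m["NCP", ]), c(0, 1))  # structural origin, identity row
  expect_equal(rowSums(m), c(CP = 1, NCP = 1))
  expect_error(estimate_transition_matrix(panel, 0, 12),
               "empty risk set.*NCP")
  # a patient missing the follow-up is excluded and counted
  m2 <- estimate_transition_matrix(panel[-11, ], 0, 12,
                                   missing_origin = "identity")
  expect_equal(attr(m2, "excluded"), 1)
  expect_equal(unname(attr(m2, "n_origin")["CP"]), 9)
})

test_that("estimated transition probabilities recover generating values", {
  cfg <- generator_config(n_trial = 2000)
  panel <- simulate_trial(cfg, seed = 101)
  for (arm in c("star", "usual_care")) {
    m <- estimate_transition_matrix(panel, 0, 12, arm = arm,
                                    missing_origin = "identity")
    k <- round(m["CP", "NCP"] * 2000)
    ci <- stats::binom.test(k, 2000)$conf.int
    truth <- cfg$trial_p_cp_to_ncp[[arm]]
    expect_gt(truth, ci[1])
    expect_lt(truth, ci[2])
  }
})

test_that("area-under-curve QALYs follow the trapezoid rule", {
  expect_equal(auc_qaly(0.5, 0.5, 0.5), 0.5)
  expect_equal(auc_qaly(0, 1, 0), 0.5)
  expect_equal(auc_qaly(0.2, 0.6, 0.8), 0.55)
  expect_equal(auc_qaly(-0.1, 0.3, 0.5), 0.25 * 0.2 + 0.25 * 0.8)
  expect_error(auc_qaly(0.5, 1.2, 0.5), "exceed 1")
})

test_that("baseline adjustment matches closed-form least squares", {
  # balanced groups: adjustment is a no-op
  qaly <- c(0.40, 0.50, 0.60, 0.45, 0.55, 0.65)
  base <- c(0.2, 0.4, 0.6, 0.2, 0.4, 0.6)
  grp <- rep(c("a", "b"), each = 3)
  adj <- adjust_qalys_for_baseline(qaly, base, grp)
  expect_equal(unname(adj), tapply(qaly, grp, mean), ignore_attr = TRUE)

  # known effects (0.46 vs 0.54) and baseline slope 0.5; oracle = normal
  # equations solved directly
  set.seed(42)
  n <- 400
  grp <- rep(c("a", "b"), each = n / 2)
  base <- stats::rnorm(n, mean = ifelse(grp == "a", 0.45, 0.55), sd = 0.1)
  qaly <- ifelse(grp == "a", 0.46, 0.54) + 0.5 * (base - 0.5) +
    stats::rnorm(n, sd = 0.05)
  adj <- adjust_qalys_for_baseline(qaly, base, grp)
  X <- cbind(1, grp == "b", base)
  beta <- solve(t(X) %*% X, t(X) %*% qaly)
  expect_equal(unname(adj[["a"]]), beta[1] + beta[3] * mean(base),
               tolerance = 1e-10)
  expect_equal(unname(adj[["b"]]), beta[1] + beta[2] + beta[3] * mean(base),
               tolerance = 1e-10)
  se_diff <- 2 * 0.05 / sqrt(n / 2)  # generous bound on the contrast SE
  expect_lt(abs((adj[["b"]] - adj[["a"]]) - 0.08), 2 * se_diff)

  # zero baseline effect: adjusted means track raw means
  set.seed(7)
  base0 <- stats::rnorm(n, 0.5, 0.1)
  qaly0 <- ifelse(grp == "a", 0.46, 0.54) + stats::rnorm(n, sd = 0.05)
  adj0 <- adjust_qalys_for_baseline(qaly0, base0, grp)
  expect_equal(unname(adj0), unname(tapply(qaly0, grp, mean)),
               tolerance = 0.01, ignore_attr = TRUE)

  expect_error(adjust_qalys_for_baseline(qaly, rep(0.5, n), grp), "singular")
  expect_error(adjust_qalys_for_baseline(1:3, 1:3 / 4, c("a", "a", "a")),
               "two groups")
})

test_that("utility projection steps reproduce the published anchored values", {
  expect_equal(popc_step(0.484, 0.465, 0.556), 0.571768, tolerance = 1e-6)
  expect_equal(popc_step(0.560, 0.539, 0.730), 0.742300, tolerance = 1e-6)
  # anchor equal to the cohort start returns the cohort end exactly,
  # for improving and declining steps alike
  expect_equal(popc_step(0.465, 0.465, 0.556), 0.556)
  expect_equal(popc_step(0.730, 0.730, 0.727), 0.727)
  expect_error(popc_step(0.5, 1.0, 0.9), "scale_max")
  expect_error(popc_step(1.2, 0.5, 0.6), "exceeds")
})

test_that("projection respects the scale ceiling", {
  # full health is absorbing under cohort improvement
  expect_equal(popc_step(1, 0.5, 0.7), 1)
  # and no on-scale input is ever projected above the ceiling
  set.seed(1)
  for (i in 1:50) {
    cur <- stats::runif(1, -0.2, 1)
    from <- stats::runif(1, 0.05, 0.95)
    to <- stats::runif(1, 0.05, 0.99)
    expect_lte(popc_step(cur, from, to), 1)
  }
})

test_that("anchored projections reproduce all four published QALY rows", {
  uc_cp <- c(0.465, 0.556, 0.607, 0.642, 0.698)
  uc_ncp <- c(0.539, 0.730, 0.727, 0.716, 0.702)
  rows <- list(
    list(anchor = 0.484, cohort = uc_cp,
         printed = c(0.484, 0.572, 0.621, 0.654, 0.708)),
    list(anchor = 0.560, cohort = uc_ncp,
         printed = c(0.560, 0.742, 0.739, 0.728, 0.714)),
    list(anchor = 0.477, cohort = uc_cp,
         printed = c(0.477, 0.566, 0.616, 0.650, 0.704)),
    list(anchor = 0.555, cohort = uc_ncp,
         printed = c(0.555, 0.739, 0.736, 0.725, 0.711)))
  for (r in rows) {
    proj <- popc_project(r$anchor, r$cohort)
    expect_equal(proj, r$printed, tolerance = 1e-3)
  }
  # identity path: anchoring at the cohort start reproduces the cohort
  expect_equal(popc_project(uc_cp[1], uc_cp), uc_cp)
  expect_equal(popc_project(uc_ncp[1], uc_ncp), uc_ncp)
})

test_that("cost projection applies cohort percent changes multiplicatively", {
  expect_equal(pct_change_project(100, c(100, 88, 91)), c(100, 88, 91))
  expect_equal(pct_change_project(200, c(100, 88)), c(200, 176))
  expect_equal(pct_change_project(50, c(100, 50, 25)), c(50, 25, 12.5))
  expect_error(pct_change_project(50, c(100, 0, 25)), "non-zero")
  # equivariance under rescaling of the anchor
  set.seed(3)
  for (i in 1:20) {
    cohort <- stats::runif(5, 10, 1000)
    anchor <- stats::runif(1, 10, 1000)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(pct_change_project(k * anchor, cohort),
                 k * pct_change_project(anchor, cohort), tolerance = 1e-12)
  }
})
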