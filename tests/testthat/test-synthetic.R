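small_cfg <- function(...) generator_config(n_trial = 150, n_cohort = 250, ...)

test_that("generated panels are deterministic under a seed", {
  cfg <- small_cfg()
  expect_identical(simulate_trial(cfg, seed = 5), simulate_trial(cfg, seed = 5))
  expect_identical(simulate_cohort(cfg, seed = 5), simulate_cohort(cfg, seed = 5))
  expect_false(identical(simulate_trial(cfg, seed = 5),
                         simulate_trial(cfg, seed = 6)))
})

test_that("generator validates its configuration", {
  expect_error(generator_config(trial_p_cp_to_ncp = c(star = 1.2,
                                                      usual_care = 0.5)),
               "\\[0,1\\]")
  expect_error(generator_config(oks_probs = list(CP = rep(1, 10),
                                                 NCP = rep(1, 14))),
               "threshold")
  expect_error(generator_config(missing_utility = 2), "probabilities")
})

test_that("zero noise makes utilities equal their state-conditional means", {
  cfg <- small_cfg(utility_sd = 0)
  panel <- simulate_trial(cfg, seed = 9)
  u0 <- panel$utility[panel$time_months == 0]
  expect_true(all(u0 == cfg$baseline_utility_mean))
  p12 <- panel[panel$time_months == 12, ]
  state <- classify_pain(p12$oks_ps)
  for (arm in c("star", "usual_care")) {
    sel <- p12$arm == arm
    expect_equal(p12$utility[sel],
                 unname(cfg$trial_utility_mean[[arm]][state[sel]]))
  }
})

test_that("OKS-PS scores identify the generating states exactly", {
  # supports are disjoint by construction, so classification recovers the
  # state that produced every score; with zero noise the utility mean
  # pins down the true state independently
  cfg <- small_cfg(utility_sd = 0)
  panel <- simulate_trial(cfg, seed = 30)
  p12 <- panel[panel$time_months == 12 & panel$arm == "star", ]
  truth <- ifelse(p12$utility == cfg$trial_utility_mean$star[["NCP"]],
                  "NCP", "CP")
  expect_identical(classify_pain(p12$oks_ps), truth)
})

test_that("trial state frequencies match the generating probabilities", {
  cfg <- generator_config(n_trial = 2000)
  panel <- simulate_trial(cfg, seed = 77)
  p12 <- panel[panel$time_months == 12 & panel$arm == "star", ]
  k <- sum(classify_pain(p12$oks_ps) == "NCP")
  ci <- stats::binom.test(k, 2000)$conf.int
  expect_gt(0.645, ci[1])
  expect_lt(0.645, ci[2])
})

test_that("cohort dynamics track the configured matrices", {
  cfg <- generator_config(n_cohort = 5000)
  panel <- simulate_cohort(cfg, seed = 13)
  y5 <- panel[panel$time_months == 60, ]
  frac_cp <- mean(classify_pain(y5$oks_ps) == "CP")
  # 0.0639 is the year-5 CP occupancy implied by the comparator matrices
  se <- sqrt(0.0639 * (1 - 0.0639) / 5000)
  expect_lt(abs(frac_cp - 0.0639), 3 * se)
})

test_that("an absorbing CP state retains the whole cohort", {
  absorbing <- lapply(1:5, function(t) transition_matrix(1, 1))
  cfg <- small_cfg(cohort_matrices = absorbing, cohort_initial_cp = 1)
  panel <- simulate_cohort(cfg, seed = 2)
  expect_true(all(panel$oks_ps <= 14))
})

test_that("full missingness removes every utility value", {
  cfg <- small_cfg(missing_utility = 1)
  expect_true(all(is.na(simulate_cohort(cfg, seed = 3)$utility)))
  expect_true(all(is.na(simulate_trial(cfg, seed = 3)$utility)))
})

test_that("the implied parameter set reproduces the fixture's comparator arm", {
  # generator defaults anchor the comparator at the built-in fixture, so the
  # infinite-sample parameters must reproduce its payoffs and dynamics
  imp <- implied_parameters(generator_config())
  fix <- star_parameters()
  expect_equal(imp$qalys$usual_care[, "CP"], fix$qalys$usual_care[, "CP"],
               tolerance = 1e-6)
  expect_equal(imp$costs$usual_care, fix$costs$usual_care, tolerance = 1e-9)
  expect_equal(imp$transitions$usual_care[[1]]["CP", "NCP"], 0.506)
  expect_equal(imp$transitions$star[2:5], fix$transitions$star[2:5])
  expect_equal(run_arm(imp, "usual_care")$total_costs,
               run_arm(fix, "usual_care")$total_costs, tolerance = 1e-9)
})
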