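test_that("default distributions are moment-matched to the point estimates", {
  p <- star_parameters()
  specs <- default_distributions(p, dispersion = 0.15)
  # a sampled probability: beta with sd = 0.15 * mean
  row <- specs[specs$target == "transition" & specs$arm == "usual_care" &
                 specs$year == 1 & specs$state == "CP", ]
  expect_equal(row$family, "beta")
  expect_equal(row$mean, 0.494)
  expect_equal(row$sd, 0.15 * 0.494, tolerance = 1e-9)
  expect_equal(row$par1 / (row$par1 + row$par2), 0.494, tolerance = 1e-9)
  v <- with(row, par1 * par2 / ((par1 + par2)^2 * (par1 + par2 + 1)))
  expect_equal(sqrt(v), row$sd, tolerance = 1e-9)

  # a cost: gamma with shape 1/cv^2 and scale mean * cv^2
  row <- specs[specs$target == "cost" & specs$arm == "usual_care" &
                 specs$year == 1 & specs$state == "CP" &
                 specs$component == "hospital", ]
  expect_equal(row$family, "gamma")
  expect_equal(row$par1, 1 / 0.15^2, tolerance = 1e-9)
  expect_equal(row$par2, 2972 * 0.15^2, tolerance = 1e-9)

  # structural zeros are never sampled
  zero <- specs[specs$target == "transition" & specs$year == 1 &
                  specs$state == "NCP", ]
  expect_true(all(zero$family == "fixed"))
  expect_true(all(zero$mean == 0))
  # every utility is beta-distributed
  expect_true(all(specs$family[specs$target == "qaly"] == "beta"))
})

test_that("sampled moments round-trip through the moment matching", {
  p <- star_parameters()
  specs <- default_distributions(p)
  set.seed(99)
  n <- 1e5
  for (idx in c(which(specs$family == "beta")[1],
                which(specs$family == "gamma")[1])) {
    s <- specs[idx, ]
    x <- if (s$family == "beta") {
      stats::rbeta(n, s$par1, s$par2)
    } else {
      stats::rgamma(n, shape = s$par1, scale = s$par2)
    }
    expect_lt(abs(mean(x) - s$mean), 3 * s$sd / sqrt(n))
    expect_lt(abs(stats::sd(x) - s$sd), 3 * s$sd / sqrt(n))
  }
})

test_that("PSA draws are reproducible and centred on the deterministic run", {
  p <- star_parameters()
  a <- run_psa(p, n = 300, seed = 21)
  b <- run_psa(p, n = 300, seed = 21)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, run_psa(p, n = 300, seed = 22)$draws))

  det <- run_model(p)$comparison
  mcse <- stats::sd(a$draws$delta_qalys) / sqrt(300)
  expect_lt(abs(mean(a$draws$delta_qalys) - det$delta_qalys), 3 * mcse)
})

test_that("a degenerate PSA reproduces the deterministic result every draw", {
  p <- star_parameters()
  specs <- default_distributions(p)
  specs$family <- "fixed"
  ps <- run_psa(p, specs, n = 5, seed = 1)
  det <- run_model(p)$comparison
  expect_equal(ps$draws$delta_qalys, rep(det$delta_qalys, 5), tolerance = 1e-12)
  expect_equal(ps$draws$delta_costs, rep(det$delta_costs, 5), tolerance = 1e-12)
})

test_that("the acceptability curve follows its definition and limits", {
  draws <- structure(list(n = 4, seed = 1, draws = data.frame(
    draw = 1:4,
    delta_qalys = c(0.1, 0.2, -0.1, 0.05),
    delta_costs = c(-100, 50, -20, 200))), class = "psa_draws")
  cc <- ceac(draws, c(0, 1000, 1e7))
  expect_equal(cc$probability[1], 0.5)            # fraction saving money
  expect_equal(cc$probability[3], 0.75)           # fraction gaining QALYs
  # uniform dominance: probability one at every threshold
  dom <- draws
  dom$draws$delta_qalys <- abs(dom$draws$delta_qalys)
  dom$draws$delta_costs <- -abs(dom$draws$delta_costs)
  expect_true(all(ceac(dom, seq(0, 50000, 500))$probability == 1))
  # non-decreasing whenever every draw gains QALYs
  set.seed(12)
  pos <- structure(list(draws = data.frame(
    delta_qalys = stats::runif(500, 0.001, 0.3),
    delta_costs = stats::rnorm(500, 0, 400))), class = "psa_draws")
  expect_true(all(diff(ceac(pos)$probability) >= 0))
})

test_that("the confidence ellipse attains its nominal coverage", {
  set.seed(4)
  n <- 10000
  x <- stats::rnorm(n, 0.08, 0.25)
  y <- 2000 * x + stats::rnorm(n, -500, 300)
  el <- confidence_ellipse(cbind(x, y), coverage = 0.95)
  inside <- mean(ellipse_contains(el, cbind(x, y)))
  expect_lt(abs(inside - 0.95), 2 * sqrt(0.95 * 0.05 / n))
  # boundary points satisfy the quadratic form
  bp <- ellipse_points(el, 400)
  d2 <- stats::mahalanobis(bp, el$centre, el$cov)
  expect_equal(d2, rep(stats::qchisq(0.95, 2), 400), tolerance = 1e-8)
})

test_that("ellipse geometry degenerates and errors sensibly", {
  set.seed(8)
  iso <- cbind(stats::rnorm(5000), stats::rnorm(5000))
  el <- confidence_ellipse(iso)
  expect_equal(el$radii[1], el$radii[2], tolerance = 0.1)
  el0 <- confidence_ellipse(iso, coverage = 1e-12)
  expect_lt(max(el0$radii), 1e-4)
  expect_error(confidence_ellipse(cbind(1:100, rep(2, 100))), "singular")
  expect_error(confidence_ellipse(cbind(1:2, 3:4)), "at least 3")
})
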