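moment_match_beta <- function(mean, sd, label = "parameter") {
  if (mean <= 0 || mean >= 1)
    stop(label, ": mean ", mean, " outside the open (0,1) support of the beta")
  cap <- sqrt(mean * (1 - mean))
  if (sd >= cap) sd <- 0.95 * cap  # keep the variance inside the beta bound
  nu <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

moment_match_gamma <- function(mean, sd, label = "parameter") {
  if (mean <= 0)
    stop(label, ": mean ", mean, " outside the positive support of the gamma")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

spec_row <- function(target, arm, year, state, component, mean, dispersion) {
  label <- paste(target, arm, year, state, component, sep = "/")
  bounded <- target %in% c("transition", "qaly")
  if ((bounded && (mean <= 0 || mean >= 1)) || (!bounded && mean <= 0)) {
    family <- "fixed"; sd <- 0; par1 <- mean; par2 <- 0  # structural constant
  } else if (bounded) {
    family <- "beta"; sd <- dispersion * mean
    p <- moment_match_beta(mean, sd, label)
    sd <- sqrt(p[1] * p[2] / ((p[1] + p[2])^2 * (p[1] + p[2] + 1)))
    par1 <- p[[1]]; par2 <- p[[2]]
  } else {
    family <- "gamma"; sd <- dispersion * mean
    p <- moment_match_gamma(mean, sd, label)
    par1 <- p[[1]]; par2 <- p[[2]]
  }
  data.frame(target = target, arm = arm, year = year, state = state,
             component = component, mean = mean, sd = sd, family = family,
             par1 = par1, par2 = par2)
}

#' Default sampling distributions for the probabilistic sensitivity analysis
#'
#' Assigns a distribution to every sampled model input, moment-matched to
#' its point estimate: beta for quantities bounded in (0,1) (transition
#' probabilities and per-state utilities) and gamma for non-negative costs,
#' each with standard deviation `dispersion * mean`. Two-state transition
#' rows are sampled through a single probability (the first entry of the
#' row) with the complement renormalising the row, which for two states is
#' equivalent to a Dirichlet. Structural constants are held fixed: rows
#' whose sampled probability is 0 or 1 (such as the year-1 NCP row), zero
#' costs, the one-off intervention cost, the discount rate and the horizon.
#'
#' The published analysis states only that appropriate distributions were
#' applied; its hyperparameters are in unpublished supplementary tables, so
#' here they are derived from the point estimates plus a configurable
#' dispersion.
#'
#' @param params A `star_params` object.
#' @param dispersion Coefficient of variation applied to every sampled mean
#'   (default 0.15). For beta parameters whose implied variance would leave
#'   the support, the standard deviation is capped just inside the bound.
#' @return Data frame of distribution specs (one row per sampled or fixed
#'   parameter) with columns `target`, `arm`, `year`, `state`, `component`,
#'   `mean`, `sd`, `family`, `par1`, `par2` (beta: shape1/shape2; gamma:
#'   shape/scale).
#' @export
default_distributions <- function(params, dispersion = 0.15) {
  stopifnot(dispersion > 0)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- spec_row(...)
  for (arm in unname(params$arms)) {
    for (t in seq_len(params$horizon)) {
      m <- params$transitions[[arm]][[t]]
      add("transition", arm, t, "CP", NA_character_, m["CP", "CP"], dispersion)
      add("transition", arm, t, "NCP", NA_character_, m["NCP", "CP"], dispersion)
      for (s in pain_states())
        add("qaly", arm, t, s, NA_character_, params$qalys[[arm]][t, s], dispersion)
      for (comp in cost_components())
        for (s in pain_states())
          add("cost", arm, t, s, comp, params$costs[[arm]][[comp]][t, s], dispersion)
    }
  }
  do.call(rbind, rows)
}

sample_spec <- function(spec, n) {
  switch(spec$family,
         fixed = rep(spec$mean, n),
         beta = stats::rbeta(n, spec$par1, spec$par2),
         gamma = stats::rgamma(n, shape = spec$par1, scale = spec$par2),
         stop("unknown distribution family: ", spec$family))
}

apply_draw <- function(params, specs, values) {
  tgt <- specs$target; arm <- specs$arm; year <- specs$year
  state <- specs$state; comp <- specs$component
  for (j in seq_along(values)) {
    v <- values[j]
    if (tgt[j] == "transition") {
      # row sampled as (p_to_CP, 1 - p_to_CP): complement renormalises the row
      params$transitions[[arm[j]]][[year[j]]][state[j], ] <- c(v, 1 - v)
    } else if (tgt[j] == "qaly") {
      params$qalys[[arm[j]]][year[j], state[j]] <- v
    } else {
      params$costs[[arm[j]]][[comp[j]]][year[j], state[j]] <- v
    }
  }
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' For each draw, samples every distribution spec independently, rebuilds
#' the parameter set (renormalising each two-state transition row via the
#' complement), runs both arms through the cohort engine, and records the
#' per-arm totals and the incremental pair (dQALY, dCost). A single RNG
#' stream is used, seeded once, with draws vectorised per parameter in a
#' stable order, so results are exactly reproducible for a given seed.
#'
#' @param params A `star_params` object.
#' @param specs Distribution specs from [default_distributions()].
#' @param n Number of draws (the published analysis used 10,000).
#' @param seed Integer seed.
#' @return Object of class `psa_draws`: list with `n`, `seed`, `draws`
#'   (data frame: `draw`, `delta_qalys`, `delta_costs`, per-arm totals) and
#'   the `specs` used.
#' @examples
#' p <- star_parameters()
#' ps <- run_psa(p, default_distributions(p), n = 25, seed = 1)
#' head(ps$draws)
#' @export
run_psa <- function(params, specs = default_distributions(params), n = 10000,
                    seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  sampled <- specs[specs$family != "fixed", , drop = FALSE]
  values <- matrix(0, nrow = n, ncol = nrow(sampled))
  for (j in seq_len(nrow(sampled)))
    values[, j] <- sample_spec(sampled[j, ], n)
  int <- unname(params$arms[["intervention"]])
  cmp <- unname(params$arms[["comparator"]])
  out <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, c("qi", "ci", "qc", "cc")))
  for (i in seq_len(n)) {
    p_i <- apply_draw(params, sampled, values[i, ])
    ri <- run_arm(p_i, int)
    rc <- run_arm(p_i, cmp)
    out[i, ] <- c(ri$total_qalys, ri$total_costs, rc$total_qalys, rc$total_costs)
  }
  draws <- data.frame(draw = seq_len(n),
                      delta_qalys = out[, "qi"] - out[, "qc"],
                      delta_costs = out[, "ci"] - out[, "cc"],
                      qalys_intervention = out[, "qi"],
                      costs_intervention = out[, "ci"],
                      qalys_comparator = out[, "qc"],
                      costs_comparator = out[, "cc"])
  structure(list(n = n, seed = seed, draws = draws, specs = specs),
            class = "psa_draws")
}

#' @export
print.psa_draws <- function(x, ...) {
  cat(sprintf("<psa_draws> %d draws (seed %d): mean dQALY %.4f, mean dCost £%.2f\n",
              x$n, x$seed, mean(x$draws$delta_qalys), mean(x$draws$delta_costs)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective: the fraction of draws with positive
#' incremental net benefit, `lambda * dQALY - dCost > 0`.
#'
#' @param draws A `psa_draws` object.
#' @param thresholds Ordered thresholds (GBP per QALY); default 0 to 50,000
#'   in steps of 500.
#' @return Data frame with columns `threshold` and `probability`.
#' @export
ceac <- function(draws, thresholds = seq(0, 50000, by = 500)) {
  dq <- draws$draws$delta_qalys
  dc <- draws$draws$delta_costs
  if (!length(dq)) stop("no draws")
  prob <- vapply(thresholds, function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Confidence ellipse on the cost-effectiveness plane
#'
#' Bivariate-normal ellipse for the cloud of (dQALY, dCost) draws: centred
#' at the sample mean, shaped by the sample covariance, and scaled by the
#' chi-square(2) quantile at the coverage level, so that under normality the
#' ellipse contains the stated fraction of draws.
#'
#' @param draws A `psa_draws` object, or a two-column matrix/data frame of
#'   (dQALY, dCost) pairs.
#' @param coverage Coverage level (default 0.95).
#' @return Object of class `ce_ellipse`: list with `centre`, `cov`, `radii`
#'   (semi-axes, major first), `angle` (radians of the major axis) and
#'   `coverage`.
#' @export
confidence_ellipse <- function(draws, coverage = 0.95) {
  xy <- if (inherits(draws, "psa_draws")) {
    cbind(draws$draws$delta_qalys, draws$draws$delta_costs)
  } else {
    as.matrix(draws)[, 1:2]
  }
  if (nrow(xy) < 3) stop("need at least 3 draws for an ellipse")
  S <- stats::cov(xy)
  if (!all(is.finite(S)) || det(S) <= 0)
    stop("singular covariance: draws do not span the plane")
  e <- eigen(S, symmetric = TRUE)
  k <- stats::qchisq(coverage, df = 2)
  structure(list(centre = colMeans(xy), cov = S,
                 radii = sqrt(pmax(e$values, 0) * k),
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 coverage = coverage),
            class = "ce_ellipse")
}

#' Boundary points of a confidence ellipse
#'
#' @param ellipse A `ce_ellipse` from [confidence_ellipse()].
#' @param n Number of boundary points.
#' @return An `n` x 2 matrix of (dQALY, dCost) boundary coordinates.
#' @export
ellipse_points <- function(ellipse, n = 200) {
  theta <- seq(0, 2 * pi, length.out = n)
  unit <- cbind(ellipse$radii[1] * cos(theta), ellipse$radii[2] * sin(theta))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(unit %*% t(rot), 2, ellipse$centre, `+`)
}

#' Which points fall inside a confidence ellipse
#'
#' @param ellipse A `ce_ellipse`.
#' @param points Two-column matrix of (dQALY, dCost) points.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  points <- as.matrix(points)
  d2 <- stats::mahalanobis(points, center = ellipse$centre, cov = ellipse$cov)
  d2 <= stats::qchisq(ellipse$coverage, df = 2)
}
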