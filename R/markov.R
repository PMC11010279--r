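#' Run the cohort trace of the two-state Markov model
#'
#' Propagates the cohort's state-membership fractions through one transition
#' matrix per year: membership at the end of year t is the membership at the
#' end of year t-1 left-multiplied by the year-t matrix, starting from the
#' initial distribution. Only end-of-cycle memberships are returned.
#'
#' @param initial_distribution Named numeric (`CP`, `NCP`) summing to 1.
#' @param matrices List of 2x2 transition matrices, one per year.
#' @param horizon Number of years (default: all matrices supplied).
#' @return A `horizon` x 2 matrix of end-of-cycle membership fractions with
#'   columns `CP`, `NCP`; rows sum to 1.
#' @examples
#' p <- star_parameters()
#' run_trace(p$initial_distribution, p$transitions$usual_care)[, "CP"]
#' @export
run_trace <- function(initial_distribution, matrices, horizon = length(matrices)) {
  if (length(matrices) < horizon)
    stop("need a transition matrix for every year 1..", horizon,
         "; got ", length(matrices))
  if (abs(sum(initial_distribution) - 1) > 1e-9)
    stop("initial distribution must sum to 1")
  m <- initial_distribution[pain_states()]
  trace <- matrix(NA_real_, nrow = horizon, ncol = 2,
                  dimnames = list(year = seq_len(horizon), state = pain_states()))
  for (t in seq_len(horizon)) {
    m <- as.numeric(m %*% matrices[[t]])
    trace[t, ] <- m
  }
  trace
}

#' Accrue discounted QALYs and costs along a cohort trace
#'
#' Payoffs are attributed by end-of-cycle state membership (no half-cycle
#' correction): the undiscounted value of year t is the membership-weighted
#' sum of that year's per-state payoffs. Costs in year 1 additionally include
#' any one-off cost at full, undiscounted value. Discounting starts from the
#' second year: the factor for year t is (1 + r)^-(t - 1), so year 1 is
#' undiscounted.
#'
#' @param trace Trace matrix from [run_trace()].
#' @param qalys Year-by-state matrix of per-cycle QALY payoffs.
#' @param costs Year-by-state matrix of per-cycle total costs (GBP).
#' @param discount_rate Annual discount rate (applied to both payoffs).
#' @param oneoff_year1_cost One-off cost added to year-1 costs (default 0).
#' @return An object of class `arm_result`: list with `cycles` (data frame of
#'   per-year undiscounted and discounted QALYs and costs), `total_qalys`,
#'   `total_costs` (discounted), and undiscounted totals.
#' @export
accrue <- function(trace, qalys, costs, discount_rate, oneoff_year1_cost = 0) {
  H <- nrow(trace)
  if (nrow(qalys) < H || nrow(costs) < H)
    stop("payoff schedules must cover all ", H, " years of the trace")
  st <- pain_states()
  q_undisc <- rowSums(trace * qalys[seq_len(H), st, drop = FALSE])
  c_undisc <- rowSums(trace * costs[seq_len(H), st, drop = FALSE])
  c_undisc[1] <- c_undisc[1] + oneoff_year1_cost
  dfac <- (1 + discount_rate)^-(seq_len(H) - 1)
  res <- list(
    cycles = data.frame(
      year = seq_len(H),
      qalys = q_undisc, costs = c_undisc,
      discount_factor = dfac,
      qalys_disc = q_undisc * dfac, costs_disc = c_undisc * dfac),
    total_qalys = sum(q_undisc * dfac),
    total_costs = sum(c_undisc * dfac),
    total_qalys_undisc = sum(q_undisc),
    total_costs_undisc = sum(c_undisc))
  class(res) <- "arm_result"
  res
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> total discounted QALYs %.4f, costs £%.2f over %d years\n",
              x$total_qalys, x$total_costs, nrow(x$cycles)))
  print(x$cycles, row.names = FALSE, digits = 5)
  invisible(x)
}

arm_total_costs <- function(params, arm) {
  Reduce(`+`, params$costs[[arm]])
}

#' Run one arm of the model
#'
#' Convenience wrapper: builds the trace from the arm's transition schedule,
#' sums the cost components, applies the one-off intervention cost (and the
#' `extra_arm_year1_cost` calibration knob) to the intervention arm only, and
#' accrues discounted payoffs.
#'
#' @param params A `star_params` object.
#' @param arm Arm identifier (one of `params$arms`).
#' @return An `arm_result`.
#' @export
run_arm <- function(params, arm) {
  arm <- match.arg(arm, unname(params$arms))
  oneoff <- if (identical(arm, unname(params$arms[["intervention"]]))) {
    params$intervention_cost + params$extra_arm_year1_cost
  } else 0
  trace <- run_trace(params$initial_distribution, params$transitions[[arm]],
                     params$horizon)
  accrue(trace, params$qalys[[arm]], arm_total_costs(params, arm),
         params$discount_rate, oneoff)
}

#' Run both arms and compare them
#'
#' @param params A `star_params` object.
#' @param threshold Willingness-to-pay threshold; defaults to the one stored
#'   in `params`.
#' @return List with per-arm `arm_result`s (named by arm) and `comparison`,
#'   a [compare_arms()] result.
#' @examples
#' run_model(star_parameters())$comparison
#' @export
run_model <- function(params, threshold = params$wtp_threshold) {
  int <- unname(params$arms[["intervention"]])
  cmp <- unname(params$arms[["comparator"]])
  arms <- stats::setNames(lapply(c(int, cmp), run_arm, params = params),
                          c(int, cmp))
  list(arms = arms,
       comparison = compare_arms(arms[[int]], arms[[cmp]], threshold))
}

#' Tidy export of a cohort trace
#'
#' @param trace Matrix from [run_trace()].
#' @param arm Arm label to attach.
#' @return Data frame with columns `arm`, `year`, `state`, `membership`.
#' @export
trace_as_df <- function(trace, arm) {
  data.frame(arm = arm,
             year = rep(seq_len(nrow(trace)), times = 2),
             state = rep(pain_states(), each = nrow(trace)),
             membership = c(trace[, "CP"], trace[, "NCP"]))
}
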