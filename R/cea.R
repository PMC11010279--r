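#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental QALYs and costs (intervention minus comparator), the
#' incremental net monetary benefit iNMB = threshold * dQALY - dCost, the
#' ICER where neither arm dominates, and the dominance classification:
#' `intervention_dominant` (more QALYs, lower cost), `comparator_dominant`
#' (fewer QALYs, higher cost), otherwise a trade-off in the north-east
#' (`trade_off_NE`: more QALYs at higher cost) or south-west
#' (`trade_off_SW`) quadrant of the cost-effectiveness plane. Positive iNMB
#' favours the intervention. The ICER is reported only for trade-offs and is
#' undefined (NA, with `icer_defined = FALSE`) when dQALY is zero.
#'
#' @param intervention,comparator `arm_result` objects from [run_arm()].
#' @param threshold Willingness-to-pay threshold (GBP per QALY).
#' @return Object of class `ce_result`: list with `delta_qalys`,
#'   `delta_costs`, `threshold`, `inmb`, `icer`, `icer_defined`, `dominance`.
#' @examples
#' m <- run_model(star_parameters())
#' m$comparison$dominance
#' @export
compare_arms <- function(intervention, comparator, threshold = 20000) {
  dq <- intervention$total_qalys - comparator$total_qalys
  dc <- intervention$total_costs - comparator$total_costs
  dominance <- if (dq > 0 && dc < 0) {
    "intervention_dominant"
  } else if (dq < 0 && dc > 0) {
    "comparator_dominant"
  } else if (dq >= 0 && dc >= 0) {
    "trade_off_NE"
  } else {
    "trade_off_SW"
  }
  trade_off <- dominance %in% c("trade_off_NE", "trade_off_SW")
  icer_defined <- trade_off && dq != 0
  structure(list(
    delta_qalys = dq, delta_costs = dc, threshold = threshold,
    inmb = threshold * dq - dc,
    icer = if (icer_defined) dc / dq else NA_real_,
    icer_defined = icer_defined,
    dominance = dominance), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> dQALY %.4f | dCost £%.2f | iNMB £%.2f at £%s/QALY\n",
              x$delta_qalys, x$delta_costs, x$inmb,
              format(x$threshold, big.mark = ",")))
  cat("  classification:", x$dominance,
      if (x$icer_defined) sprintf("(ICER £%.0f/QALY)", x$icer) else "", "\n")
  invisible(x)
}

#' National budget impact of rolling out the intervention
#'
#' Scales a per-patient saving up to an annual national cohort: the product
#' of the number of surgeries per year, the fraction who develop chronic
#' pain (and would be offered the intervention), and the expected per-patient
#' saving over the model horizon.
#'
#' @param annual_surgeries Number of knee replacements per year.
#' @param cp_rate Fraction developing chronic pain (0-1).
#' @param per_patient_saving Expected saving per treated patient (GBP).
#' @return Total saving (GBP) for one annual cohort.
#' @examples
#' budget_impact(100000, 0.20, 375)  # 7.5 million
#' @export
budget_impact <- function(annual_surgeries, cp_rate, per_patient_saving) {
  stopifnot(annual_surgeries >= 0, cp_rate >= 0, cp_rate <= 1,
            per_patient_saving >= 0)
  annual_surgeries * cp_rate * per_patient_saving
}

#' Year-1 cost needed to calibrate the intervention arm to a target total
#'
#' The intervention arm's published total cost carries a constant component
#' not reconstructable from the published per-state inputs. Because year-1
#' costs enter the total undiscounted, the gap between a target total and
#' the model's total is exactly the `extra_arm_year1_cost` that closes it.
#'
#' @param params A `star_params` object.
#' @param target_total_cost Target discounted total cost (GBP) for the
#'   intervention arm.
#' @return The additional year-1 cost (GBP); set it as
#'   `params$extra_arm_year1_cost` to reproduce the target.
#' @export
calibrate_extra_year1_cost <- function(params, target_total_cost) {
  base <- run_arm(params, unname(params$arms[["intervention"]]))
  target_total_cost - base$total_costs
}
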