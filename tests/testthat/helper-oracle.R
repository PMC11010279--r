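# Independent oracle: fully hand-unrolled 5-cycle recursion with explicit
# scalar arithmetic. Deliberately shares no code with run_trace()/accrue().
hand_unrolled_arm <- function(params, arm) {
  M <- params$transitions[[arm]]
  q <- params$qalys[[arm]]
  cst <- params$costs[[arm]]$prescriptions + params$costs[[arm]]$consultations +
    params$costs[[arm]]$hospital
  oneoff <- if (identical(arm, unname(params$arms[["intervention"]]))) {
    params$intervention_cost + params$extra_arm_year1_cost
  } else 0
  r <- params$discount_rate
  cp0 <- params$initial_distribution[["CP"]]
  ncp0 <- params$initial_distribution[["NCP"]]

  cp1 <- cp0 * M[[1]]["CP", "CP"] + ncp0 * M[[1]]["NCP", "CP"]
  ncp1 <- cp0 * M[[1]]["CP", "NCP"] + ncp0 * M[[1]]["NCP", "NCP"]
  cp2 <- cp1 * M[[2]]["CP", "CP"] + ncp1 * M[[2]]["NCP", "CP"]
  ncp2 <- cp1 * M[[2]]["CP", "NCP"] + ncp1 * M[[2]]["NCP", "NCP"]
  cp3 <- cp2 * M[[3]]["CP", "CP"] + ncp2 * M[[3]]["NCP", "CP"]
  ncp3 <- cp2 * M[[3]]["CP", "NCP"] + ncp2 * M[[3]]["NCP", "NCP"]
  cp4 <- cp3 * M[[4]]["CP", "CP"] + ncp3 * M[[4]]["NCP", "CP"]
  ncp4 <- cp3 * M[[4]]["CP", "NCP"] + ncp3 * M[[4]]["NCP", "NCP"]
  cp5 <- cp4 * M[[5]]["CP", "CP"] + ncp4 * M[[5]]["NCP", "CP"]
  ncp5 <- cp4 * M[[5]]["CP", "NCP"] + ncp4 * M[[5]]["NCP", "NCP"]

  qalys <-
    (cp1 * q[1, "CP"] + ncp1 * q[1, "NCP"]) +
    (cp2 * q[2, "CP"] + ncp2 * q[2, "NCP"]) / (1 + r) +
    (cp3 * q[3, "CP"] + ncp3 * q[3, "NCP"]) / (1 + r)^2 +
    (cp4 * q[4, "CP"] + ncp4 * q[4, "NCP"]) / (1 + r)^3 +
    (cp5 * q[5, "CP"] + ncp5 * q[5, "NCP"]) / (1 + r)^4
  costs <-
    (cp1 * cst[1, "CP"] + ncp1 * cst[1, "NCP"] + oneoff) +
    (cp2 * cst[2, "CP"] + ncp2 * cst[2, "NCP"]) / (1 + r) +
    (cp3 * cst[3, "CP"] + ncp3 * cst[3, "NCP"]) / (1 + r)^2 +
    (cp4 * cst[4, "CP"] + ncp4 * cst[4, "NCP"]) / (1 + r)^3 +
    (cp5 * cst[5, "CP"] + ncp5 * cst[5, "NCP"]) / (1 + r)^4
  list(total_qalys = qalys, total_costs = costs,
       cp_trace = c(cp1, cp2, cp3, cp4, cp5),
       mass = c(cp1 + ncp1, cp2 + ncp2, cp3 + ncp3, cp4 + ncp4, cp5 + ncp5))
}

# small hand-built panel: 10 patients all CP at month 0, 6 of them NCP at 12
tiny_trial_panel <- function() {
  ids <- sprintf("p%02d", 1:10)
  rbind(
    data.frame(patient_id = ids, arm = "a", time_months = 0,
               oks_ps = 10, utility = 0.4,
               cost_prescriptions = NA_real_, cost_consultations = NA_real_,
               cost_hospital = NA_real_),
    data.frame(patient_id = ids, arm = "a", time_months = 12,
               oks_ps = c(rep(20, 6), rep(8, 4)), utility = 0.6,
               cost_prescriptions = 10, cost_consultations = 20,
               cost_hospital = 30))
}
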