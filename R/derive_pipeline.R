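panel_columns <- function() {
  c("patient_id", "arm", "time_months", "oks_ps", "utility",
    "cost_prescriptions", "cost_consultations", "cost_hospital")
}

#' Read or validate a patient panel
#'
#' The panel dialect is a CSV with columns `patient_id`, `arm`,
#' `time_months`, `oks_ps`, `utility`, `cost_prescriptions`,
#' `cost_consultations`, `cost_hospital`; empty cells are allowed for the
#' optional utility and cost fields. Validation checks the OKS-PS range and
#' that each (patient, time) pair appears at most once, and reports the
#' offending row on failure.
#'
#' @param x Path to a CSV file, or a data frame.
#' @return The validated panel data frame.
#' @export
read_panel <- function(x) {
  panel <- if (is.character(x)) {
    if (!file.exists(x)) stop("panel file not found: ", x)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  missing_cols <- setdiff(panel_columns(), names(panel))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.na(panel$oks_ps) & (panel$oks_ps < 0 | panel$oks_ps > 28))
  if (length(bad))
    stop("row ", bad[1], ": OKS-PS score ", panel$oks_ps[bad[1]],
         " outside 0..28 (column oks_ps)")
  key <- paste(panel$patient_id, panel$time_months)
  if (anyDuplicated(key))
    stop("row ", which(duplicated(key))[1],
         ": duplicate (patient_id, time_months) pair")
  panel
}

#' Write a patient panel to CSV
#'
#' @param panel A panel data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(read_panel(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive a full parameter set from trial and cohort panels
#'
#' Runs the complete derivation chain on patient-level data:
#'
#' 1. Year-1 transition matrices per trial arm from paired baseline /
#'    12-month OKS-PS classifications (the NCP origin row is structural at
#'    baseline, where everyone is in CP, and is filled with the identity);
#'    years 2-5 from consecutive yearly cohort assessments, applied to both
#'    arms.
#' 2. Year-1 QALY anchors per arm and 12-month state: per-patient
#'    area-under-curve QALYs regression-adjusted for baseline utility
#'    ([adjust_qalys_for_baseline()] with arm-state groups), then projected
#'    through years 2-5 by the cohort's yearly utility means via
#'    [popc_project()].
#' 3. Year-1 cost anchors per arm, component and 12-month state from trial
#'    means, projected by the cohort's annual percent changes via
#'    [pct_change_project()].
#'
#' Patients with incomplete utility triplets are dropped from the QALY
#' regression; counts of exclusions are attached as attribute
#' `"exclusions"`.
#'
#' @param trial_panel Trial-like panel (see [simulate_trial()]).
#' @param cohort_panel Cohort-like panel (see [simulate_cohort()]).
#' @param arms Named arm identifiers (`intervention`, `comparator`) matching
#'   the trial panel's `arm` column.
#' @param intervention_cost One-off intervention cost (GBP, default 191).
#' @param oks_threshold Classification cut-point (default 14).
#' @param ... Passed to [parameter_set()] (discount rate, threshold, ...).
#' @return A validated `star_params` object.
#' @export
derive_parameters <- function(trial_panel, cohort_panel,
                              arms = c(intervention = "star",
                                       comparator = "usual_care"),
                              intervention_cost = 191,
                              oks_threshold = 14, ...) {
  trial <- read_panel(trial_panel)
  cohort <- read_panel(cohort_panel)
  exclusions <- list()

  later_years <- lapply(2:5, function(t)
    estimate_transition_matrix(cohort, 12 * (t - 1), 12 * t,
                               threshold = oks_threshold))
  transitions <- lapply(stats::setNames(unname(arms), unname(arms)), function(a) {
    y1 <- estimate_transition_matrix(trial, 0, 12, arm = a,
                                     threshold = oks_threshold,
                                     missing_origin = "identity")
    exclusions[[paste0("transitions_", a)]] <<- attr(y1, "excluded")
    c(list(y1), later_years)
  })

  # per-patient AUC QALYs, grouped by arm x 12-month state
  wide <- merge(
    merge(trial[trial$time_months == 0, c("patient_id", "arm", "utility")],
          trial[trial$time_months == 6, c("patient_id", "utility")],
          by = "patient_id", suffixes = c("_0", "_6")),
    trial[trial$time_months == 12, c("patient_id", "utility", "oks_ps")],
    by = "patient_id")
  complete <- stats::complete.cases(wide[c("utility_0", "utility_6", "utility")])
  exclusions$qaly_incomplete_utilities <- sum(!complete)
  wide <- wide[complete, ]
  wide$state12 <- classify_pain(wide$oks_ps, oks_threshold)
  wide$qaly <- auc_qaly(wide$utility_0, wide$utility_6, wide$utility)
  adj <- adjust_qalys_for_baseline(wide$qaly, wide$utility_0,
                                   paste(wide$arm, wide$state12, sep = "."))

  cohort_by <- function(value, year, state) {
    tapply(value, list(year, state), mean, na.rm = TRUE)
  }
  cy <- cohort[cohort$time_months > 0, ]
  cy$year <- cy$time_months / 12
  cy$state <- classify_pain(cy$oks_ps, oks_threshold)
  u_cohort <- cohort_by(cy$utility, cy$year, cy$state)

  qalys <- lapply(stats::setNames(unname(arms), unname(arms)), function(a) {
    anchor <- function(s) unname(adj[paste(a, s, sep = ".")])
    payoff_matrix(cp = popc_project(anchor("CP"), u_cohort[, "CP"]),
                  ncp = popc_project(anchor("NCP"), u_cohort[, "NCP"]))
  })

  t12 <- trial[trial$time_months == 12, ]
  t12$state12 <- classify_pain(t12$oks_ps, oks_threshold)
  costs <- lapply(stats::setNames(unname(arms), unname(arms)), function(a) {
    ta <- t12[t12$arm == a, ]
    stats::setNames(lapply(cost_components(), function(comp) {
      col <- paste0("cost_", comp)
      anchors <- tapply(ta[[col]], ta$state12, mean, na.rm = TRUE)
      series <- cohort_by(cy[[col]], cy$year, cy$state)
      payoff_matrix(
        cp = pct_change_project(anchors[["CP"]], series[, "CP"]),
        ncp = pct_change_project(anchors[["NCP"]], series[, "NCP"]))
    }), cost_components())
  })

  params <- parameter_set(arms = arms, transitions = transitions,
                          qalys = qalys, costs = costs,
                          intervention_cost = intervention_cost, ...)
  attr(params, "exclusions") <- exclusions
  params
}
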