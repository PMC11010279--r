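#' Classify chronic-pain state from the OKS pain subscale
#'
#' The Oxford Knee Score pain subscale (OKS-PS) runs from 0 (worst) to 28
#' (best). Scores of 14 or less are classified as chronic pain (CP), scores
#' above 14 as no chronic pain (NCP).
#'
#' @param oks_ps Integer score(s) in 0..28.
#' @param threshold Classification cut-point (default 14; CP iff score <=
#'   threshold).
#' @return Character vector of `"CP"` / `"NCP"`.
#' @examples
#' classify_pain(c(0, 14, 15, 28))
#' @export
classify_pain <- function(oks_ps, threshold = 14) {
  if (anyNA(oks_ps) || any(oks_ps < 0 | oks_ps > 28))
    stop("OKS-PS scores must lie in 0..28")
  ifelse(oks_ps <= threshold, "CP", "NCP")
}

#' Estimate a transition matrix from paired panel observations
#'
#' Classifies each patient's state at two assessment times and estimates the
#' transition matrix by row-wise relative frequencies: entry (i, j) is the
#' number of patients in state i at `from_time` and state j at `to_time`,
#' divided by the number in state i at `from_time`. Patients missing either
#' observation are excluded (available-case); their count is attached as
#' attribute `"excluded"`.
#'
#' @param panel A patient panel data frame (see [simulate_trial()]) with
#'   columns `patient_id`, `arm`, `time_months`, `oks_ps`.
#' @param from_time,to_time Assessment times in months since operation.
#' @param arm Optional arm filter.
#' @param threshold OKS-PS classification cut-point (default 14).
#' @param missing_origin What to do when no patient occupies an origin state
#'   at `from_time`: `"error"` (default) or `"identity"`, which fills that
#'   row with the identity (stay put) — used for trial baselines where
#'   everyone enters in CP and the NCP row is structural.
#' @return A 2x2 [transition_matrix()]-style matrix with attribute
#'   `"excluded"` (number of patients dropped) and `"n_origin"` (risk-set
#'   sizes per origin state).
#' @export
estimate_transition_matrix <- function(panel, from_time, to_time, arm = NULL,
                                       threshold = 14,
                                       missing_origin = c("error", "identity")) {
  missing_origin <- match.arg(missing_origin)
  if (!is.null(arm)) panel <- panel[panel$arm == arm, , drop = FALSE]
  at <- function(t) {
    p <- panel[panel$time_months == t & !is.na(panel$oks_ps), c("patient_id", "oks_ps")]
    stats::setNames(classify_pain(p$oks_ps, threshold), p$patient_id)
  }
  s_from <- at(from_time)
  s_to <- at(to_time)
  ids <- intersect(names(s_from), names(s_to))
  n_total <- length(union(names(s_from), names(s_to)))
  excluded <- n_total - length(ids)
  if (!length(ids))
    stop("no patients observed at both ", from_time, " and ", to_time, " months")
  st <- pain_states()
  m <- matrix(0, 2, 2, dimnames = list(from = st, to = st))
  n_origin <- stats::setNames(numeric(2), st)
  for (s in st) {
    in_s <- ids[s_from[ids] == s]
    n_origin[s] <- length(in_s)
    if (!length(in_s)) {
      if (missing_origin == "error")
        stop("empty risk set: no patients in state ", s, " at ", from_time,
             " months")
      m[s, ] <- as.numeric(st == s)  # identity row for a structural origin
      next
    }
    m[s, ] <- vapply(st, function(d) mean(s_to[in_s] == d), numeric(1))
  }
  attr(m, "excluded") <- excluded
  attr(m, "n_origin") <- n_origin
  m
}

#' Area-under-the-curve QALYs over one year
#'
#' Trapezoidal area under the utility-time curve with utilities observed at
#' baseline, 6 and 12 months: 0.25 (u0 + u6) + 0.25 (u6 + u12).
#'
#' @param u0,u6,u12 Health utilities (EQ-5D-3L scale: at most 1, may be
#'   negative).
#' @return QALYs accrued over the year.
#' @examples
#' auc_qaly(0.2, 0.6, 0.8)  # 0.55
#' @export
auc_qaly <- function(u0, u6, u12) {
  if (any(c(u0, u6, u12) > 1)) stop("utilities cannot exceed 1")
  0.25 * (u0 + u6) + 0.25 * (u6 + u12)
}

#' Baseline-adjusted group mean QALYs
#'
#' Fits a linear model of per-patient QALYs on group membership plus
#' baseline utility (one pooled baseline slope across groups) and returns
#' each group's predicted mean QALY at the pooled mean baseline utility.
#' This is the standard regression adjustment for baseline imbalance in
#' utility between randomised groups.
#'
#' @param qaly Numeric vector of per-patient QALYs.
#' @param baseline Numeric vector of baseline utilities.
#' @param group Factor (or character) of group labels, at least two groups
#'   with at least two patients each.
#' @return Named numeric vector of adjusted mean QALYs, one per group, with
#'   the fitted model attached as attribute `"fit"`.
#' @export
adjust_qalys_for_baseline <- function(qaly, baseline, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) < 2)) stop("need at least two patients per group")
  if (stats::sd(baseline) == 0)
    stop("baseline utility is constant; adjustment model is singular")
  fit <- stats::lm(qaly ~ group + baseline)
  newdata <- data.frame(group = factor(levels(group), levels = levels(group)),
                        baseline = mean(baseline))
  out <- stats::setNames(stats::predict(fit, newdata), levels(group))
  attr(out, "fit") <- fit
  out
}

#' One step of the utility projection used for years 2-5
#'
#' Projects an anchored utility forward by the change observed in a
#' reference cohort between two consecutive years. Improvements are applied
#' as a percentage of potential change (PoPC): the cohort's gain as a
#' fraction of its remaining distance to the scale maximum is applied to the
#' anchor's own remaining distance,
#' `next = current + (to - from) / (scale_max - from) * (scale_max - current)`.
#' Deteriorations are applied as a percentage change of the level itself,
#' `next = current * to / from`, which is how the published projected series
#' behave in their declining years. Both rules return `cohort_to` exactly
#' when `current == cohort_from`.
#'
#' @param current The anchored value being projected.
#' @param cohort_from,cohort_to Consecutive cohort values defining the
#'   observed change.
#' @param scale_max Upper bound of the measure (1 for utility).
#' @return The projected next value.
#' @examples
#' popc_step(0.484, 0.465, 0.556)  # 0.5718
#' @export
popc_step <- function(current, cohort_from, cohort_to, scale_max = 1) {
  if (cohort_from >= scale_max)
    stop("cohort_from must be below scale_max (remaining potential is zero)")
  if (current > scale_max) stop("current exceeds scale_max")
  if (cohort_to >= cohort_from) {
    popc <- (cohort_to - cohort_from) / (scale_max - cohort_from)
    current + popc * (scale_max - current)
  } else {
    if (cohort_from <= 0)
      stop("cohort_from must be positive to apply a relative decline")
    current * (cohort_to / cohort_from)
  }
}

#' Project an anchored utility series along a cohort trajectory
#'
#' Iterates [popc_step()] along consecutive cohort values, starting from an
#' anchor in year 1. Output has the same length as the cohort series; the
#' first element is the anchor itself.
#'
#' @param anchor Year-1 anchored value (for example a trial estimate).
#' @param cohort_series Numeric vector of cohort values by year (length >= 2).
#' @param scale_max Upper bound of the measure (default 1).
#' @return Numeric vector of projected values, same length as
#'   `cohort_series`.
#' @examples
#' popc_project(0.484, c(0.465, 0.556, 0.607, 0.642, 0.698))
#' @export
popc_project <- function(anchor, cohort_series, scale_max = 1) {
  if (length(cohort_series) < 2) stop("cohort series needs at least two values")
  out <- numeric(length(cohort_series))
  out[1] <- anchor
  for (t in 2:length(cohort_series))
    out[t] <- popc_step(out[t - 1], cohort_series[t - 1], cohort_series[t],
                        scale_max)
  out
}

#' Project an anchored cost series by cohort percent changes
#'
#' Applies the annual percentage changes observed in a reference cohort
#' multiplicatively to a year-1 anchor: the projected series is
#' `anchor * cohort[t] / cohort[1]`. Equivariant under rescaling of the
#' anchor.
#'
#' @param anchor Year-1 anchored cost (GBP).
#' @param cohort_costs Positive cohort cost values by year.
#' @return Projected yearly costs, same length as `cohort_costs`, starting
#'   at the anchor.
#' @examples
#' pct_change_project(200, c(100, 88))  # 200, 176
#' @export
pct_change_project <- function(anchor, cohort_costs) {
  if (any(cohort_costs == 0))
    stop("cohort costs must be non-zero (relative change undefined at 0)")
  anchor * cohort_costs / cohort_costs[1]
}
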