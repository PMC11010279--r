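#' Health states of the chronic-pain model
#'
#' The model distinguishes exactly two health states after total knee
#' replacement: chronic pain (`"CP"`) and no chronic pain (`"NCP"`), defined
#' from the Oxford Knee Score pain subscale (OKS-PS, 0-28) with CP meaning a
#' score of 14 or less (see [classify_pain()]).
#'
#' @return Character vector `c("CP", "NCP")`.
#' @export
pain_states <- function() c("CP", "NCP")

#' Build a 2x2 transition matrix between pain states
#'
#' Rows index the origin state, columns the destination, in the order
#' CP, NCP. Each row must be a probability distribution.
#'
#' @param cp_to_cp Probability of remaining in chronic pain over one cycle.
#' @param ncp_to_cp Probability of relapsing from NCP to CP over one cycle.
#' @return A 2x2 numeric matrix with dimnames `list(from, to)`.
#' @examples
#' transition_matrix(0.494, 0.0)
#' @export
transition_matrix <- function(cp_to_cp, ncp_to_cp) {
  m <- matrix(c(cp_to_cp, 1 - cp_to_cp, ncp_to_cp, 1 - ncp_to_cp),
              nrow = 2, byrow = TRUE,
              dimnames = list(from = pain_states(), to = pain_states()))
  m
}

payoff_matrix <- function(cp, ncp, horizon = length(cp)) {
  stopifnot(length(cp) == horizon, length(ncp) == horizon)
  matrix(c(cp, ncp), ncol = 2,
         dimnames = list(year = seq_len(horizon), state = pain_states()))
}

#' Assemble a validated model parameter set
#'
#' Bundles everything the cohort model needs for both arms: per-year
#' transition matrices, per-year per-state QALY payoffs, per-year per-state
#' cost components, the one-off intervention cost, discounting and horizon
#' settings, the initial state distribution and the willingness-to-pay
#' threshold.
#'
#' @param arms Named character vector with entries `intervention` and
#'   `comparator` giving the two arm identifiers.
#' @param transitions Named list (one entry per arm) of lists of 2x2
#'   transition matrices, one matrix per model year.
#' @param qalys Named list (per arm) of year-by-state matrices of QALYs
#'   accrued per cycle in each state (columns `CP`, `NCP`).
#' @param costs Named list (per arm) of named lists of year-by-state cost
#'   matrices, one per component (`prescriptions`, `consultations`,
#'   `hospital`), in GBP.
#' @param intervention_cost One-off cost (GBP) applied undiscounted in year 1
#'   to the intervention arm only.
#' @param extra_arm_year1_cost Calibration knob (GBP, default 0): an
#'   additional year-1 cost on the intervention arm. The published totals for
#'   the intervention arm carry a constant cost not reconstructable from the
#'   published per-state inputs; this knob makes that gap explicit and
#'   calibratable (see [calibrate_extra_year1_cost()]) instead of silently
#'   absorbed. It is never set by default.
#' @param discount_rate Annual discount rate applied to costs and QALYs from
#'   the second year onwards (default 0.035).
#' @param horizon Number of annual cycles (default 5).
#' @param initial_distribution Named numeric (`CP`, `NCP`) summing to 1;
#'   default is everyone entering in chronic pain.
#' @param wtp_threshold Willingness-to-pay threshold in GBP per QALY
#'   (default 20000).
#' @param check If `TRUE` (default) stop on any validation violation.
#' @return An object of class `star_params`.
#' @seealso [star_parameters()] for the built-in base-case fixture,
#'   [validate_parameters()], [load_parameters()].
#' @export
parameter_set <- function(arms, transitions, qalys, costs,
                          intervention_cost,
                          extra_arm_year1_cost = 0,
                          discount_rate = 0.035,
                          horizon = 5,
                          initial_distribution = c(CP = 1, NCP = 0),
                          wtp_threshold = 20000,
                          check = TRUE) {
  params <- structure(
    list(arms = arms,
         transitions = transitions,
         qalys = qalys,
         costs = costs,
         intervention_cost = intervention_cost,
         extra_arm_year1_cost = extra_arm_year1_cost,
         discount_rate = discount_rate,
         horizon = as.integer(horizon),
         initial_distribution = initial_distribution[pain_states()],
         wtp_threshold = wtp_threshold),
    class = "star_params")
  if (check) {
    v <- validate_parameters(params)
    if (length(v)) stop("invalid parameter set:\n  ", paste(v, collapse = "\n  "))
  }
  params
}

#' Built-in base-case parameter set
#'
#' The published inputs of the model, exactly as printed: annual transition
#' probabilities per arm (trial-based in year 1, cohort-based in years 2-5),
#' annual per-state QALY values, annual per-state cost components
#' (prescriptions, medical consultations, hospital admissions; GBP at
#' 2019-2020 prices), the GBP 191 one-off intervention cost, a 3.5% discount
#' rate, a five-year horizon, a cohort entering 100% in chronic pain, and a
#' GBP 20,000 per QALY threshold.
#'
#' Values are stored to their printed precision; no attempt is made to
#' reconstruct unrounded trial estimates. The year-1 NCP transition rows
#' print as zeros in the source table because no-one occupies NCP at entry;
#' they are stored here as (NCP to CP = 0, NCP to NCP = 1) so every row is a
#' valid distribution, which is inert under the all-CP initial distribution.
#'
#' @return A validated [parameter_set()] with arms `star` (intervention) and
#'   `usual_care` (comparator).
#' @examples
#' p <- star_parameters()
#' p$transitions$usual_care[[1]]["CP", "CP"]  # 0.494
#' @export
star_parameters <- function() {
  ncp_to_cp <- c(0.000, 0.050, 0.042, 0.031, 0.037)
  uc_cp_cp <- c(0.494, 0.368, 0.388, 0.400, 0.406)
  st_cp_cp <- c(0.355, 0.368, 0.388, 0.400, 0.406)
  transitions <- list(
    star = lapply(1:5, function(t) transition_matrix(st_cp_cp[t], ncp_to_cp[t])),
    usual_care = lapply(1:5, function(t) transition_matrix(uc_cp_cp[t], ncp_to_cp[t])))

  qalys <- list(
    star = payoff_matrix(cp = c(0.484, 0.572, 0.621, 0.654, 0.708),
                         ncp = c(0.560, 0.742, 0.739, 0.728, 0.714)),
    usual_care = payoff_matrix(cp = c(0.465, 0.556, 0.607, 0.642, 0.698),
                               ncp = c(0.539, 0.730, 0.727, 0.716, 0.702)))

  prescriptions <- payoff_matrix(cp = c(100, 88, 91, 91, 91),
                                 ncp = c(22, 18, 17, 17, 18))
  consultations <- payoff_matrix(cp = c(166, 143, 137, 137, 125),
                                 ncp = c(62, 51, 48, 46, 48))
  costs <- list(
    star = list(
      prescriptions = prescriptions,
      consultations = consultations,
      hospital = payoff_matrix(cp = c(1265, 898, 464, 65, 24),
                               ncp = c(1302, 386, 331, 82, 249))),
    usual_care = list(
      prescriptions = prescriptions,
      consultations = consultations,
      hospital = payoff_matrix(cp = c(2972, 898, 464, 65, 24),
                               ncp = c(1057, 386, 331, 82, 249))))

  parameter_set(
    arms = c(intervention = "star", comparator = "usual_care"),
    transitions = transitions, qalys = qalys, costs = costs,
    intervention_cost = 191)
}

cost_components <- function() c("prescriptions", "consultations", "hospital")

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and returns the
#' violations as data rather than raising: each element names the offending
#' field and the rule broken. An empty character vector means the set is
#' valid.
#'
#' @param params A `star_params` object (or a bare list with the same shape).
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_parameters <- function(params) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))
  H <- params$horizon
  if (!is.numeric(H) || length(H) != 1 || is.na(H) || H < 1 || H != round(H))
    say("horizon: must be an integer >= 1 (got %s)", format(params$horizon))
  if (!is.numeric(params$discount_rate) || params$discount_rate < 0)
    say("discount_rate: must be >= 0")
  if (is.null(params$wtp_threshold) || params$wtp_threshold <= 0)
    say("wtp_threshold: must be > 0")
  arms <- params$arms
  if (length(arms) != 2 || !all(c("intervention", "comparator") %in% names(arms)))
    say("arms: need named entries 'intervention' and 'comparator'")
  init <- params$initial_distribution
  if (length(init) != 2 || anyNA(init) || any(init < 0) || any(init > 1))
    say("initial_distribution: needs CP and NCP fractions in [0,1]")
  else if (abs(sum(init) - 1) > 1e-9)
    say("initial_distribution: fractions sum to %.6f, not 1", sum(init))
  if (length(v)) return(v)  # shape errors make the per-year checks unreliable

  for (arm in arms) {
    tr <- params$transitions[[arm]]
    if (length(tr) < H) {
      say("transitions[%s]: covers %d years, horizon is %d", arm, length(tr), H)
    } else {
      for (t in seq_len(H)) {
        m <- tr[[t]]
        if (!is.matrix(m) || !all(dim(m) == 2)) {
          say("transitions[%s][%d]: not a 2x2 matrix", arm, t); next
        }
        if (any(m < 0) || any(m > 1))
          say("transitions[%s][%d]: entries outside [0,1]", arm, t)
        bad <- which(abs(rowSums(m) - 1) > 1e-9)
        for (i in bad)
          say("transitions[%s][%d]: row %s sums to %.6f, not 1",
              arm, t, pain_states()[i], rowSums(m)[i])
      }
    }
    q <- params$qalys[[arm]]
    if (!is.matrix(q) || nrow(q) < H) {
      say("qalys[%s]: must be a year-by-state matrix covering years 1..%d", arm, H)
    } else if (any(q < 0) || any(q > 1)) {
      idx <- which(q < 0 | q > 1, arr.ind = TRUE)
      for (k in seq_len(nrow(idx)))
        say("qalys[%s][year %d, %s]: value %.3f outside [0,1]",
            arm, idx[k, 1], pain_states()[idx[k, 2]], q[idx[k, , drop = FALSE]])
    }
    for (comp in cost_components()) {
      cc <- params$costs[[arm]][[comp]]
      if (!is.matrix(cc) || nrow(cc) < H)
        say("costs[%s][%s]: must cover years 1..%d", arm, comp, H)
      else if (any(cc < 0))
        say("costs[%s][%s]: negative cost component", arm, comp)
    }
  }
  if (params$intervention_cost < 0)
    say("intervention_cost: must be >= 0")
  v
}

#' @export
print.star_params <- function(x, ...) {
  cat(sprintf("<star_params> %s vs %s | horizon %d y | discount %.1f%% | WTP £%s/QALY\n",
              x$arms[["intervention"]], x$arms[["comparator"]],
              x$horizon, 100 * x$discount_rate,
              format(x$wtp_threshold, big.mark = ",")))
  cat(sprintf("  intervention one-off cost £%s; extra year-1 arm cost £%s\n",
              format(x$intervention_cost), format(x$extra_arm_year1_cost)))
  cat(sprintf("  initial distribution: CP %.0f%%, NCP %.0f%%\n",
              100 * x$initial_distribution[["CP"]],
              100 * x$initial_distribution[["NCP"]]))
  invisible(x)
}

# ---- serialization -----------------------------------------------------

#' Convert a parameter set to a plain nested list
#'
#' The list mirrors the on-disk config layout (blocks `arms`, `settings`,
#' `transitions`, `payoffs`) and round-trips through
#' [write_parameters()] / [load_parameters()].
#'
#' @param params A `star_params` object.
#' @return A nested list of plain vectors.
#' @export
as_parameter_list <- function(params) {
  tr_block <- function(arm) lapply(params$transitions[[arm]], function(m)
    list(cp_to_cp = m["CP", "CP"], cp_to_ncp = m["CP", "NCP"],
         ncp_to_cp = m["NCP", "CP"], ncp_to_ncp = m["NCP", "NCP"]))
  payoff_block <- function(arm) list(
    qalys = list(CP = unname(params$qalys[[arm]][, "CP"]),
                 NCP = unname(params$qalys[[arm]][, "NCP"])),
    costs = lapply(params$costs[[arm]], function(m)
      list(CP = unname(m[, "CP"]), NCP = unname(m[, "NCP"]))))
  arms <- as.list(params$arms)
  list(
    arms = arms,
    settings = list(
      discount_rate = params$discount_rate,
      horizon = params$horizon,
      wtp_threshold = params$wtp_threshold,
      intervention_cost = params$intervention_cost,
      extra_arm_year1_cost = params$extra_arm_year1_cost,
      initial_distribution = as.list(params$initial_distribution)),
    transitions = stats::setNames(lapply(unlist(arms), tr_block), unlist(arms)),
    payoffs = stats::setNames(lapply(unlist(arms), payoff_block), unlist(arms)))
}

#' Write a parameter set to YAML or JSON
#'
#' @param params A `star_params` object.
#' @param path Output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  x <- as_parameter_list(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unrecognised config extension (want .yaml/.yml or .json): ", path)
  }
  invisible(path)
}

need <- function(x, path) {
  node <- x
  for (k in strsplit(path, "/", fixed = TRUE)[[1]]) {
    node <- node[[k]]
    if (is.null(node)) stop("config is missing required field '", path, "'")
  }
  node
}

#' Load a parameter set from a config document
#'
#' Reads the nested-document layout produced by [write_parameters()] (blocks
#' `arms`, `settings`, `transitions`, `payoffs`) from a YAML or JSON file, or
#' from an already-parsed list. Missing optional settings are filled with
#' their defaults: discount rate 0.035, horizon 5, willingness-to-pay
#' threshold 20000, extra arm year-1 cost 0, and an all-CP initial
#' distribution. The result is validated; any violation (for example a
#' transition row not summing to 1) raises an error naming the offending
#' field.
#'
#' @param x Path to a `.yaml`/`.yml`/`.json` file, or a nested list.
#' @return A validated `star_params` object.
#' @export
load_parameters <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      jsonlite::read_json(x, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
    } else {
      yaml::read_yaml(x)
    }
  }
  if (!is.list(x)) stop("config must be a file path or a nested list")

  arms <- c(intervention = need(x, "arms/intervention"),
            comparator = need(x, "arms/comparator"))
  st <- x$settings %||% list()
  horizon <- as.integer(st$horizon %||% 5)

  read_tr <- function(arm) {
    block <- need(x, paste0("transitions/", arm))
    if (length(block) < horizon)
      stop("transitions/", arm, ": ", length(block),
           " years listed, horizon is ", horizon)
    lapply(seq_len(horizon), function(t) {
      row <- block[[t]]
      for (f in c("cp_to_cp", "cp_to_ncp", "ncp_to_cp", "ncp_to_ncp"))
        if (is.null(row[[f]]))
          stop("transitions/", arm, "/year ", t, ": missing '", f, "'")
      matrix(as.numeric(c(row$cp_to_cp, row$cp_to_ncp,
                          row$ncp_to_cp, row$ncp_to_ncp)),
             nrow = 2, byrow = TRUE,
             dimnames = list(from = pain_states(), to = pain_states()))
    })
  }
  read_series <- function(path) {
    s <- need(x, path)
    out <- payoff_matrix(cp = as.numeric(unlist(s$CP)),
                         ncp = as.numeric(unlist(s$NCP)))
    if (nrow(out) < horizon)
      stop(path, ": ", nrow(out), " years listed, horizon is ", horizon)
    out
  }
  qalys <- lapply(stats::setNames(unname(arms), unname(arms)), function(a)
    read_series(paste0("payoffs/", a, "/qalys")))
  costs <- lapply(stats::setNames(unname(arms), unname(arms)), function(a)
    stats::setNames(lapply(cost_components(), function(comp)
      read_series(paste0("payoffs/", a, "/costs/", comp))), cost_components()))

  init <- st$initial_distribution %||% list(CP = 1, NCP = 0)
  parameter_set(
    arms = arms,
    transitions = stats::setNames(lapply(unname(arms), read_tr), unname(arms)),
    qalys = qalys, costs = costs,
    intervention_cost = as.numeric(need(x, "settings/intervention_cost")),
    extra_arm_year1_cost = as.numeric(st$extra_arm_year1_cost %||% 0),
    discount_rate = as.numeric(st$discount_rate %||% 0.035),
    horizon = horizon,
    initial_distribution = c(CP = as.numeric(init$CP), NCP = as.numeric(init$NCP)),
    wtp_threshold = as.numeric(st$wtp_threshold %||% 20000))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
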