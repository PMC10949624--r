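#' Periodontal state definitions
#'
#' Thresholds separating the three periodontal health states: stable means
#' probing pocket depth (PPD) at or below the threshold with bleeding on
#' probing (BOP) below the BOP threshold; remission means pockets controlled
#' but BOP at or above the threshold; unstable means residual pockets above
#' the PPD threshold.
#'
#' @param ppd_threshold_mm Pocket-depth threshold in mm (default 4: "4 mm and
#'   less" is controlled, "5 mm and more" is unstable).
#' @param bop_threshold_fraction BOP threshold as a fraction of sites
#'   (default 0.10).
#' @return List of class `state_definitions`.
#' @export
state_definitions <- function(ppd_threshold_mm = 4,
                              bop_threshold_fraction = 0.10) {
  if (ppd_threshold_mm <= 0 || bop_threshold_fraction <= 0) {
    stop_domain("state thresholds must be positive")
  }
  structure(list(ppd_threshold_mm = ppd_threshold_mm,
                 bop_threshold_fraction = bop_threshold_fraction),
            class = "state_definitions")
}

#' State proportions from a trial-arm summary
#'
#' Estimates the fraction of an arm in each periodontal state from its
#' summary statistics, assuming patient-level mean PPD is normally
#' distributed. The probability of controlled pockets is
#' `pnorm((ppd_threshold + 0.5 - mean_ppd) / sd_ppd)`; the 0.5 mm continuity
#' offset reflects the integer banding of the clinical definition ("4 mm and
#' less" vs "5 mm and more"). The controlled mass is split between stable and
#' remission by whether the arm's mean BOP is below the BOP threshold (a
#' point indicator, the only option when only the summary is available), the
#' two being mutually exclusive; the remainder is unstable.
#'
#' @param arm A trial-arm summary: list or one-row data frame with
#'   `mean_ppd_mm`, `sd_ppd_mm`, `bop_fraction` (and usually `n`, `arm`,
#'   `strategy`, `followup_months`).
#' @param defs [state_definitions()].
#' @return Named numeric vector `c(stable, remission, unstable)` of class
#'   `state_proportions`, summing to 1.
#' @examples
#' state_proportions_from_summary(
#'   list(mean_ppd_mm = 4.5, sd_ppd_mm = 1, bop_fraction = 0.05),
#'   state_definitions())
#' @export
state_proportions_from_summary <- function(arm, defs = state_definitions()) {
  m <- arm$mean_ppd_mm; s <- arm$sd_ppd_mm; bop <- arm$bop_fraction
  if (is.null(m) || is.null(s) || is.null(bop)) {
    stop_validation("arm summary needs mean_ppd_mm, sd_ppd_mm, bop_fraction")
  }
  assert_probability(bop, "bop_fraction")
  if (s < 0) stop_domain("sd_ppd_mm must be >= 0")
  cut <- defs$ppd_threshold_mm + 0.5
  if (s == 0) {
    if (m == cut) {
      stop_domain("sd_ppd_mm = 0 with mean at the threshold: ",
                  "pocket-control indicator undefined")
    }
    p_controlled <- as.numeric(m < cut)
  } else {
    p_controlled <- stats::pnorm((cut - m) / s)
  }
  p_lowbop <- as.numeric(bop < defs$bop_threshold_fraction)
  p_stable <- p_controlled * p_lowbop
  state_proportions(c(stable = p_stable,
                      remission = p_controlled - p_stable,
                      unstable = 1 - p_controlled))
}

#' Validate a triple of state proportions
#'
#' @param p Numeric vector of length 3 (stable, remission, unstable).
#' @return Named numeric vector of class `state_proportions`.
#' @export
state_proportions <- function(p) {
  p <- stats::setNames(as.numeric(unlist(p)), PERIO_STATES)
  if (any(p < -1e-12) || any(p > 1 + 1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop_domain("state proportions must lie in [0,1] and sum to 1 (got ",
                paste(format(p), collapse = ", "), ")")
  }
  structure(pmin(pmax(p, 0), 1), class = "state_proportions")
}

#' Pooled relative risk of reaching one state, test vs control
#'
#' Pools derived event counts (`n` times the arm's state proportion) across
#' arms within each group and returns the ratio of pooled event proportions.
#' If either pooled event count is zero, a Haldane-Anscombe continuity
#' correction (0.5 added to each arm's event and non-event cells) is applied
#' to both groups and a message is emitted.
#'
#' @param test_arms,control_arms Data frames (or lists of lists) of arm
#'   summaries accepted by [state_proportions_from_summary()], each with `n`.
#' @param state Destination state, one of [PERIO_STATES].
#' @param defs [state_definitions()].
#' @return Relative risk (test over control), length 1.
#' @export
pooled_relative_risk <- function(test_arms, control_arms, state,
                                 defs = state_definitions()) {
  state <- match.arg(state, PERIO_STATES)
  pool <- function(arms) {
    arms <- as_arm_list(arms)
    if (!length(arms)) stop_domain("arm list must be non-empty")
    ev <- 0; n <- 0
    for (a in arms) {
      if (is.null(a$n) || a$n < 1) stop_domain("every arm needs n >= 1")
      p <- state_proportions_from_summary(a, defs)
      ev <- ev + a$n * unname(p[state])
      n <- n + a$n
    }
    c(events = ev, n = n)
  }
  te <- pool(test_arms); co <- pool(control_arms)
  if (te[["events"]] == 0 || co[["events"]] == 0) {
    k_t <- length(as_arm_list(test_arms)); k_c <- length(as_arm_list(control_arms))
    message("pooled_relative_risk: zero pooled events for state '", state,
            "'; applying Haldane-Anscombe continuity correction")
    te <- c(events = te[["events"]] + 0.5 * k_t, n = te[["n"]] + 1 * k_t)
    co <- c(events = co[["events"]] + 0.5 * k_c, n = co[["n"]] + 1 * k_c)
  }
  if (co[["events"]] == 0) {
    stop_domain("control pooled proportion is zero even after continuity ",
                "correction; relative risk undefined")
  }
  (te[["events"]] / te[["n"]]) / (co[["events"]] / co[["n"]])
}

as_arm_list <- function(arms) {
  if (is.data.frame(arms)) {
    lapply(seq_len(nrow(arms)), function(i) as.list(arms[i, , drop = FALSE]))
  } else if (is.list(arms) && !is.null(arms$mean_ppd_mm)) {
    list(arms)
  } else {
    arms
  }
}

#' Apply relative risks to a control state distribution
#'
#' Scales each destination probability of the control distribution by its
#' relative risk, clamps to [0, 1], then renormalises the triple to sum to 1.
#'
#' @param control_probs [state_proportions()] of the control group.
#' @param rr_by_state Named relative risks (missing states default to 1).
#' @return [state_proportions()] for the treated group.
#' @examples
#' apply_rr(state_proportions(c(0.5, 0.3, 0.2)), c(stable = 1.2))
#' @export
apply_rr <- function(control_probs, rr_by_state) {
  p <- state_proportions(control_probs)
  rr <- stats::setNames(rep(1, 3), PERIO_STATES)
  rr[names(rr_by_state)] <- unlist(rr_by_state)
  if (any(rr < 0)) stop_domain("relative risks must be non-negative")
  q <- pmin(pmax(unclass(p) * rr, 0), 1)
  if (sum(q) == 0) stop_domain("all scaled probabilities are zero")
  state_proportions(q / sum(q))
}

#' Convert an annual transition probability to the model cycle length
#'
#' Standard rate-based conversion: the annual probability is turned into a
#' constant hazard and re-expressed over `1/cycles_per_year` of a year,
#' `1 - (1 - p)^(1/cycles_per_year)`.
#'
#' @param p_annual Annual transition probability in [0, 1).
#' @param cycles_per_year Number of model cycles per year (4 for a 3-month
#'   cycle).
#' @return Per-cycle probability.
#' @examples
#' annual_to_cycle(0.27, 4)
#' @export
annual_to_cycle <- function(p_annual, cycles_per_year = 4) {
  if (cycles_per_year < 1 || cycles_per_year != round(cycles_per_year)) {
    stop_domain("cycles_per_year must be a positive integer")
  }
  if (any(p_annual < 0) || any(p_annual >= 1)) {
    stop_domain("p_annual must lie in [0, 1); p = 1 implies an infinite rate")
  }
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Validate a 3x3 transition matrix
#'
#' @param m Numeric 3x3 matrix, rows = origin states, columns = destination
#'   states, both ordered as [PERIO_STATES].
#' @param require_irreducible Also check that every state can reach every
#'   other (no absorbing state), as the base-case model assumes.
#' @return The matrix with dimnames set, invisibly classed
#'   `transition_matrix`.
#' @export
transition_matrix <- function(m, require_irreducible = FALSE) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3, 3))) stop_domain("transition matrix must be 3x3")
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop_domain("transition probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop_domain("every transition-matrix row must sum to 1")
  }
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(PERIO_STATES, PERIO_STATES)
  if (require_irreducible) {
    reach <- (m > 0) | diag(3) > 0
    for (i in 1:3) reach <- (reach %*% reach) > 0
    if (!all(reach)) stop_domain("matrix is reducible: some state is absorbing")
  }
  structure(m, class = c("transition_matrix", "matrix", "array"))
}

#' Build the per-cycle transition matrix set
#'
#' Assembles, for each treatment strategy, the cycle-indexed 3x3 matrices of
#' the one-year model. Rows out of the stable and remission states come from
#' published 1-year probabilities, converted entry-wise to the cycle length
#' via [annual_to_cycle()] and renormalised to sum to 1 (the exact multi-state
#' conversion via a matrix root is deliberately not used; it is not
#' identifiable from row-wise published probabilities). The row out of the
#' unstable state is already a per-cycle quantity: strategy-specific at cycle
#' 1 (effect of the initial instrumentation with or without adjuncts), and a
#' shared maintenance (re-instrumentation) row at cycles 2 onwards.
#'
#' @param unstable_rows_by_strategy Named list over [PERIO_STRATEGIES] of
#'   per-cycle [state_proportions()] for the first cycle.
#' @param stable_row_annual,remission_row_annual Annual probability triples.
#' @param unstable_maintenance_row Per-cycle triple for cycles 2+; defaults
#'   to the NSPT-only row (re-instrumentation without adjuncts).
#' @param n_cycles Number of cycles (default 4).
#' @param cycles_per_year Cycles per year for the annual conversion
#'   (default 4).
#' @return Named list by strategy; each element a list of `n_cycles`
#'   [transition_matrix()] objects.
#' @export
build_matrices <- function(unstable_rows_by_strategy,
                           stable_row_annual,
                           remission_row_annual,
                           unstable_maintenance_row = NULL,
                           n_cycles = 4,
                           cycles_per_year = 4) {
  convert_row <- function(row_annual) {
    row_annual <- stats::setNames(as.numeric(row_annual), PERIO_STATES)
    if (abs(sum(row_annual) - 1) > 1e-9) {
      stop_domain("annual row must sum to 1 before conversion")
    }
    # a certain annual transition stays certain per cycle (degenerate rows,
    # e.g. the identity, carry through unchanged)
    q <- row_annual
    sub <- row_annual < 1
    q[sub] <- annual_to_cycle(row_annual[sub], cycles_per_year)
    if (sum(q) == 0) stop_domain("annual row converts to an all-zero cycle row")
    q / sum(q)
  }
  stable_cycle <- convert_row(stable_row_annual)
  remission_cycle <- convert_row(remission_row_annual)
  maint <- state_proportions(
    unstable_maintenance_row %||% unstable_rows_by_strategy$NSPT_only)

  lapply_named <- function(x, f) stats::setNames(lapply(names(x), f), names(x))
  lapply_named(unstable_rows_by_strategy, function(strat) {
    first <- state_proportions(unstable_rows_by_strategy[[strat]])
    lapply(seq_len(n_cycles), function(k) {
      unstable_row <- if (k == 1) first else maint
      transition_matrix(rbind(stable_cycle, remission_cycle,
                              unclass(unstable_row)))
    })
  })
}

#' Transition matrices from a model configuration
#'
#' Dispatches on `config$transition_spec$mode`: `"rows"` feeds the configured
#' row triples to [build_matrices()]; `"matrices"` validates explicit
#' per-cycle matrices per strategy.
#'
#' @param config A `perio_config`.
#' @return As [build_matrices()].
#' @export
derive_matrices_from_config <- function(config) {
  spec <- config$transition_spec
  mode <- spec$mode %||% "rows"
  if (mode == "rows") {
    build_matrices(
      unstable_rows_by_strategy = spec$unstable_cycle1_rows,
      stable_row_annual = unlist(spec$stable_row_annual),
      remission_row_annual = unlist(spec$remission_row_annual),
      unstable_maintenance_row = if (!is.null(spec$unstable_maintenance_row)) {
        unlist(spec$unstable_maintenance_row)
      },
      n_cycles = config$n_cycles,
      cycles_per_year = round(12 / config$cycle_length_months)
    )
  } else if (mode == "matrices") {
    lapply(spec$matrices, function(per_cycle) {
      lapply(per_cycle, function(m) {
        transition_matrix(matrix(unlist(m), nrow = 3, byrow = TRUE))
      })
    })
  } else {
    stop_validation("unknown transition_spec mode: ", mode)
  }
}

#' Derive per-strategy unstable-row proportions from trial arms
#'
#' Composes the summary-based state proportions, the pooled relative risks
#' and their application into the first-cycle row out of the unstable state
#' for every strategy: the control (instrumentation-only) arms are pooled
#' into the NSPT-only row, and each adjunct strategy's row is the control row
#' scaled by its pooled per-state relative risks.
#'
#' @param summaries Data frame of arm summaries (columns `arm` with values
#'   "control"/"test", `strategy`, `n`, `mean_ppd_mm`, `sd_ppd_mm`,
#'   `bop_fraction`).
#' @param defs [state_definitions()].
#' @return Named list over the strategies present, each a
#'   [state_proportions()] triple.
#' @export
derive_unstable_rows_from_arms <- function(summaries, defs = state_definitions()) {
  ctl <- summaries[summaries$arm == "control", , drop = FALSE]
  if (!nrow(ctl)) stop_domain("no control arms in the summaries")
  pooled_row <- function(arms) {
    props <- vapply(seq_len(nrow(arms)), function(i) {
      unclass(state_proportions_from_summary(as.list(arms[i, ]), defs))
    }, numeric(3))
    state_proportions(as.numeric(props %*% arms$n) / sum(arms$n))
  }
  control_row <- pooled_row(ctl)
  rows <- list(NSPT_only = control_row)
  test_strategies <- unique(summaries$strategy[summaries$arm == "test"])
  for (strat in test_strategies) {
    test <- summaries[summaries$arm == "test" &
                        summaries$strategy == strat, , drop = FALSE]
    rr <- vapply(PERIO_STATES, function(st) {
      pooled_relative_risk(test, ctl, st, defs)
    }, numeric(1))
    rows[[strat]] <- apply_rr(control_row, rr)
  }
  rows
}
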