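#' Construct a synthetic ground truth for end-to-end testing
#'
#' Defines trial-arm population parameters (probing pocket depth mean/SD and
#' mean bleeding-on-probing fraction per arm), the implied true state
#' proportions and transition matrices, and a true cost schedule drawn within
#' the packaged base-case bounds. Control arms receive subgingival
#' instrumentation only; one test arm per antibiotic adjunct.
#'
#' @param seed Seed for the cost-schedule draw.
#' @param defs [state_definitions()].
#' @param stable_row_annual,remission_row_annual Annual rows out of the
#'   stable and remission states used for the true matrices.
#' @param bop_precision Beta-distribution precision of patient-level BOP
#'   around each arm's mean.
#' @return List of class `synthetic_truth` with `arms` (population
#'   parameters), `defs`, `true_proportions` (per arm),
#'   `true_unstable_rows` (per strategy, through the pooled relative-risk
#'   path), `true_matrices`, `cost_schedule`, `bop_precision` and `seed`.
#' @export
synthetic_truth <- function(seed = 1,
                            defs = state_definitions(),
                            stable_row_annual = c(0.70, 0.20, 0.10),
                            remission_row_annual = c(0.30, 0.50, 0.20),
                            bop_precision = 20) {
  # Two studies per adjunct strategy, one low-BOP and one high-BOP pair, so
  # every pooled state proportion is strictly positive; equal arm sizes keep
  # the population pooling identical to the equal-n pooling of regenerated
  # summaries.
  arms <- data.frame(
    study = rep(c("S1", "S2", "S3", "S4"), each = 2),
    arm = rep(c("control", "test"), 4),
    strategy = c("NSPT_only", "NSPT_AMOX_MET", "NSPT_only", "NSPT_AZ",
                 "NSPT_only", "NSPT_AMOX_MET", "NSPT_only", "NSPT_AZ"),
    n = 80,
    mean_ppd_mm = c(4.3, 3.9, 4.5, 4.1, 4.4, 4.0, 4.6, 4.2),
    sd_ppd_mm = c(1.1, 1.0, 1.2, 1.1, 1.0, 1.0, 1.1, 1.0),
    bop_fraction = c(0.06, 0.05, 0.07, 0.06, 0.25, 0.20, 0.28, 0.22),
    followup_months = 3,
    stringsAsFactors = FALSE
  )
  true_props <- lapply(seq_len(nrow(arms)), function(i) {
    state_proportions_from_summary(as.list(arms[i, ]), defs)
  })
  names(true_props) <- paste(arms$study, arms$arm, sep = ":")
  rows <- derive_unstable_rows_from_arms(arms, defs)
  matrices <- build_matrices(rows, stable_row_annual, remission_row_annual,
                             unstable_maintenance_row = rows$NSPT_only)
  bounds <- base_config()$cost_schedule
  structure(list(arms = arms, defs = defs,
                 true_proportions = true_props,
                 true_unstable_rows = rows,
                 true_matrices = matrices,
                 stable_row_annual = stable_row_annual,
                 remission_row_annual = remission_row_annual,
                 cost_schedule = generate_cost_schedule(bounds, seed),
                 bop_precision = bop_precision,
                 seed = seed),
            class = "synthetic_truth")
}

#' Simulate trial-arm summaries with known truth
#'
#' Draws patient-level probing pocket depths from a normal law and
#' bleeding-on-probing fractions from a beta law around each arm's population
#' parameters, then summarises to the mean/SD/BOP format the transition
#' derivation consumes. Deterministic given the seed.
#'
#' @param truth A [synthetic_truth()].
#' @param n_per_arm Patients per arm (>= 2).
#' @param seed RNG seed.
#' @return Data frame of arm summaries (columns `study`, `arm`, `strategy`,
#'   `n`, `mean_ppd_mm`, `sd_ppd_mm`, `bop_fraction`, `followup_months`).
#' @export
generate_trial_summaries <- function(truth, n_per_arm, seed = truth$seed) {
  if (n_per_arm < 2) stop_domain("n_per_arm must be at least 2")
  arms <- truth$arms
  phi <- truth$bop_precision
  with_seed(seed, {
    out <- lapply(seq_len(nrow(arms)), function(i) {
      a <- arms[i, ]
      ppd <- stats::rnorm(n_per_arm, a$mean_ppd_mm, a$sd_ppd_mm)
      bop <- stats::rbeta(n_per_arm, a$bop_fraction * phi,
                          (1 - a$bop_fraction) * phi)
      data.frame(study = a$study, arm = a$arm, strategy = a$strategy,
                 n = n_per_arm,
                 mean_ppd_mm = mean(ppd),
                 sd_ppd_mm = stats::sd(ppd),
                 bop_fraction = mean(bop),
                 followup_months = a$followup_months,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Patient-level microsimulation of the cohort model
#'
#' Independent oracle for [expected_patient_cost()]: simulates each patient's
#' state path through the cycles, sums the visit costs along the path
#' (strategy-specific unstable entry cost, then the state cost at each recall
#' visit), and returns the sample mean with its standard error.
#'
#' @param matrices As for [run_cohort()].
#' @param schedule A [cost_schedule()].
#' @param sector "public" or "private".
#' @param strategy Strategy determining the entry cost.
#' @param n_patients Number of simulated patients.
#' @param seed RNG seed.
#' @param n_cycles Number of cycles (default 4).
#' @return List with `mean`, `se`, `n`.
#' @export
microsimulate_cohort <- function(matrices, schedule, sector, strategy,
                                 n_patients, seed = 1, n_cycles = 4) {
  if (n_patients < 1) stop_domain("n_patients must be >= 1")
  if (inherits(matrices, "transition_matrix") || !is.list(matrices)) {
    matrices <- rep(list(transition_matrix(matrices)), n_cycles)
  }
  matrices <- lapply(matrices, transition_matrix)
  visit_costs <- vapply(seq_len(n_cycles), function(k) {
    vapply(PERIO_STATES, function(st) schedule_cell(schedule, sector, k, st),
           numeric(1))
  }, numeric(3))  # 3 x n_cycles
  entry <- schedule_cell(schedule, sector, 0L, "unstable", strategy)

  with_seed(seed, {
    state <- rep(3L, n_patients)  # everyone enters unstable
    cost <- rep(entry, n_patients)
    for (k in seq_len(n_cycles)) {
      m <- matrices[[k]]
      u <- stats::runif(n_patients)
      nxt <- integer(n_patients)
      for (s in 1:3) {
        idx <- state == s
        if (!any(idx)) next
        cum <- cumsum(m[s, ])
        nxt[idx] <- 1L + (u[idx] > cum[1]) + (u[idx] > cum[2])
      }
      state <- nxt
      cost <- cost + visit_costs[state, k]
    }
    list(mean = mean(cost),
         se = stats::sd(cost) / sqrt(n_patients),
         n = n_patients)
  })
}

#' Draw a random cost schedule within bounds
#'
#' Uniform draw per cell between the `cost_low` and `cost_high` bounds of the
#' supplied schedule; the result keeps the bounds, so cell ordering
#' `low <= base <= high` holds by construction.
#'
#' @param bounds A [cost_schedule()] supplying the per-cell bounds.
#' @param seed RNG seed.
#' @return A [cost_schedule()].
#' @export
generate_cost_schedule <- function(bounds, seed = 1) {
  bounds <- cost_schedule(as.data.frame(bounds))
  if (any(bounds$cost_low > bounds$cost_high)) {
    stop_validation("crossed bounds: cost_low > cost_high in some cell")
  }
  out <- bounds
  with_seed(seed, {
    out$cost_base <- stats::runif(nrow(bounds), bounds$cost_low,
                                  bounds$cost_high)
  })
  cost_schedule(as.data.frame(out))
}
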