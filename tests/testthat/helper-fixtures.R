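# Shared fixtures for the test suite. Everything is built in code.

# The packaged base case, loaded once per test run.
base_cfg <- base_config()

# A uniform-cost schedule for both sectors: every recall cell costs
# `recall`, every initial cell `initial`, regardless of state/strategy.
flat_schedule <- function(initial = 1000, recall = 100) {
  rows <- list()
  for (sec in c("public", "private")) {
    for (strat in PERIO_STRATEGIES) {
      for (st in PERIO_STATES) {
        rows[[length(rows) + 1]] <- data.frame(
          sector = sec, visit = 0L, state = st, strategy = strat,
          cost_base = initial, cost_low = initial, cost_high = initial)
      }
    }
    for (v in 1:4) {
      for (st in PERIO_STATES) {
        rows[[length(rows) + 1]] <- data.frame(
          sector = sec, visit = v, state = st, strategy = NA_character_,
          cost_base = recall, cost_low = recall, cost_high = recall)
      }
    }
  }
  cost_schedule(do.call(rbind, rows))
}

# Random row-stochastic 3x3 matrix.
random_transition_matrix <- function() {
  m <- matrix(stats::rexp(9), 3, 3)
  transition_matrix(m / rowSums(m))
}

# An arm summary whose implied unstable proportion is exactly `p_unstable`
# (normal threshold model with sd 1), with BOP placing the controlled mass
# in stable (low BOP) or remission (high BOP).
arm_with_unstable <- function(p_unstable, n, bop = 0.05) {
  list(mean_ppd_mm = 4.5 - stats::qnorm(1 - p_unstable),
       sd_ppd_mm = 1,
       bop_fraction = bop,
       n = n)
}

# Deep-copy a config and overwrite one field by path (list of names).
mutate_cfg <- function(cfg, path, value) {
  expr <- Reduce(function(acc, k) call("[[", acc, k), path, quote(cfg))
  eval(call("<-", expr, value))
  cfg
}
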