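defs <- state_definitions()

test_that("summary-based state proportions match the threshold model", {
  far_below <- state_proportions_from_summary(
    list(mean_ppd_mm = 2.0, sd_ppd_mm = 0.5, bop_fraction = 0.05), defs)
  expect_lt(far_below[["unstable"]], 1e-6)
  expect_gt(far_below[["stable"]], 1 - 1e-6)

  far_above <- state_proportions_from_summary(
    list(mean_ppd_mm = 8.0, sd_ppd_mm = 0.5, bop_fraction = 0.5), defs)
  expect_gt(far_above[["unstable"]], 1 - 1e-6)

  at_cut <- state_proportions_from_summary(
    list(mean_ppd_mm = 4.5, sd_ppd_mm = 1.0, bop_fraction = 0.05), defs)
  expect_equal(unclass(at_cut),
               c(stable = 0.5, remission = 0, unstable = 0.5))

  # high BOP moves the controlled mass from stable to remission
  high_bop <- state_proportions_from_summary(
    list(mean_ppd_mm = 4.5, sd_ppd_mm = 1.0, bop_fraction = 0.25), defs)
  expect_equal(unclass(high_bop),
               c(stable = 0, remission = 0.5, unstable = 0.5))

  expect_error(state_proportions_from_summary(
    list(mean_ppd_mm = 4.5, sd_ppd_mm = 0, bop_fraction = 0.05), defs),
    class = "perioburden_domain_error")
})

test_that("p_unstable increases weakly with mean pocket depth", {
  means <- seq(2, 8, by = 0.25)
  p <- vapply(means, function(m) {
    state_proportions_from_summary(
      list(mean_ppd_mm = m, sd_ppd_mm = 1.1, bop_fraction = 0.2),
      defs)[["unstable"]]
  }, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("relative risks pool derived events across arms", {
  a <- arm_with_unstable(0.25, 100)
  expect_equal(pooled_relative_risk(list(a), list(a), "unstable"), 1)

  rr <- pooled_relative_risk(list(arm_with_unstable(0.4, 100)),
                             list(arm_with_unstable(0.2, 100)),
                             "unstable")
  expect_equal(rr, 2, tolerance = 1e-9)

  # pooled control proportion of (0.1 @ n=50, 0.3 @ n=150) is (5+45)/200
  rr2 <- pooled_relative_risk(
    list(arm_with_unstable(0.25, 200)),
    list(arm_with_unstable(0.1, 50), arm_with_unstable(0.3, 150)),
    "unstable")
  expect_equal(rr2, 0.25 / 0.25, tolerance = 1e-9)

  # zero pooled events trigger the continuity correction
  zero <- list(mean_ppd_mm = 2, sd_ppd_mm = 0, bop_fraction = 0.05, n = 100)
  ctl <- arm_with_unstable(0.2, 100)
  expect_message(
    rr3 <- pooled_relative_risk(list(zero), list(ctl), "unstable"),
    "continuity")
  expect_equal(rr3, (0.5 / 101) / (20.5 / 101), tolerance = 1e-9)
})

test_that("relative risks rescale and renormalise a control distribution", {
  ctl <- state_proportions(c(0.5, 0.3, 0.2))
  expect_equal(unclass(apply_rr(ctl, c(stable = 1, remission = 1, unstable = 1))),
               unclass(ctl))
  shifted <- apply_rr(ctl, c(stable = 1.2))
  expect_equal(unclass(shifted),
               c(stable = 0.6, remission = 0.3, unstable = 0.2) / 1.1)
  # products above 1 are clamped before renormalisation
  clamped <- apply_rr(ctl, c(stable = 10))
  expect_equal(unclass(clamped), c(1, 0.3, 0.2) / 1.5, ignore_attr = TRUE)
  expect_error(apply_rr(ctl, c(stable = 0, remission = 0, unstable = 0)),
               class = "perioburden_domain_error")
})

test_that("annual-to-cycle conversion uses the constant-rate formula", {
  expect_equal(annual_to_cycle(0, 4), 0)
  expect_equal(annual_to_cycle(0.75, 2), 0.5)
  expect_equal(annual_to_cycle(0.27, 4), 1 - 0.73^0.25)
  expect_error(annual_to_cycle(1, 4), class = "perioburden_domain_error")
  # inverse of independent per-cycle compounding, to near machine precision
  for (p in seq(0.05, 0.95, by = 0.1)) {
    expect_equal(1 - (1 - annual_to_cycle(p, 4))^4, p, tolerance = 1e-12)
  }
})

test_that("build_matrices assembles per-cycle, per-strategy matrix sets", {
  rows <- list(NSPT_only = c(0, 0, 1))
  ident <- build_matrices(rows,
                          stable_row_annual = c(1, 0, 0),
                          remission_row_annual = c(0, 1, 0))
  for (m in ident$NSPT_only) {
    expect_equal(unclass(m), diag(3), ignore_attr = TRUE)
  }

  # hand-checked entry-wise conversion then renormalisation
  got <- build_matrices(list(NSPT_only = c(0.45, 0.25, 0.30)),
                        stable_row_annual = c(0.6, 0.3, 0.1),
                        remission_row_annual = c(1/3, 1/3, 1/3))
  q <- 1 - (1 - c(0.6, 0.3, 0.1))^0.25
  expect_equal(as.numeric(got$NSPT_only[[1]][1, ]), q / sum(q))
  # uniform annual rows stay uniform after conversion
  expect_equal(as.numeric(got$NSPT_only[[1]][2, ]), rep(1/3, 3))

  # cycle 1 is strategy-specific, cycles 2+ share the maintenance row
  rows2 <- list(NSPT_only = c(0.45, 0.25, 0.30),
                NSPT_AMOX_MET = c(0.50, 0.25, 0.25))
  got2 <- build_matrices(rows2, c(0.7, 0.2, 0.1), c(0.3, 0.5, 0.2),
                         unstable_maintenance_row = c(0.35, 0.25, 0.40))
  expect_equal(as.numeric(got2$NSPT_AMOX_MET[[1]][3, ]), c(0.50, 0.25, 0.25))
  for (k in 2:4) {
    expect_equal(as.numeric(got2$NSPT_AMOX_MET[[k]][3, ]),
                 c(0.35, 0.25, 0.40))
    expect_equal(unclass(got2$NSPT_only[[k]]),
                 unclass(got2$NSPT_AMOX_MET[[k]]))
  }
})

test_that("every produced matrix is row-stochastic with entries in [0,1]", {
  set.seed(42)
  for (i in 1:50) {
    r <- function() {
      x <- stats::runif(3)
      x / sum(x)
    }
    ms <- build_matrices(list(NSPT_only = r()), r(), r())
    for (m in ms$NSPT_only) {
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(rowSums(m), rep(1, 3), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("matrix validation rejects malformed and absorbing inputs", {
  expect_error(transition_matrix(matrix(0.5, 3, 3)),
               class = "perioburden_domain_error")
  expect_error(transition_matrix(matrix(1, 2, 2)),
               class = "perioburden_domain_error")
  absorbing <- rbind(c(1, 0, 0), c(0.2, 0.5, 0.3), c(0.1, 0.2, 0.7))
  expect_error(transition_matrix(absorbing, require_irreducible = TRUE),
               class = "perioburden_domain_error")
  ok <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.2, 0.7))
  expect_silent(transition_matrix(ok, require_irreducible = TRUE))
})

test_that("arm-level derivation pools controls and applies strategy RRs", {
  truth <- synthetic_truth(seed = 3)
  rows <- derive_unstable_rows_from_arms(truth$arms, truth$defs)
  ctl <- truth$arms[truth$arms$arm == "control", ]
  props <- vapply(seq_len(nrow(ctl)), function(i) {
    unclass(state_proportions_from_summary(as.list(ctl[i, ]), truth$defs))
  }, numeric(3))
  pooled <- as.numeric(props %*% ctl$n) / sum(ctl$n)
  expect_equal(unclass(rows$NSPT_only), pooled, ignore_attr = TRUE)
  for (strat in c("NSPT_AMOX_MET", "NSPT_AZ")) {
    test <- truth$arms[truth$arms$arm == "test" &
                         truth$arms$strategy == strat, ]
    rr <- vapply(PERIO_STATES, function(st) {
      pooled_relative_risk(test, ctl, st, truth$defs)
    }, numeric(1))
    expect_equal(unclass(rows[[strat]]),
                 unclass(apply_rr(rows$NSPT_only, rr)))
  }
})
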