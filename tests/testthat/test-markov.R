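test_that("cohort propagation follows the per-cycle matrices", {
  ident <- transition_matrix(diag(3))
  tr <- run_cohort(ident, 4)
  expect_equal(dim(tr), c(5, 3))
  for (k in 1:5) expect_equal(as.numeric(tr[k, ]), c(0, 0, 1))

  uniform <- transition_matrix(matrix(1/3, 3, 3))
  tr2 <- run_cohort(uniform, 4)
  expect_equal(as.numeric(tr2[2, ]), rep(1/3, 3))

  scatter <- transition_matrix(rbind(c(1, 0, 0), c(0, 1, 0),
                                     c(0.5, 0.3, 0.2)))
  tr3 <- run_cohort(c(list(scatter), rep(list(ident), 3)), 4)
  for (k in 2:5) expect_equal(as.numeric(tr3[k, ]), c(0.5, 0.3, 0.2))

  expect_error(run_cohort(matrix(0.5, 3, 3), 4),
               class = "perioburden_domain_error")
  expect_error(run_cohort(list(ident), 4),
               class = "perioburden_validation_error")
})

test_that("trace rows conserve probability for random valid matrices", {
  set.seed(7)
  for (i in 1:100) {
    ms <- replicate(4, random_transition_matrix(), simplify = FALSE)
    tr <- run_cohort(ms, 4)
    expect_equal(rowSums(tr), rep(1, 5), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(tr >= 0 & tr <= 1))
  }
})

test_that("expected patient cost matches hand sums on degenerate traces", {
  sched <- base_cfg$cost_schedule
  all_stable <- transition_matrix(matrix(rep(c(1, 0, 0), each = 3), 3, 3))
  tr_stable <- run_cohort(all_stable, 4)
  expect_equal(expected_patient_cost(tr_stable, sched, "public", "NSPT_only"),
               2551.82 + 3 * 572.12 + 625.46)  # 4,893.64

  tr_unstable <- run_cohort(transition_matrix(diag(3)), 4)
  expect_equal(expected_patient_cost(tr_unstable, sched, "public", "NSPT_only"),
               2551.82 + 3 * 2373.78 + 3152.12)  # 12,825.28

  zero <- flat_schedule(initial = 0, recall = 0)
  expect_equal(expected_patient_cost(tr_unstable, zero, "public", "NSPT_only"),
               0)
})

test_that("blended per-patient cost lies between the all-stable and all-unstable sums", {
  res <- burden_pipeline(base_cfg)
  expect_gte(res$report$per_patient[["public"]], 4893.64)
  expect_lte(res$report$per_patient[["public"]], 12825.28)
  sched <- base_cfg$cost_schedule
  lo <- 4987.50 + 3 * 338.75 + 488.75
  hi <- 4987.50 + 3 * 4947.50 + 5885.00
  expect_gte(res$report$per_patient[["private"]], lo)
  expect_lte(res$report$per_patient[["private"]], hi)
})

test_that("the national burden is linear in counts and in single cost cells", {
  res <- burden_pipeline(base_cfg)
  rep1 <- blend_and_scale(res$per_strategy_costs,
                          strategy_mix(base_cfg$strategy_mix),
                          c(public = 66609, private = 17387))
  rep2 <- blend_and_scale(res$per_strategy_costs,
                          strategy_mix(base_cfg$strategy_mix),
                          c(public = 2 * 66609, private = 17387))
  expect_equal(rep2$sector_burden_myr[["public"]],
               2 * rep1$sector_burden_myr[["public"]])
  expect_equal(rep2$sector_burden_myr[["private"]],
               rep1$sector_burden_myr[["private"]])

  # bump one public recall cell by delta: burden moves by
  # delta * occupancy-weighted exposure * count, i.e. linearly
  cfg2 <- base_cfg
  sel <- cfg2$cost_schedule$sector == "public" &
    cfg2$cost_schedule$visit == 2 & cfg2$cost_schedule$state == "unstable"
  delta <- 100
  cfg2$cost_schedule$cost_base[sel] <- cfg2$cost_schedule$cost_base[sel] + delta
  cfg2$cost_schedule$cost_high[sel] <- cfg2$cost_schedule$cost_high[sel] + delta
  res2 <- burden_pipeline(cfg2)
  mix <- strategy_mix(base_cfg$strategy_mix)
  occ <- sum(vapply(names(res$traces), function(s) {
    mix[[s]] * res$traces[[s]][3, "unstable"]
  }, numeric(1)))
  expect_equal(res2$report$total_myr - res$report$total_myr,
               delta * occ * 66609, tolerance = 1e-6)
})

test_that("report arithmetic: sector totals, USD conversion, zero counts", {
  # cent-rounded per-patient figures recover the sector total to within the
  # rounding slack (half a cent per patient)
  rep <- blend_and_scale(list(public = 7277.30, private = 12139.24),
                         counts = c(public = 66609, private = 17387),
                         fx = 0.2382)
  expect_lte(abs(rep$sector_burden_myr[["public"]] - 484733861.59),
             0.005 * 66609)
  expect_equal(rep$total_usd, rep$total_myr * 0.2382)

  none <- blend_and_scale(list(public = 7277.30, private = 12139.24),
                          counts = c(public = 0, private = 0))
  expect_equal(none$total_myr, 0)
  expect_equal(none$total_usd, 0)
})

test_that("the microsimulation oracle agrees with the cohort expectation", {
  truth <- synthetic_truth(seed = 5)
  sched <- base_cfg$cost_schedule
  ms <- truth$true_matrices$NSPT_AMOX_MET
  expected <- expected_patient_cost(run_cohort(ms, 4), sched,
                                    "public", "NSPT_AMOX_MET")
  sim <- microsimulate_cohort(ms, sched, "public", "NSPT_AMOX_MET",
                              n_patients = 20000, seed = 11)
  expect_lt(abs(sim$mean - expected), 3 * sim$se)
})
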