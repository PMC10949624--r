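test_that("GDP deflation scales proportionally and inverts", {
  expect_equal(deflate_cost(100, 95, 95), 100)
  expect_equal(deflate_cost(100, 100, 110), 110)
  expect_equal(round_cents(deflate_cost(2511.30, 98.4, 100)), 2552.13)
  for (x in c(0.01, 57.3, 2551.82)) {
    expect_equal(deflate_cost(deflate_cost(x, 98.4, 103.2), 103.2, 98.4), x)
  }
  expect_error(deflate_cost(100, 0, 100), class = "perioburden_domain_error")
})

test_that("visit costs are receipt-proportion-weighted sums", {
  one <- data.frame(unit_cost = 572.12, receipt_proportion = 1)
  expect_equal(weighted_visit_cost(one), 572.12)
  two <- data.frame(unit_cost = c(100, 200), receipt_proportion = c(0.5, 0.25))
  expect_equal(weighted_visit_cost(two), 100)
  none <- data.frame(unit_cost = c(10, 20), receipt_proportion = c(0, 0))
  expect_equal(weighted_visit_cost(none), 0)
  expect_error(weighted_visit_cost(data.frame()),
               class = "perioburden_domain_error")
  # deflation applied per procedure when deflators are provided
  defl <- data.frame(unit_cost = 100, receipt_proportion = 1,
                     base_year_deflator = 50)
  expect_equal(weighted_visit_cost(defl, target_year_deflator = 100), 200)
})

test_that("strategy blending of the initial visit matches hand sums", {
  sched <- base_cfg$cost_schedule
  mix <- strategy_mix()
  expect_equal(blend_initial_cost(sched, mix, "public"), 2553.44)
  expect_equal(blend_initial_cost(sched, mix, "private"), 4995.50)
  expect_equal(blend_initial_cost(sched, c(NSPT_only = 1), "public"), 2551.82)
  # blended cost lies within the per-strategy cell range
  cells <- vapply(PERIO_STRATEGIES, function(s) {
    schedule_cell(sched, "public", 0L, "unstable", s)
  }, numeric(1))
  b <- blend_initial_cost(sched, mix, "public")
  expect_gte(b, min(cells))
  expect_lte(b, max(cells))
})

test_that("sensitivity variants scale public cells and swap private bounds", {
  sched <- base_cfg$cost_schedule
  lo <- cost_range_variant(sched, "low")
  hi <- cost_range_variant(sched, "high")
  expect_equal(schedule_cell(lo, "public", 1, "stable"), 457.70)
  expect_equal(schedule_cell(hi, "public", 1, "stable"), 686.54)
  expect_equal(schedule_cell(hi, "private", 4, "unstable"), 9600.00)
  expect_equal(schedule_cell(lo, "private", 4, "unstable"), 2170.00)
  # variants preserve the cell ordering low <= base <= high everywhere
  expect_true(all(lo$cost_base <= sched$cost_base + 1e-9))
  expect_true(all(sched$cost_base <= hi$cost_base + 1e-9))
  # the packaged public bounds are exactly the +/-20% scaling
  pub <- sched[sched$sector == "public", ]
  expect_equal(pub$cost_low, round_cents(pub$cost_base * 0.8))
  expect_equal(pub$cost_high, round_cents(pub$cost_base * 1.2))
})

test_that("the packaged schedule satisfies its structural invariants", {
  sched <- base_cfg$cost_schedule
  # recall visits: stable <= remission <= unstable within each sector
  for (sec in c("public", "private")) {
    for (v in 1:4) {
      costs <- vapply(PERIO_STATES, function(st) {
        schedule_cell(sched, sec, v, st)
      }, numeric(1))
      expect_true(all(diff(costs) >= 0), info = paste(sec, v))
    }
  }
  # recall visits 1-3 share identical cells
  for (sec in c("public", "private")) {
    v1 <- sched[sched$sector == sec & sched$visit == 1,
                c("state", "cost_base")]
    for (v in 2:3) {
      vk <- sched[sched$sector == sec & sched$visit == v,
                  c("state", "cost_base")]
      expect_equal(vk$cost_base[match(v1$state, vk$state)], v1$cost_base)
    }
  }
})

test_that("schedule lookups fail loudly on missing or ambiguous cells", {
  sched <- base_cfg$cost_schedule
  expect_error(schedule_cell(sched, "public", 0, "unstable"),
               class = "perioburden_validation_error")
  expect_error(schedule_cell(sched, "public", 5, "stable"),
               class = "perioburden_validation_error")
  expect_error(strategy_mix(c(NSPT_only = 0.5)),
               class = "perioburden_validation_error")
  expect_error(blend_initial_cost(sched, c(bogus = 1), "public"),
               class = "perioburden_validation_error")
})
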