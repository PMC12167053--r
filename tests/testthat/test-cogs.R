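test_that("required_units matches hand arithmetic and handles exact multiples", {
  # ceil(1e14 / (2.45e13 * 0.30)) = ceil(13.605...) = 14
  expect_identical(required_units(1e14, 2.45e13, 0.30), 14L)
  expect_identical(required_units(0, 2.45e13, 0.30), 0L)
  expect_identical(required_units(6.81e13 * 0.30, 6.81e13, 0.30), 1L)
  expect_error(required_units(1e14, 0, 0.3), "per_unit_yield_vg")
  expect_error(required_units(1e14, 1e13, 0), "dsp_recovery")
  expect_error(required_units(1e14, 1e13, 1.2), "dsp_recovery")
})

test_that("required_units is exact at integer multiples and monotone", {
  set.seed(42)
  for (rep in 1:25) {
    y <- runif(1, 1e12, 2e14)
    r <- runif(1, 0.05, 1)
    n <- sample(1:50, 1)
    expect_identical(required_units(n * y * r, y, r), as.integer(n))
  }
  # non-decreasing in target, non-increasing in yield and recovery
  targets <- sort(runif(20, 0, 1e15))
  u <- vapply(targets, required_units, integer(1),
              per_unit_yield_vg = 3e13, dsp_recovery = 0.3)
  expect_true(all(diff(u) >= 0))
  yields <- sort(runif(20, 1e12, 1e14))
  uy <- vapply(yields, function(y) required_units(5e14, y, 0.3), integer(1))
  expect_true(all(diff(uy) <= 0))
  recs <- sort(runif(20, 0.05, 1))
  ur <- vapply(recs, function(r) required_units(5e14, 3e13, r), integer(1))
  expect_true(all(diff(ur) <= 0))
})

test_that("ten closed hollow-fiber systems fit one production with one MSC and two operators", {
  s <- gen_reference_scenario()
  plan <- plan_batches(10, s$platforms$Quantum, s$processes$Quantum, s$facility)
  expect_equal(nrow(plan$productions), 1)
  expect_equal(plan$mscs_used, 1)
  expect_equal(plan$operators_assigned, 2)
  expect_equal(plan$units_required, 10L)
  # 10 x 0.6 m^2 bench space for the systems themselves
  expect_equal(10 * s$platforms$Quantum$footprint_m2, 6.0)
  expect_lte(plan$area_used_m2, s$facility$area_m2)
})

test_that("zero units give an empty plan with no days", {
  s <- gen_reference_scenario()
  plan <- plan_batches(0, s$platforms$Quantum, s$processes$Quantum, s$facility)
  expect_equal(nrow(plan$productions), 0)
  expect_equal(plan$total_days, 0L)
  expect_equal(plan$area_used_m2, 0)
})

test_that("capacity-capped batches split into sequential productions", {
  pl <- tiny_platform(units_per_msc_session = 6)
  fac <- tiny_facility(max_mscs = 1)  # cap = 6 units per production
  pd <- one_step_process(day = 4)     # 5-day schedule
  plan <- plan_batches(12, pl, pd, fac)
  expect_equal(plan$productions$units, c(6L, 6L))
  expect_equal(plan$total_days, 2L * pd$batch_duration_days)
  expect_equal(sum(plan$productions$units), plan$units_required)
})

test_that("an infeasible single unit raises a capacity error naming the constraint", {
  pl <- tiny_platform(footprint_m2 = 100)
  expect_error(plan_batches(1, pl, one_step_process(), tiny_facility()),
               "capacity error.*area")
})

test_that("greedy packing matches the exhaustive minimal production count", {
  # small capacity bounds driven through MSC throughput, MSC cap and area
  configs <- expand.grid(per_msc = c(1, 2, 3, 5), max_mscs = 1:3,
                         area = c(12, 60))
  pd <- one_step_process()
  for (i in seq_len(nrow(configs))) {
    pl <- tiny_platform(units_per_msc_session = configs$per_msc[i])
    fac <- tiny_facility(area_m2 = configs$area[i],
                         max_mscs = configs$max_mscs[i])
    # feasibility recomputed from first principles for the oracle
    feas <- Filter(function(n) {
      mscs <- ceiling(n / configs$per_msc[i])
      ops <- 2 * mscs
      mscs <= configs$max_mscs[i] &&
        (mscs * 3 + ops * 2) <= configs$area[i]
    }, 1:30)
    for (units in c(0:10, 17, 23, 30)) {
      oracle <- brute_min_productions(units, feas)
      if (is.na(oracle)) {
        expect_error(plan_batches(units, pl, pd, fac), "capacity error")
      } else {
        plan <- plan_batches(units, pl, pd, fac)
        expect_equal(nrow(plan$productions), oracle,
                     info = sprintf("config %d, units %d", i, units))
      }
    }
  }
})

test_that("cost_of_batch reproduces hand arithmetic", {
  # 1 unit, material qty 2 at cost 5, 2 h x 1 operator at rate 10,
  # 1 day at facility rate 100, no QC: 10 + 20 + 100 = 130
  pl <- tiny_platform()
  fac <- tiny_facility(operator_cost_per_hour = 10, facility_cost_per_day = 100)
  cat <- cost_catalog(items = list(m = list(unit_cost = 5, unit = "ea")))
  pd <- one_step_process(duration_hours = 2, operators = 1,
                         materials = list(list(item = "m", quantity = 2,
                                               basis = "per_unit")))
  rep <- cost_of_batch(plan_batches(1, pl, pd, fac), pd, cat, fac)
  expect_equal(rep$materials_cost, 10)
  expect_equal(rep$labor_cost, 20)
  expect_equal(rep$facility_cost, 100)
  expect_equal(rep$qc_cost, 0)
  expect_equal(rep$total_cost, 130)
})

test_that("QC samples share whole analytical plates", {
  pl <- tiny_platform()
  fac <- tiny_facility(operator_cost_per_hour = 0, facility_cost_per_day = 0)
  cat <- cost_catalog(items = list(), qc_cost_per_plate = 960,
                      qc_samples_per_plate = 96)
  pd <- one_step_process(qc_samples = 7)
  rep <- cost_of_batch(plan_batches(1, pl, pd, fac), pd, cat, fac)
  expect_equal(rep$qc_cost, 960)  # 7 samples still cost one full plate
  pd97 <- one_step_process(qc_samples = 97)
  rep97 <- cost_of_batch(plan_batches(1, pl, pd97, fac), pd97, cat, fac)
  expect_equal(rep97$qc_cost, 2 * 960)
})

test_that("a zero-unit plan is charged per-batch items and open steps only", {
  pl <- tiny_platform()
  fac <- tiny_facility(operator_cost_per_hour = 10, facility_cost_per_day = 100)
  cat <- cost_catalog(items = list(pb = list(unit_cost = 7, unit = "ea"),
                                   pu = list(unit_cost = 100, unit = "ea")))
  pd <- one_step_process(
    duration_hours = 5, operators = 2, open_per_unit = 4, open_per_batch = 3,
    materials = list(list(item = "pb", quantity = 2, basis = "per_batch"),
                     list(item = "pu", quantity = 1, basis = "per_unit")))
  rep <- cost_of_batch(plan_batches(0, pl, pd, fac), pd, cat, fac)
  expect_equal(rep$total_cost, 14)       # only the per-batch line
  expect_equal(rep$open_steps, 3L)       # only per-batch manipulations
  expect_equal(rep$production_days, 0L)
})

test_that("a missing catalog item surfaces as a dangling-reference error", {
  pl <- tiny_platform()
  fac <- tiny_facility()
  pd <- one_step_process(materials = list(list(item = "ghost", quantity = 1,
                                               basis = "per_unit")))
  expect_error(cost_of_batch(plan_batches(1, pl, pd, fac), pd,
                             cost_catalog(items = list()), fac),
               "ghost")
})

test_that("open steps scale affinely in unit count", {
  pl <- tiny_platform(units_per_msc_session = 100)
  fac <- tiny_facility(area_m2 = 1000)
  cat <- cost_catalog(items = list())
  pd <- one_step_process(open_per_unit = 3, open_per_batch = 5)
  open <- vapply(c(1, 4, 9, 20), function(n) {
    cost_of_batch(plan_batches(n, pl, pd, fac), pd, cat, fac)$open_steps
  }, integer(1))
  expect_equal(open, 3 * c(1, 4, 9, 20) + 5L)
})

test_that("cost and days are non-decreasing in the target output", {
  s <- gen_reference_scenario()
  sweep <- seq(5e13, 1e15, length.out = 12)
  for (pl in names(s$processes)) {
    reps <- lapply(sweep, function(tv) run_cog(s, pl, tv))
    expect_true(all(diff(vapply(reps, `[[`, numeric(1), "total_cost")) >= 0))
    expect_true(all(diff(vapply(reps, function(r) as.numeric(r$production_days),
                                numeric(1))) >= 0))
  }
})

test_that("reference-vs-reference fold changes are exactly 1", {
  s <- gen_reference_scenario()
  tab <- compare_platforms(s, "Quantum", c(1e14, 5e14, 1e15))
  ref <- tab[tab$platform == "Quantum", ]
  expect_true(all(ref$fold_cost == 1))
  expect_true(all(ref$fold_open_steps == 1))
  expect_true(all(ref$fold_days == 1))
})

test_that("fold changes are invariant under global price rescaling", {
  s <- gen_reference_scenario()
  s2 <- s
  for (id in names(s2$catalog$items)) {
    s2$catalog$items[[id]]$unit_cost <- s2$catalog$items[[id]]$unit_cost * 7
  }
  s2$facility$operator_cost_per_hour <- s$facility$operator_cost_per_hour * 7
  s2$facility$facility_cost_per_day <- s$facility$facility_cost_per_day * 7
  s2$catalog$qc_cost_per_plate <- s$catalog$qc_cost_per_plate * 7
  t1 <- compare_platforms(s, "Quantum", c(1e14, 1e15))
  t2 <- compare_platforms(s2, "Quantum", c(1e14, 1e15))
  expect_equal(t2$fold_cost, t1$fold_cost, tolerance = 1e-12)
  expect_equal(t2$total_cost, 7 * t1$total_cost, tolerance = 1e-12)
})

test_that("doses_from_batch floors whole doses after recovery", {
  expect_identical(doses_from_batch(6.81e13, 0.30, 1.5e11), 136L)
  expect_identical(doses_from_batch(1e10, 0.30, 1.5e11), 0L)
  expect_identical(doses_from_batch(1.5e11, 1.0, 1.5e11), 1L)
  expect_error(doses_from_batch(1e13, 0.3, 0), "dose_vg")
})

test_that("capacity errors in a sweep are annotated with platform and target", {
  s <- gen_reference_scenario()
  s$platforms$CS10$footprint_m2 <- 500  # no single unit fits
  expect_error(compare_platforms(s, "Quantum", 1e14), "CS10.*1e\\+?14")
})
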