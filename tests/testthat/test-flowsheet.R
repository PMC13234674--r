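test_that("chain_yield multiplies step yields", {
  expect_equal(chain_yield(c(0.98)), 0.98)
  expect_equal(chain_yield(c(1, 1, 1)), 1)

  # independent oracle: explicit cumulative multiplication of the six
  # product-bearing step yields of the baseline recipe
  yields <- c(0.98, 0.90, 0.95, 0.90, 0.97, 0.99)
  oracle <- 1
  for (y in yields) oracle <- oracle * y
  expect_equal(chain_yield(yields), oracle)
  expect_equal(oracle, 0.7241715, tolerance = 1e-6)

  # the default recipe's overall yield equals the product of its six
  # lossy steps (the remaining steps are unit-yield)
  expect_equal(chain_yield(tea_process()$steps), oracle)
})

test_that("chain_yield validates its input", {
  expect_error(chain_yield(numeric(0)), "no steps")
  expect_error(chain_yield(list()), "no steps")
  expect_error(chain_yield(c(0.9, 1.2)), "0, 1")
  expect_error(chain_yield(c(0.9, 0)), "0, 1")
  expect_error(reaction_step("s", 1.5, 2), "yield")
  expect_error(reaction_step("s", 0.9, -1), "duration")
})

test_that("chain_yield never increases as steps are appended", {
  set.seed(42)
  for (rep in 1:20) {
    y <- runif(8, 0.5, 1)
    partial <- vapply(seq_along(y),
                      function(k) chain_yield(y[1:k]), numeric(1))
    expect_true(all(diff(partial) <= 1e-12))
  }
})

test_that("batches_per_year floors the cycle count", {
  ct <- 7920 / 134
  expect_identical(batches_per_year(7920, ct), 134)
  expect_identical(batches_per_year(50, ct), 0)
  expect_identical(batches_per_year(8760, ct), floor(8760 / ct))
  expect_identical(batches_per_year(8760, ct), 148)
  expect_error(batches_per_year(0, ct), "positive")
  expect_error(batches_per_year(7920, -1), "positive")
})

test_that("batches_per_year is monotone in hours and cycle time", {
  hours <- seq(7200, 8760, by = 120)
  b <- batches_per_year(hours, 7920 / 134)
  expect_true(all(diff(b) >= 0))
  cycles <- seq(50, 120, by = 5)
  b2 <- vapply(cycles, function(ct) batches_per_year(7920, ct), numeric(1))
  expect_true(all(diff(b2) <= 0))
})

test_that("annual production matches the baseline plant and scales linearly", {
  mass <- 33000 / 134
  expect_equal(annual_production(134, mass), 33000, tolerance = 1 / 33000)
  expect_equal(annual_production(0, mass), 0)
  expect_equal(annual_production(148, mass), 36448, tolerance = 1 / 36448)
  expect_error(annual_production(-1, mass), "non-negative")
})

test_that("material demand scales linearly with batches", {
  proc <- tea_process()
  d1 <- material_demand(proc, 1)
  d134 <- material_demand(proc, 134)
  d0 <- material_demand(proc, 0)
  expect_equal(d134$material, d1$material * 134)
  expect_equal(d134$waste, d1$waste * 134)
  expect_true(all(d0$material == 0) && all(d0$waste == 0))
  expect_true(all(d134$material >= 0) && all(d134$waste >= 0))
  # a unit coefficient worth 10 kg/batch gives 1340 kg/yr at 134 batches
  proc2 <- tea_process(material_coef = c(quinaldine_cost = 10),
                       waste_coef = c(hcl_waste_cost = 10))
  expect_equal(material_demand(proc2, 134)$material[["quinaldine_cost"]],
               1340)
})

test_that("calibrated coefficients reproduce the baseline material bills", {
  proc <- tea_process()
  flows <- material_demand(proc, 134)
  prices <- baseline_inputs()
  raw_bill <- sum(flows$material * prices[names(flows$material)])
  waste_bill <- sum(flows$waste * prices[names(flows$waste)])
  expect_equal(raw_bill, 2143000, tolerance = 1e-9)
  expect_equal(waste_bill, 884000, tolerance = 1e-9)
})

test_that("flowsheet specification loads from a YAML file", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("cycle_time: 60.0",
               "steps:",
               "  - {id: A, yield: 0.9, duration: 10}",
               "  - {id: B, yield: 0.8, duration: 5, equipment: R-1}"), f)
  p <- load_flowsheet(f)
  expect_equal(p$cycle_time, 60)
  expect_equal(chain_yield(p$steps), 0.72)
  # omitted parts fall back to the calibrated baseline
  expect_equal(p$batch_mass, tea_process()$batch_mass)
  writeLines("bogus: 1", f)
  expect_error(load_flowsheet(f), "bogus")
  expect_error(load_flowsheet(tempfile()), "not found")
})

test_that("flowsheet spec validates cycle time and coefficients", {
  expect_error(tea_process(cycle_time = 0), "positive")
  expect_error(tea_process(material_coef = c(a = -1)), "non-negative")
  # the calibrated cycle lies inside the reported scheduling range
  ct <- tea_process()$cycle_time
  expect_gte(ct, 58.47)
  expect_lte(ct, 113.39)
})
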