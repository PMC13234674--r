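test_that("npv equals a brute-force discounted sum", {
  expect_equal(npv(c(-100, 110), 0.10), 0, tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:10) {
    cf <- runif(16, -5e6, 5e6)
    r <- runif(1, -0.5, 0.8)
    brute <- 0
    for (t in seq_along(cf)) brute <- brute + cf[t] / (1 + r)^(t - 1)
    expect_equal(npv(cf, r), brute, tolerance = 1e-9)
    expect_equal(npv(cf, 0), sum(cf), tolerance = 1e-12)
  }
  expect_error(npv(c(-1, 2), -1), "exceed -1")
})

test_that("npv decreases in the rate for front-loaded outflows", {
  base <- baseline_case()
  cf <- build_cash_flow(300, 33000, base$opex, base$inputs,
                        base$assumptions)
  rates <- seq(0.01, 0.8, by = 0.05)
  vals <- vapply(rates, function(r) npv(cf, r), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("irr recovers analytic roots and rejects rootless flows", {
  expect_equal(irr(c(-100, 110)), 0.10, tolerance = 1e-6)
  expect_error(irr(c(100, 110)), "sign")
  base <- baseline_case()
  price <- solve_mpsp(33000, base$opex, base$inputs, 0.30,
                      base$assumptions)
  cf <- build_cash_flow(price, 33000, base$opex, base$inputs,
                        base$assumptions)
  expect_equal(irr(cf), 0.30, tolerance = 1e-4)
})

test_that("cash-flow schedule has the documented shape", {
  base <- baseline_case()
  a <- base$assumptions
  cf <- build_cash_flow(300, 33000, base$opex, base$inputs, a)
  expect_equal(nrow(cf), a$lifetime + 1)
  expect_equal(cf$year, 0:a$lifetime)
  # construction years are net outflows at the baseline
  expect_true(all(cf$net[1:2] < 0))
  # capital follows the construction split
  expect_equal(cf$capital[1:3], a$capex_total * a$construction_shares)
  # zero selling price: every operating year is strictly negative
  cf0 <- build_cash_flow(0, 33000, base$opex, base$inputs, a)
  expect_true(all(cf0$net[cf0$year >= a$first_op_year] < 0))
  expect_error(build_cash_flow(-5, 33000, base$opex, base$inputs, a),
               "non-negative")
})

test_that("simplified schedule matches a hand-computed toy oracle", {
  base <- baseline_case()
  inp <- base$inputs
  inp["income_tax"] <- 0; inp["inflation"] <- 0
  a <- tea_assumptions(lifetime = 3, construction_shares = 1,
                       first_op_year = 1, startup_fraction = 1,
                       loan_fraction = 0)
  cf <- build_cash_flow(250, 33000, base$opex, inp, a)
  # by hand: year 0 pays all capital; each operating year earns revenue
  # minus cash operating cost (total minus embedded depreciation)
  cash_opex <- base$opex$total - a$dfc / a$depreciation_period
  expect_equal(cf$net[1], -a$capex_total)
  expect_equal(cf$net[2:4], rep(250 * 33000 - cash_opex, 3))
})

test_that("solve_mpsp finds the zero-NPV price", {
  base <- baseline_case()
  p30 <- solve_mpsp(33000, base$opex, base$inputs, 0.30, base$assumptions)
  cf <- build_cash_flow(p30, 33000, base$opex, base$inputs,
                        base$assumptions)
  expect_equal(npv(cf, 0.30), 0, tolerance = 1e-4 * base$opex$total)
  # grid-scan oracle: the sign change of NPV(price) lies within one
  # 0.01-USD grid step of the reported root
  grid <- seq(p30 - 0.5, p30 + 0.5, by = 0.01)
  vals <- vapply(grid, function(p)
    npv(build_cash_flow(p, 33000, base$opex, base$inputs,
                        base$assumptions), 0.30), numeric(1))
  flip <- which(diff(sign(vals)) != 0)[1]
  expect_lte(abs(grid[flip] - p30), 0.011)
  expect_error(solve_mpsp(33000, base$opex, base$inputs, 0.30,
                          base$assumptions, bracket = c(5000, 10000)),
               "bracket")
})

test_that("MPSP is monotone in the target return and in operating cost", {
  base <- baseline_case()
  prices <- vapply(c(0.05, 0.20, 0.30, 0.35, 0.50), function(r)
    solve_mpsp(33000, base$opex, base$inputs, r, base$assumptions),
    numeric(1))
  expect_true(all(diff(prices) > 0))
  # inflate every category by 20%
  op2 <- base$opex
  for (nm in names(op2)) op2[[nm]] <- op2[[nm]] * 1.2
  p2 <- solve_mpsp(33000, op2, base$inputs, 0.30, base$assumptions)
  expect_gt(p2, prices[3])
  # MPSP at a non-negative target never undercuts the UPC
  upc <- compute_upc(base$opex, 33000)
  expect_gt(prices[1], upc)
})

test_that("long-horizon MPSP approaches the annuity closed form", {
  # with no tax, no inflation, no debt, capital all in year 0 and a
  # negligible facility charge, MPSP -> UPC + capex * r / production
  b <- tea_bounds()
  inp <- baseline_inputs(b)
  inp["income_tax"] <- 0; inp["inflation"] <- 0
  a <- tea_assumptions(lifetime = 200, construction_shares = 1,
                       first_op_year = 1, startup_fraction = 1,
                       loan_fraction = 0, dfc = 1e-3)
  flows <- material_demand(tea_process(), 134)
  op <- compute_opex(inp, flows, a)
  r <- 0.10
  p <- solve_mpsp(flows$production, op, inp, r, a)
  closed <- compute_upc(op, flows$production) +
    a$capex_total * r / flows$production
  expect_equal(p, closed, tolerance = 0.02)
})
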