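#' Year-by-year project cash-flow schedule
#'
#' Builds the net equity cash flows of the project over years
#' `0..lifetime`.  Capital is spent over the construction years according to
#' `construction_shares`; a loan covering `loan_fraction` of the DFC is drawn
#' in year 0 and amortized with equal principal payments over the sampled
#' loan period starting in the first operating year, with interest charged on
#' the outstanding balance.  Revenue and operating cost escalate with the
#' sampled inflation rate (year-0 money basis); the startup year runs at
#' reduced throughput, scaling revenue and the variable cost categories
#' (raw materials, waste treatment).  Income tax applies to revenue minus
#' operating cost, depreciation and interest, floored at zero (no refund on
#' losses).
#'
#' @param price Product selling price, USD/kg (year-0 basis).
#' @param production Annual production at full throughput, kg/yr.
#' @param opex A `tea_opex` from [compute_opex()].
#' @param inputs Named scenario-input vector (uses `inflation`,
#'   `income_tax`, `loan_interest`, `loan_period`).
#' @param assumptions A [tea_assumptions()].
#' @return An object of class `tea_cashflow`: a data.frame with one row per
#'   year and columns `year`, `capital`, `debt_draw`, `revenue`, `opex`,
#'   `depreciation`, `interest`, `principal`, `tax`, `net`.
#' @examples
#' proc <- tea_process()
#' flows <- material_demand(proc, 134)
#' opex <- compute_opex(baseline_inputs(), flows)
#' cf <- build_cash_flow(300, flows$production, opex, baseline_inputs())
#' npv(cf, 0.30)
#' @export
build_cash_flow <- function(price, production, opex, inputs,
                            assumptions = tea_assumptions()) {
  stopifnot(inherits(opex, "tea_opex"),
            inherits(assumptions, "tea_assumptions"))
  if (price < 0) stop("price must be non-negative")
  a <- assumptions
  n <- a$lifetime
  if (n <= length(a$construction_shares) - 1)
    stop("lifetime must exceed the construction period")
  years <- 0:n
  zeros <- numeric(n + 1)

  capital <- zeros
  idx <- seq_along(a$construction_shares)
  capital[idx] <- a$capex_total * a$construction_shares

  debt <- a$loan_fraction * a$dfc
  debt_draw <- zeros
  debt_draw[1] <- debt

  infl <- inputs[["inflation"]]
  esc <- (1 + infl)^years

  op_years <- years >= a$first_op_year
  startup <- years == a$first_op_year
  thr <- ifelse(op_years, ifelse(startup, a$startup_fraction, 1), 0)

  # The operating-cost total embeds the annual depreciation charge inside
  # the facility-dependent category; the cash operating cost excludes it
  # (depreciation is non-cash and enters only the taxable base below).
  # Startup: fixed cost in full, variable cost scaled with throughput.
  dep_embedded <- a$dfc / a$depreciation_period
  variable <- opex$raw_materials + opex$waste_treatment
  fixed <- opex$total - variable - dep_embedded
  revenue <- price * production * thr * esc
  opex_y <- ifelse(op_years, fixed + variable * thr, 0) * esc

  dep <- zeros
  dep_years <- years >= a$first_op_year &
    years < a$first_op_year + a$depreciation_period
  dep[dep_years] <- a$dfc / a$depreciation_period

  L <- max(1L, as.integer(round(inputs[["loan_period"]])))
  rate <- inputs[["loan_interest"]]
  interest <- zeros; principal <- zeros
  balance <- debt
  for (t in seq_len(n)) {         # years 1..n
    interest[t + 1] <- balance * rate
    if (years[t + 1] >= a$first_op_year && balance > 0) {
      pay <- min(debt / L, balance)
      principal[t + 1] <- pay
      balance <- balance - pay
    }
  }

  taxable <- revenue - opex_y - dep - interest
  tax <- pmax(taxable, 0) * inputs[["income_tax"]]

  net <- revenue - opex_y - interest - principal - tax - capital + debt_draw
  structure(data.frame(year = years, capital = capital,
                       debt_draw = debt_draw, revenue = revenue,
                       opex = opex_y, depreciation = dep,
                       interest = interest, principal = principal,
                       tax = tax, net = net),
            class = c("tea_cashflow", "data.frame"))
}

#' Net present value
#'
#' Discounted sum of net cash flows, `sum(CF_t / (1 + r)^t)`.
#'
#' @param schedule A `tea_cashflow`, or a numeric vector of net flows for
#'   years `0, 1, ...`.
#' @param r Discount rate (fraction, > -1).
#' @return NPV in USD.
#' @export
npv <- function(schedule, r) {
  if (r <= -1) stop("discount rate must exceed -1")
  cf <- if (is.data.frame(schedule)) schedule$net else schedule
  t <- if (is.data.frame(schedule)) schedule$year else seq_along(cf) - 1
  sum(cf / (1 + r)^t)
}

#' Internal rate of return
#'
#' The discount rate at which the NPV of a schedule is zero, found by
#' bracketing and bisection.  Requires the net-flow sequence to change sign;
#' with several sign changes the smallest positive root is returned with a
#' warning.
#'
#' @param schedule A `tea_cashflow` or numeric net-flow vector.
#' @param lower,upper Search interval for the rate.
#' @return The IRR as a fraction.
#' @export
irr <- function(schedule, lower = -0.99, upper = 20) {
  cf <- if (is.data.frame(schedule)) schedule$net else schedule
  s <- sign(cf[cf != 0])
  changes <- sum(diff(s) != 0)
  if (changes == 0) stop("IRR undefined: cash flows never change sign")
  if (changes > 1)
    warning("multiple sign changes in cash flows; returning the smallest positive root")
  f <- function(r) npv(schedule, r)
  grid <- sort(unique(c(seq(lower, 1, by = 0.05), seq(1, upper, by = 0.5))))
  fv <- vapply(grid, f, numeric(1))
  roots <- c()
  for (i in seq_len(length(grid) - 1)) {
    if (is.finite(fv[i]) && is.finite(fv[i + 1]) &&
        fv[i] * fv[i + 1] <= 0 && (fv[i] != 0 || i == 1)) {
      root <- stats::uniroot(f, c(grid[i], grid[i + 1]),
                             tol = 1e-10)$root
      roots <- c(roots, root)
    }
  }
  if (!length(roots)) stop("IRR undefined: no root in the search interval")
  pos <- roots[roots > 0]
  if (changes > 1 && length(pos)) min(pos) else roots[1]
}

#' Minimum product selling price
#'
#' The selling price at which the project NPV is zero at the target rate of
#' return, found by bisection on the price.  The NPV is strictly increasing
#' in the price, so the root is unique.
#'
#' @param production Annual production at full throughput, kg/yr.
#' @param opex A `tea_opex`.
#' @param inputs Named scenario-input vector.
#' @param target_irr Target rate of return (fraction).
#' @param assumptions A [tea_assumptions()].
#' @param bracket Price bracket, USD/kg.
#' @param tol Relative tolerance on the price.
#' @return MPSP in USD/kg.
#' @examples
#' proc <- tea_process()
#' flows <- material_demand(proc, 134)
#' opex <- compute_opex(baseline_inputs(), flows)
#' solve_mpsp(flows$production, opex, baseline_inputs(), 0.30)
#' @export
solve_mpsp <- function(production, opex, inputs, target_irr = 0.30,
                       assumptions = tea_assumptions(),
                       bracket = c(0, 10000), tol = 1e-6) {
  if (target_irr <= -1) stop("target_irr must exceed -1")
  if (production <= 0) stop("production must be positive")
  f <- function(p) npv(build_cash_flow(p, production, opex, inputs,
                                       assumptions), target_irr)
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) stop("MPSP outside bracket [", lo, ", ", hi, "]")
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (flo * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
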