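# Baseline cost structure used for calibration (annual USD at baseline
# inputs): raw materials 2,143,000; facility-dependent 1,325,000;
# labor-dependent 1,238,000; laboratory/QC/QA 186,000; waste treatment
# 884,000; total 5,776,000.

.facility_factors <- c(maintenance = 0.06, insurance = 0.01,
                       local_taxes = 0.02, overhead = 0.05)

# Direct fixed capital: the unique value consistent with the baseline
# facility-dependent cost under the stated factors plus 10-yr straight-line
# depreciation: 1,325,000 = (0.14 + 0.10) * DFC.
.default_dfc <- 1325000 / (sum(.facility_factors) + 1 / 10)

# Operator hours at the 7,920 h/yr design availability, back-solved from the
# baseline labor-dependent cost at 41.4 USD/h with admin + supervision
# factors (0.1, 0.2): 1,238,000 = hours * 41.4 * 1.3.
.default_operator_hours <- 1238000 / (41.4 * 1.3)

# Laboratory/QC/QA as a fixed ratio of labor-dependent cost (186/1238).
.lab_ratio <- 186000 / 1238000

#' Financial and plant-level assumptions
#'
#' Fixed (non-sampled) assumptions of the discounted-cash-flow model.  The
#' defaults describe the baseline plant: a 15-year project horizon, a
#' 30-month construction period (capital spent 40/40/20% over years 0-2),
#' a 4-month startup at reduced throughput in the first operating year,
#' 10-year straight-line depreciation of the direct fixed capital (DFC),
#' and 40% of the DFC financed by an equal-principal loan.
#'
#' @param lifetime Project horizon in years; cash flows run over years
#'   `0..lifetime`.
#' @param construction_shares Fractions of total capital spent in years
#'   `0..length(construction_shares)-1`; must sum to 1.
#' @param first_op_year First year with production (startup year).
#' @param startup_fraction Throughput fraction in the startup year.
#' @param depreciation_period Straight-line depreciation period, years.
#' @param capex_total Total capital investment, USD.
#' @param dfc Direct fixed capital, USD (depreciable; basis of the
#'   facility factors and of the loan).
#' @param facility_factors Named fractions of DFC charged annually
#'   (maintenance, insurance, local taxes, overhead).
#' @param loan_fraction Fraction of DFC financed by debt.
#' @param operator_hours Annual operator hours at `operator_hours_basis`
#'   hours of plant availability; scaled proportionally with the sampled
#'   annual operation time.
#' @param operator_hours_basis Availability (h/yr) at which
#'   `operator_hours` applies.
#' @param lab_ratio Laboratory/QC/QA cost as a fraction of the
#'   labor-dependent cost.
#' @param marr Minimum attractive rate of return used for feasibility
#'   screening.
#' @return An object of class `tea_assumptions`.
#' @export
tea_assumptions <- function(lifetime = 15,
                            construction_shares = c(0.4, 0.4, 0.2),
                            first_op_year = 2,
                            startup_fraction = 0.5,
                            depreciation_period = 10,
                            capex_total = 7066000,
                            dfc = .default_dfc,
                            facility_factors = .facility_factors,
                            loan_fraction = 0.4,
                            operator_hours = .default_operator_hours,
                            operator_hours_basis = 7920,
                            lab_ratio = .lab_ratio,
                            marr = 0.30) {
  if (abs(sum(construction_shares) - 1) > 1e-8)
    stop("construction_shares must sum to 1")
  if (lifetime <= length(construction_shares) - 1)
    stop("lifetime must exceed the construction period")
  if (first_op_year > lifetime) stop("first_op_year beyond lifetime")
  fr <- c(startup_fraction, loan_fraction, facility_factors, marr)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (dfc <= 0 || capex_total <= 0) stop("capital values must be positive")
  structure(list(lifetime = lifetime,
                 construction_shares = construction_shares,
                 first_op_year = first_op_year,
                 startup_fraction = startup_fraction,
                 depreciation_period = depreciation_period,
                 capex_total = capex_total, dfc = dfc,
                 facility_factors = facility_factors,
                 loan_fraction = loan_fraction,
                 operator_hours = operator_hours,
                 operator_hours_basis = operator_hours_basis,
                 lab_ratio = lab_ratio, marr = marr),
            class = "tea_assumptions")
}

#' Administration and supervision burden factors
#'
#' Tiered overhead on the operator wage: cheaper labor carries a relatively
#' larger administrative and supervisory burden.  The administration ladder
#' is 0.9 (below 5 USD/h), 0.5 (5-10), 0.3 (10-15), 0.2 (15-18, bridging
#' tier) and 0.1 (above 18); supervision mirrors it from 0.8 at the lowest
#' wages to 0.2 at the highest.
#'
#' @param rate Operator labor rate, USD/h.
#' @return Named vector `c(administration, supervision)`.
#' @examples
#' labor_factors(41.4) # c(0.1, 0.2)
#' @export
labor_factors <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("labor rate must be a single positive value")
  tier <- findInterval(rate, c(5, 10, 15, 18)) + 1L
  admin <- c(0.9, 0.5, 0.3, 0.2, 0.1)[tier]
  superv <- c(0.8, 0.5, 0.3, 0.2, 0.2)[tier]
  c(administration = admin, supervision = superv)
}

#' Annual operating cost breakdown
#'
#' Composes the five operating-cost categories for one scenario:
#' raw materials (annual demand times sampled unit prices), the
#' facility-dependent charge (DFC factors plus straight-line depreciation),
#' the labor-dependent cost (operator hours scaled with operation time,
#' times the wage and its tiered burden factors), laboratory/QC/QA as a
#' fixed ratio of labor, and waste treatment (stream masses times sampled
#' unit costs).
#'
#' @param inputs Named vector of scenario inputs (see [tea_bounds()]).
#' @param flows A `tea_batch` from [material_demand()].
#' @param assumptions A [tea_assumptions()].
#' @return An object of class `tea_opex`: the five categories plus `total`,
#'   all USD/yr.
#' @examples
#' proc <- tea_process()
#' flows <- material_demand(proc, 134)
#' compute_opex(baseline_inputs(), flows, tea_assumptions())
#' @export
compute_opex <- function(inputs, flows, assumptions = tea_assumptions()) {
  stopifnot(inherits(flows, "tea_batch"),
            inherits(assumptions, "tea_assumptions"))
  need <- names(flows$material)
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing price for material: ",
                         paste(miss, collapse = ", "))
  missw <- setdiff(names(flows$waste), names(inputs))
  if (length(missw)) stop("missing price for waste stream: ",
                          paste(missw, collapse = ", "))
  raw <- sum(flows$material * inputs[names(flows$material)])
  waste <- sum(flows$waste * inputs[names(flows$waste)])
  hours <- assumptions$operator_hours *
    inputs[["annual_operation_time"]] / assumptions$operator_hours_basis
  lf <- labor_factors(inputs[["labor_rate"]])
  labor <- hours * inputs[["labor_rate"]] * (1 + sum(lf))
  facility <- sum(assumptions$facility_factors) * assumptions$dfc +
    assumptions$dfc / assumptions$depreciation_period
  lab <- assumptions$lab_ratio * labor
  out <- list(raw_materials = raw, facility_dependent = facility,
              labor_dependent = labor, lab_qc_qa = lab,
              waste_treatment = waste)
  out$total <- sum(unlist(out))
  structure(out, class = "tea_opex")
}

#' @export
print.tea_opex <- function(x, ...) {
  cats <- setdiff(names(x), "total")
  v <- unlist(x[cats])
  df <- data.frame(`USD/yr` = round(v),
                   `share %` = round(100 * v / x$total, 2),
                   check.names = FALSE)
  print(df)
  cat("total (OPEX): ", format(round(x$total), big.mark = ","), " USD/yr\n",
      sep = "")
  invisible(x)
}

#' Unit production cost
#'
#' Annual operating cost divided by annual production.
#'
#' @param opex Annual operating cost, USD/yr (or a `tea_opex`).
#' @param production Annual production, kg/yr.
#' @return UPC in USD/kg.
#' @export
compute_upc <- function(opex, production) {
  if (inherits(opex, "tea_opex")) opex <- opex$total
  if (production <= 0) stop("annual production must be positive")
  opex / production
}
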