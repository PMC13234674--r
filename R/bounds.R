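#' Uncertain input variables and their sampling bounds
#'
#' The 34 scenario inputs of the stochastic TEA: 10 raw-material unit prices,
#' 18 waste-stream treatment unit costs, the operator labor rate, four
#' financial parameters and the annual operation time.  Each variable carries
#' its baseline value and the uniform sampling interval used by the Monte
#' Carlo scenario generator.  Rates (inflation, income tax, loan interest) are
#' stored as decimal fractions.
#'
#' @param overrides Optional named list; each entry is a numeric vector
#'   `c(baseline, min, max)` replacing the default row of that variable.
#' @return A data.frame with columns `name`, `unit`, `baseline`, `min`,
#'   `max`, `group` and 34 rows.
#' @examples
#' b <- tea_bounds()
#' b[b$name == "labor_rate", ]
#' @export
tea_bounds <- function(overrides = NULL) {
  row <- function(name, unit, baseline, lo, hi, group)
    data.frame(name = name, unit = unit, baseline = baseline,
               min = lo, max = hi, group = group,
               stringsAsFactors = FALSE)
  b <- rbind(
    row("quinaldine_cost",           "USD/kg", 32.0, 16.0, 48.0, "raw"),
    row("isopropanol_cost",          "USD/kg", 1.1,  0.1,  1.5,  "raw"),
    row("nitrogen_cost",             "USD/kg", 1.0,  0.05, 1.5,  "raw"),
    row("sodium_carbonate_cost",     "USD/kg", 6.5,  3.0,  13.0, "raw"),
    row("hydroquinone_cost",         "USD/kg", 4.0,  2.0,  10.0, "raw"),
    row("carbon_tetrachloride_cost", "USD/kg", 0.8,  0.2,  2.0,  "raw"),
    row("chlorine_cost",             "USD/kg", 3.0,  2.0,  4.0,  "raw"),
    row("sodium_hydroxide_cost",     "USD/kg", 2.0,  0.5,  5.0,  "raw"),
    row("process_water_cost",        "USD/kg", 0.1,  0.01, 1.0,  "raw"),
    row("wash_water_cost",           "USD/kg", 0.1,  0.01, 1.0,  "raw"),
    row("ccl4_waste_cost",           "USD/kg", 5.0,  4.0,  6.0,  "waste"),
    row("co2_waste_cost",            "USD/kg", 5.0,  4.0,  6.0,  "waste"),
    row("isopropanol_waste_cost",    "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("naoh_waste_cost",           "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("charcoal_waste_cost",       "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("quinaldine_waste_cost",     "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("chloroquinaldine_waste_cost", "USD/kg", 2.0, 1.0, 3.0,  "waste"),
    row("product_waste_cost",        "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("product_crystal_waste_cost", "USD/kg", 2.0, 1.0,  3.0,  "waste"),
    row("impurity_waste_cost",       "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("product_na_waste_cost",     "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("chlorine_waste_cost",       "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("hcl_waste_cost",            "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("hydroquinone_na_waste_cost", "USD/kg", 2.0, 1.0,  3.0,  "waste"),
    row("methanol_waste_cost",       "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("sodium_carbonate_waste_cost", "USD/kg", 2.0, 1.0, 3.0,  "waste"),
    row("hydroquinone_waste_cost",   "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("nacl_waste_cost",           "USD/kg", 2.0,  1.0,  3.0,  "waste"),
    row("labor_rate",                "USD/h",  41.4, 5.0,  50.0, "labor"),
    row("inflation",                 "fraction/yr", 0.04, 0.01, 0.06, "financial"),
    row("income_tax",                "fraction", 0.40, 0.10, 0.50, "financial"),
    row("loan_interest",             "fraction/yr", 0.09, 0.01, 0.10, "financial"),
    row("loan_period",               "yr",     10.0, 3.0,  12.0, "financial"),
    row("annual_operation_time",     "h/yr",   7920, 7200, 8760, "operation")
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a named list")
    for (nm in names(overrides)) {
      i <- match(nm, b$name)
      if (is.na(i)) stop("unknown variable in overrides: ", nm)
      v <- overrides[[nm]]
      if (length(v) != 3L) stop("override for ", nm,
                                " must be c(baseline, min, max)")
      b$baseline[i] <- v[1]; b$min[i] <- v[2]; b$max[i] <- v[3]
    }
  }
  bad <- b$min >= b$max
  if (any(bad)) stop("invalid bounds (min >= max) for: ",
                     paste(b$name[bad], collapse = ", "))
  off <- b$baseline < b$min | b$baseline > b$max
  if (any(off)) stop("baseline outside bounds for: ",
                     paste(b$name[off], collapse = ", "))
  b
}

#' Baseline scenario inputs
#'
#' @param bounds A bounds table from [tea_bounds()].
#' @return Named numeric vector of the 34 baseline input values.
#' @export
baseline_inputs <- function(bounds = tea_bounds()) {
  stats::setNames(bounds$baseline, bounds$name)
}
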