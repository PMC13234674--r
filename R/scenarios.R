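#' Draw uniform scenario inputs
#'
#' Samples each of the 34 input variables independently from a uniform
#' distribution on its bounds, `X = X_min + U * (X_max - X_min)` with
#' `U ~ Unif(0, 1)`.
#'
#' @param n Number of scenarios.
#' @param seed Integer seed (the draw is reproducible for a fixed seed).
#' @param bounds Bounds table from [tea_bounds()].
#' @return An `n` x 34 numeric matrix, one column per variable.
#' @export
sample_inputs <- function(n, seed = 1L, bounds = tea_bounds()) {
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  m <- vapply(seq_len(nrow(bounds)), function(j)
    stats::runif(n, bounds$min[j], bounds$max[j]), numeric(n))
  m <- matrix(m, nrow = n)
  colnames(m) <- bounds$name
  m
}

#' Evaluate one scenario through the TEA engine
#'
#' Runs the flowsheet and economics models for one sampled input vector:
#' the realized batch count and production follow from the sampled annual
#' operation time, the operating cost from the sampled prices, and the MPSP
#' from a discounted-cash-flow solve at the scenario's target rate of
#' return.
#'
#' @param inputs Named vector of the 34 scenario inputs.
#' @param target_irr Target rate of return for the MPSP solve.
#' @param process A [tea_process()].
#' @param assumptions A [tea_assumptions()].
#' @param reference_price Optional selling price (USD/kg); when supplied the
#'   returned `irr` is the realized rate of return at that price instead of
#'   the target.
#' @return List with `upc`, `mpsp`, `irr`, `production`, `opex` (total) and
#'   `revenue` (at the MPSP).
#' @export
run_scenario <- function(inputs, target_irr = 0.30,
                         process = tea_process(),
                         assumptions = tea_assumptions(),
                         reference_price = NULL) {
  batches <- batches_per_year(inputs[["annual_operation_time"]],
                              process$cycle_time)
  flows <- material_demand(process, batches)
  opex <- compute_opex(inputs, flows, assumptions)
  upc <- compute_upc(opex, flows$production)
  mpsp <- solve_mpsp(flows$production, opex, inputs, target_irr,
                     assumptions)
  irr_out <- if (is.null(reference_price)) target_irr else
    irr(build_cash_flow(reference_price, flows$production, opex, inputs,
                        assumptions))
  list(upc = upc, mpsp = mpsp, irr = irr_out,
       production = flows$production, opex = opex$total,
       revenue = flows$production * mpsp)
}

#' Generate the Monte Carlo scenario dataset
#'
#' The synthetic-data stage of the pipeline: draws `n` scenarios uniformly
#' within the input bounds, draws a target rate of return per scenario, and
#' runs the full engine for each, producing the 37-column dataset (34 inputs,
#' `irr`, and the two targets `upc` and `mpsp`).  Scenarios whose MPSP solve
#' fails are resampled so exactly `n` rows are returned.
#'
#' @param n Number of scenarios.
#' @param seed Integer seed; the dataset is deterministic given the seed.
#' @param bounds Bounds table from [tea_bounds()].
#' @param process A [tea_process()].
#' @param assumptions A [tea_assumptions()].
#' @param irr_range Sampling interval for the target rate of return.
#' @return A data.frame of class `tea_scenarios` with `n` rows and 37
#'   columns, carrying `seed`, `n` and `irr_range` attributes.
#' @examples
#' ds <- tea_scenarios(25, seed = 7)
#' dim(ds)
#' @export
tea_scenarios <- function(n = 5000, seed = 1L, bounds = tea_bounds(),
                          process = tea_process(),
                          assumptions = tea_assumptions(),
                          irr_range = c(0.01, 0.50)) {
  if (n < 1) stop("n must be at least 1")
  x <- sample_inputs(n, seed = seed, bounds = bounds)
  set.seed(seed + 1L)
  irr_s <- stats::runif(n, irr_range[1], irr_range[2])
  upc <- numeric(n); mpsp <- numeric(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(run_scenario(x[i, ], irr_s[i], process, assumptions),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
    } else {
      upc[i] <- res$upc; mpsp[i] <- res$mpsp
    }
  }
  if (any(failed)) {
    message(sum(failed), " scenario(s) failed and were resampled")
    set.seed(seed + 2L)
    for (i in which(failed)) {
      repeat {
        xi <- vapply(seq_len(nrow(bounds)), function(j)
          stats::runif(1, bounds$min[j], bounds$max[j]), numeric(1))
        names(xi) <- bounds$name
        ri <- stats::runif(1, irr_range[1], irr_range[2])
        res <- tryCatch(run_scenario(xi, ri, process, assumptions),
                        error = function(e) e)
        if (!inherits(res, "error")) {
          x[i, ] <- xi; irr_s[i] <- ri
          upc[i] <- res$upc; mpsp[i] <- res$mpsp
          break
        }
      }
    }
  }
  out <- data.frame(x, irr = irr_s, upc = upc, mpsp = mpsp)
  attr(out, "seed") <- seed
  attr(out, "n") <- n
  attr(out, "irr_range") <- irr_range
  class(out) <- c("tea_scenarios", "data.frame")
  out
}

#' Write / read a scenario dataset as CSV
#'
#' The CSV round-trips losslessly (full double precision); the seed and
#' sampling metadata are stored in a comment header.
#'
#' @param x A `tea_scenarios` data.frame.
#' @param path File path.
#' @return `read_scenarios` returns the `tea_scenarios` data.frame.
#' @export
write_scenarios <- function(x, path) {
  stopifnot(inherits(x, "tea_scenarios"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# batchtea scenarios seed=%d n=%d irr_range=%.17g,%.17g",
                     attr(x, "seed"), attr(x, "n"),
                     attr(x, "irr_range")[1], attr(x, "irr_range")[2]), con)
  utils::write.csv(format(as.data.frame(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  meta <- regmatches(hdr, regexec(
    "seed=(-?\\d+) n=(\\d+) irr_range=([0-9.eE+-]+),([0-9.eE+-]+)", hdr))[[1]]
  if (length(meta) == 5) {
    attr(df, "seed") <- as.integer(meta[2])
    attr(df, "n") <- as.integer(meta[3])
    attr(df, "irr_range") <- as.numeric(meta[4:5])
  }
  class(df) <- c("tea_scenarios", "data.frame")
  df
}
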