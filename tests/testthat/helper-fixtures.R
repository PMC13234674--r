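# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# small Monte Carlo dataset for unit tests
small_dataset <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- tea_scenarios(120, seed = 301L)
  .fixtures$small
}

# full-scale dataset and fits shared by the acceptance tests
acceptance_dataset <- function() {
  if (is.null(.fixtures$full))
    .fixtures$full <- tea_scenarios(5000, seed = 2026L)
  .fixtures$full
}

acceptance_surrogate <- function() {
  if (is.null(.fixtures$fit))
    .fixtures$fit <- tea_surrogate(acceptance_dataset(), seed = 2026L)
  .fixtures$fit
}

# baseline engine objects
baseline_case <- function() {
  if (is.null(.fixtures$base)) {
    proc <- tea_process()
    asm <- tea_assumptions()
    inp <- baseline_inputs()
    batches <- batches_per_year(inp[["annual_operation_time"]],
                                proc$cycle_time)
    flows <- material_demand(proc, batches)
    opex <- compute_opex(inp, flows, asm)
    .fixtures$base <- list(process = proc, assumptions = asm,
                           inputs = inp, batches = batches,
                           flows = flows, opex = opex)
  }
  .fixtures$base
}

# synthetic regression problem with a planted linear support
planted_linear <- function(n = 400, p = 20, seed = 99L) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- cbind(t1 = 3 * x[, 2] - 2 * x[, 7] + 0.5 * x[, 13],
             t2 = 1.5 * x[, 2] + x[, 7] - 2 * x[, 13])
  list(x = x, y = y, support = c("f2", "f7", "f13"))
}
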