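.config_defaults <- function() {
  list(n_scenarios = 5000, seed = 1L, marr = 0.30, irr_range = c(0.01, 0.50),
       upc_window = c(140, 240), models = .tea_model_names,
       select_features = TRUE, cv_folds = 5, train_fraction = 0.8,
       tune = FALSE, tune_iterations = 30,
       bounds_overrides = NULL, out_dir = "tea_output")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults (`n_scenarios = 5000`, `seed = 1`,
#' `marr = 0.30`, ...) and rejects unknown keys.  `bounds_overrides`
#' entries are checked against the variable table at load time.
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return A validated list of class `tea_config`.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$n_scenarios
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg$n_scenarios <- as.integer(cfg$n_scenarios); cfg$seed <- as.integer(cfg$seed)
  if (cfg$n_scenarios < 1) stop("n_scenarios must be at least 1")
  if (cfg$marr < 0 || cfg$marr > 1) stop("marr must lie in [0, 1]")
  if (length(cfg$irr_range) != 2 || cfg$irr_range[1] >= cfg$irr_range[2])
    stop("irr_range must be c(low, high) with low < high")
  if (length(cfg$upc_window) != 2 || cfg$upc_window[1] >= cfg$upc_window[2])
    stop("upc_window must be c(low, high) with low < high")
  cfg$models <- match.arg(cfg$models, .tea_model_names, several.ok = TRUE)
  if (!is.null(cfg$bounds_overrides))
    tea_bounds(overrides = lapply(cfg$bounds_overrides, as.numeric))
  structure(cfg, class = "tea_config")
}

#' Save a configuration to YAML
#'
#' @param cfg A `tea_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tea_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full pipeline: generate, train, analyze
#'
#' Chains the scenario generator, the surrogate fit and the uncertainty
#' analyses under one configuration and writes all artifacts to
#' `cfg$out_dir`: the scenario CSV, cross-validation and hold-out metrics
#' (JSON), the selected-feature list, the Spearman table (CSV), the
#' feasibility range (JSON) and a provenance block (seed, configuration,
#' package version).  Fully deterministic for a fixed seed.
#'
#' @param cfg A [load_config()] result (or `NULL` for defaults).
#' @param out_dir Overrides `cfg$out_dir`.
#' @return Invisibly, a list with the dataset, surrogate fit, Spearman
#'   table, heatmap and feasibility range.
#' @export
reproduce <- function(cfg = load_config(), out_dir = NULL) {
  if (is.null(cfg)) cfg <- load_config()
  stopifnot(inherits(cfg, "tea_config"))
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, ...)

  bounds <- tea_bounds(overrides = cfg$bounds_overrides)
  message("generating ", cfg$n_scenarios, " scenarios (seed ", cfg$seed, ")")
  ds <- tea_scenarios(cfg$n_scenarios, seed = cfg$seed, bounds = bounds,
                      irr_range = cfg$irr_range)
  write_scenarios(ds, p("scenarios.csv"))

  message("fitting surrogate models: ",
          paste(cfg$models, collapse = ", "))
  fit <- tea_surrogate(ds, models = cfg$models,
                       select = cfg$select_features,
                       cv_folds = cfg$cv_folds,
                       train_fraction = cfg$train_fraction,
                       seed = cfg$seed)
  jsonlite::write_json(
    list(cv = metrics_table(fit, "cv"),
         holdout = metrics_table(fit, "holdout"), best = fit$best),
    p("metrics.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(fit$features, p("selected_features.txt"))

  tuned <- NULL
  if (isTRUE(cfg$tune)) {
    message("randomized hyperparameter search (",
            cfg$tune_iterations, " iterations)")
    tuned <- tune_surrogate(fit, n_iter = cfg$tune_iterations,
                            seed = cfg$seed)
  }

  st <- spearman_table(ds)
  utils::write.csv(st, p("spearman.csv"), row.names = FALSE)

  hm <- interpolate_heatmap(ds)
  rng <- feasible_mpsp_range(hm, cfg$marr, cfg$upc_window)
  jsonlite::write_json(
    list(marr = cfg$marr, upc_window = cfg$upc_window,
         mpsp_lower = rng[["lower"]], mpsp_upper = rng[["upper"]]),
    p("feasibility.json"), auto_unbox = TRUE, digits = NA)

  grDevices::png(p("heatmap.png"), 900, 700)
  plot(hm); grDevices::dev.off()
  grDevices::png(p("kde_marginals.png"), 1200, 900)
  plot(kde_marginals(ds, utils::head(fit$features, 9)))
  grDevices::dev.off()

  jsonlite::write_json(
    list(seed = cfg$seed, n = cfg$n_scenarios,
         package_version = as.character(utils::packageVersion("batchtea")),
         config = unclass(cfg)),
    p("provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, surrogate = fit, tuned = tuned,
                 spearman = st, heatmap = hm, feasible_range = rng))
}
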