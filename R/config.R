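#' Run configuration
#'
#' Bundles everything one pipeline run needs: the problem, the data source
#' (synthetic setting or a measurement file), the multi-start budget and
#' hyperparameter ranges, seeds, solver tolerances and evaluation options.
#' Configurations round-trip through YAML ([read_run_config()],
#' [write_run_config()]), and named presets embody the canonical study
#' settings.
#'
#' @param problem Problem name (see [ude_problems()]).
#' @param data Either a list `list(n_points=, noise_percent=, seed=)` for
#'   synthetic glycolysis data or `list(file=)` for a measurement table.
#' @param n_starts Number of multi-start runs.
#' @param ranges Ranges preset name or list (see [multistart_ranges()]).
#' @param seed Master seed.
#' @param solver `"nonstiff"`, `"stiff"` or `NULL` for the problem default.
#' @param rtol,atol Solver tolerances.
#' @param budget Named vector `c(adam=, total=)`.
#' @param threshold Success threshold on the test NMAE.
#' @param test_points Test-grid resolution for evaluation.
#' @return A `run_config` list.
#' @export
run_config <- function(problem, data = list(n_points = 46, noise_percent = 5,
                                            seed = 1L),
                       n_starts = 10L, ranges = "glycolysis", seed = 1L,
                       solver = NULL, rtol = 1e-6, atol = 1e-8,
                       budget = c(adam = 500, total = 3000),
                       threshold = 0.15, test_points = 100L) {
  problem <- match.arg(problem, ude_problems())
  if (is.character(ranges)) ranges <- multistart_ranges(ranges)
  if (length(ranges) == 0) stop("empty hyperparameter ranges", call. = FALSE)
  structure(
    list(problem = problem, data = data, n_starts = as.integer(n_starts),
         ranges = ranges, seed = as.integer(seed), solver = solver,
         rtol = rtol, atol = atol,
         budget = c(adam = unname(budget[["adam"]]),
                    total = unname(budget[["total"]])),
         threshold = threshold, test_points = as.integer(test_points)),
    class = "run_config"
  )
}

#' Canonical study presets
#'
#' @param name `"glycolysis"`, `"stat5_scenario1"`, `"stat5_scenario2"`,
#'   `"stat5_scenario3"` or `"stat5_scenario4"`.
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
preset_config <- function(name, ...) {
  presets <- list(
    glycolysis = list(problem = "glycolysis_ude", ranges = "glycolysis"),
    stat5_scenario1 = list(problem = "stat5_scenario1",
                           ranges = "stat5_scenario1_3", solver = "stiff"),
    stat5_scenario2 = list(problem = "stat5_scenario2",
                           ranges = "stat5_scenario1_3", solver = "stiff"),
    stat5_scenario3 = list(problem = "stat5_scenario3",
                           ranges = "stat5_scenario1_3", solver = "stiff"),
    stat5_scenario4 = list(problem = "stat5_scenario4",
                           ranges = "stat5_scenario4", solver = "stiff")
  )
  name <- match.arg(name, names(presets))
  do.call(run_config, modifyList(presets[[name]], list(...)))
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$budget <- unlist(raw$budget)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$budget <- as.list(out$budget)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a configured multi-start study
#'
#' Loads or generates the data, runs the multi-start pipeline and (for
#' synthetic data) evaluates the best fit. The workhorse behind the command
#' line interface.
#'
#' @param config A `run_config`.
#' @param out_dir Optional output directory for artifacts.
#' @return List with `dataset`, `multistart`, `best`, and (synthetic data)
#'   `evaluation`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  problem <- ude_problem(config$problem)
  if (!is.null(config$data$file)) {
    meas <- read_measurements(config$data$file, problem)
    dataset <- list(measurements = meas)
  } else {
    dataset <- generate_glycolysis_dataset(
      data_setting(config$data$n_points, config$data$noise_percent,
                   config$data$seed %||% config$seed),
      test_points = config$test_points
    )
  }
  ms <- run_multistart(problem, dataset$measurements, config$n_starts,
                       config$ranges, seed = config$seed,
                       budget = config$budget, rtol = config$rtol,
                       atol = config$atol)
  best <- best_fit(ms)
  out <- list(dataset = dataset, multistart = ms, best = best)
  if (inherits(dataset, "ude_dataset")) {
    ref <- problem$parameters
    out$evaluation <- evaluate_fit(
      best, dataset,
      true_theta = ref$values[ref$free],
      threshold = config$threshold
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(dataset$truth)) write_dataset(dataset, out_dir)
    write_multistart(ms, file.path(out_dir, "starts"))
    if (!is.null(out$evaluation)) {
      jsonlite::write_json(
        evaluation_json(out$evaluation),
        file.path(out_dir, "evaluation.json"),
        auto_unbox = TRUE, digits = NA, null = "null"
      )
    }
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

evaluation_json <- function(ev) {
  list(test_nmae = ev$test_nmae, success = ev$success, aic = ev$aic,
       bic = ev$bic,
       parameter_error = ev$parameter_error,
       sigma = as.list(ev$sigma),
       sigma_relative_error = as.list(ev$sigma_relative_error),
       oscillation = lapply(ev$oscillation, function(o) {
         o[c("sustained", "amplitude", "frequency", "n_peaks")]
       }))
}
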