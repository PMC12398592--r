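CANONICAL_POINTS <- c(8L, 16L, 31L, 46L, 61L)
CANONICAL_NOISE <- c(5, 10, 20, 35)

#' Describe a synthetic glycolysis data setting
#'
#' The synthetic study crosses five sampling densities (8, 16, 31, 46, 61
#' points per observable on the training window) with four noise levels
#' (5, 10, 20, 35 percent). Other values are accepted for exploration but
#' flagged as non-canonical.
#'
#' @param n_points Points per observable on `[0, 1.5]` (endpoints included).
#' @param noise_percent Noise level in percent of the mean observable
#'   magnitude (see [generate_glycolysis_dataset()]); 0 gives noise-free
#'   data.
#' @param seed Integer seed for the noise draw.
#' @return A `data_setting` list.
#' @export
data_setting <- function(n_points = 46, noise_percent = 5, seed = 1L) {
  stopifnot(n_points >= 2, noise_percent >= 0)
  canonical <- n_points %in% CANONICAL_POINTS &&
    noise_percent %in% c(0, CANONICAL_NOISE)
  if (!canonical) {
    message("non-canonical data setting (", n_points, " points, ",
            noise_percent, "% noise)")
  }
  structure(list(n_points = as.integer(n_points),
                 noise_percent = noise_percent, seed = as.integer(seed),
                 canonical = canonical),
            class = "data_setting")
}

#' Generate a synthetic glycolysis dataset
#'
#' Simulates the reference glycolysis ODE, samples the observables `N2` and
#' `A3` on a uniform grid over the training window `[0, 1.5]` (both
#' endpoints included) and corrupts them with additive Gaussian noise. The
#' noise standard deviation per observable is
#' `noise_percent/100 * mean(|truth|)` over the training grid — a single
#' per-observable scale consistent with the additive error model. Noise-free
#' truth is returned on the training grid and on a dense test grid over
#' `(1.5, 5]`, where prediction quality is assessed.
#'
#' @param setting A [data_setting()].
#' @param problem The reference problem (defaults to the mechanistic
#'   glycolysis model with its published parameters).
#' @param theta Optional parameter override used for the truth simulation.
#' @param test_points Size of the dense test grid on `(1.5, 5]`.
#' @param rtol,atol Solver tolerances for the truth simulation.
#' @return A `ude_dataset`: list with `measurements` (tibble: `time`,
#'   `observable`, `measurement`, `partition`, `is_initial`), `truth`
#'   (tibble: `time`, `observable`, `value`, `window` train/test), `sigma`
#'   (named true noise SDs) and `setting`.
#' @export
generate_glycolysis_dataset <- function(setting = data_setting(),
                                        problem = glycolysis_problem(),
                                        theta = NULL,
                                        test_points = 100L,
                                        rtol = 1e-8, atol = 1e-10) {
  n <- setting$n_points
  t_train <- seq(0, 1.5, length.out = n)
  t_test <- seq(1.5, 5, length.out = test_points + 1L)[-1]
  params <- if (is.null(theta)) NULL else list(theta = theta)

  truth_tr <- ude_predict(problem, params, t_train, rtol = rtol, atol = atol)
  truth_te <- ude_predict(problem, params, t_test, rtol = rtol, atol = atol)
  if (!isTRUE(attr(truth_tr, "success")) || !isTRUE(attr(truth_te, "success"))) {
    stop("reference simulation failed; cannot generate data", call. = FALSE)
  }
  truth <- dplyr::bind_rows(
    dplyr::mutate(truth_tr, window = "train"),
    dplyr::mutate(truth_te, window = "test")
  )
  truth <- dplyr::rename(truth, value = "prediction")

  sigma <- vapply(problem$obs_names, function(o) {
    setting$noise_percent / 100 *
      mean(abs(truth_tr$prediction[truth_tr$observable == o]))
  }, numeric(1))

  meas <- dplyr::rename(truth_tr, measurement = "prediction")
  if (setting$noise_percent > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(setting$seed)
    meas$measurement <- meas$measurement +
      rnorm(nrow(meas), 0, sigma[meas$observable])
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  meas$is_initial <- meas$time == 0
  out <- structure(
    list(measurements = meas, truth = truth, sigma = sigma,
         setting = setting, problem_name = problem$name),
    class = "ude_dataset"
  )
  out$measurements <- split_dataset(out$measurements, n)
  out
}

#' @export
print.ude_dataset <- function(x, ...) {
  cat(sprintf("<ude_dataset> %d points/observable, %g%% noise, seed %d\n",
              x$setting$n_points, x$setting$noise_percent, x$setting$seed))
  print(dplyr::count(x$measurements, .data$partition), ...)
  invisible(x)
}

#' Split measurements into training and validation partitions
#'
#' Implements the study's bookkeeping: the known initial-condition record
#' (t = 0) always trains; the remaining time points are split 4:3 for 8
#' points per observable, 7:8 for 16, and 1:1 otherwise (odd remainders give
#' the extra point to training). Validation points are spread evenly over
#' the time window; the same time points are held out for every observable.
#' Unknown canonical counts fall back to the 1:1 rule with a warning.
#'
#' @param data Measurement tibble (columns `time`, `observable`,
#'   `measurement`).
#' @param n_points Points per observable, used to select the split rule.
#' @return The tibble with `partition` and `is_initial` columns.
#' @export
split_dataset <- function(data, n_points = length(unique(data$time))) {
  times <- sort(unique(data$time))
  has_t0 <- times[1] == 0
  rest <- if (has_t0) times[-1] else times
  n_rem <- length(rest)
  n_val <- if (n_points == 8) 3L
  else if (n_points == 16) 8L
  else {
    if (!n_points %in% CANONICAL_POINTS) {
      warning("no canonical split for ", n_points,
              " points; using the 1:1 rule", call. = FALSE)
    }
    as.integer(floor(n_rem / 2))
  }
  idx <- unique(round(seq(1, n_rem, length.out = n_val)))
  # guard against rounding collisions for dense validation fractions
  while (length(idx) < n_val) {
    idx <- sort(unique(c(idx, setdiff(seq_len(n_rem), idx)[1])))
  }
  val_times <- rest[idx]
  data$partition <- ifelse(data$time %in% val_times, "validation", "train")
  data$is_initial <- data$time == times[1] & has_t0
  data
}

#' Read a measurement table
#'
#' Reads the tab-separated measurement dialect (columns `observableId`,
#' `time`, `measurement`) used by systems-biology benchmark collections,
#' checks the observables against a problem, and applies a train:validation
#' split by time point (default 4:1, the real-data convention).
#'
#' @param path TSV file path.
#' @param problem Optional `ude_problem` whose observables validate the
#'   table.
#' @param split Either `"4:1"` (every fifth time point validates), a
#'   numeric validation share, or `NULL` for no partitioning.
#' @return Measurement tibble with `partition`.
#' @export
read_measurements <- function(path, problem = NULL, split = "4:1") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("observableId", "time", "measurement")
  if (!all(need %in% names(tab))) {
    stop("measurement table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(tab$time) | !is.finite(tab$measurement)
  if (any(bad)) {
    stop("malformed measurement rows (line ",
         paste(which(bad) + 1L, collapse = ", "), ")", call. = FALSE)
  }
  out <- tibble::tibble(time = tab$time, observable = tab$observableId,
                        measurement = tab$measurement)
  if (!is.null(problem)) {
    unknown <- setdiff(unique(out$observable), problem$obs_names)
    if (length(unknown)) {
      stop("unknown observables: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(split)) {
    share <- if (identical(split, "4:1")) 0.2 else as.numeric(split)
    times <- sort(unique(out$time))
    n_val <- max(1L, round(share * length(times)))
    idx <- unique(round(seq(2, length(times), length.out = n_val)))
    out$partition <- ifelse(out$time %in% times[idx], "validation", "train")
  }
  out
}

#' Write measurements in the TSV dialect
#'
#' @param data Measurement tibble (`time`, `observable`, `measurement`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  readr::write_tsv(
    tibble::tibble(observableId = data$observable, time = data$time,
                   measurement = data$measurement),
    path
  )
  invisible(path)
}

#' Write a full synthetic dataset with provenance
#'
#' Measurements as TSV, truth as CSV, and the generation parameters as a
#' JSON sidecar, so every artifact is reproducible from its provenance.
#'
#' @param dataset A `ude_dataset`.
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, stem = "glycolysis") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_measurements(dataset$measurements,
                     file.path(dir, paste0(stem, "_measurements.tsv")))
  readr::write_csv(dataset$truth, file.path(dir, paste0(stem, "_truth.csv")))
  jsonlite::write_json(
    list(n_points = dataset$setting$n_points,
         noise_percent = dataset$setting$noise_percent,
         seed = dataset$setting$seed, sigma = as.list(dataset$sigma),
         problem = dataset$problem_name),
    file.path(dir, paste0(stem, "_provenance.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
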