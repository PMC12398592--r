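#' Canonical multi-start hyperparameter ranges
#'
#' The hyperparameter grids used by the multi-start studies, per problem
#' family: network depth/width/activation sets, whether inputs are
#' log-normalised, the log-uniform ADAM learning-rate range, and the
#' weight-decay range with "no regularisation" as an extra discrete level.
#'
#' @param preset One of `"glycolysis"`, `"stat5_scenario1_3"`,
#'   `"stat5_scenario4"`.
#' @return A named list of ranges consumed by [sample_starts()].
#' @export
multistart_ranges <- function(preset = c("glycolysis", "stat5_scenario1_3",
                                         "stat5_scenario4")) {
  preset <- match.arg(preset)
  switch(preset,
    glycolysis = list(
      n_hidden_layers = 1:4, width = c(3L, 5L, 10L), activation = ACTIVATIONS,
      input_normalisation = c(TRUE, FALSE),
      learning_rate = c(1e-4, 1e-1),
      lambda = c(1e-4, 1e-1), lambda_none_share = 0.2
    ),
    stat5_scenario1_3 = list(
      n_hidden_layers = 3L, width = 5L, activation = "tanh",
      input_normalisation = c(TRUE, FALSE),
      learning_rate = c(1e-4, 1e-2),
      lambda = c(1e-3, 1), lambda_none_share = 0.2
    ),
    stat5_scenario4 = list(
      n_hidden_layers = 1:4, width = c(3L, 5L, 10L), activation = ACTIVATIONS,
      input_normalisation = c(TRUE, FALSE),
      learning_rate = c(1e-4, 1e-1),
      lambda = c(1e-3, 1e3), lambda_none_share = 0.2
    ))
}

#' Sample multi-start initialisations
#'
#' Draws `n_starts` joint initialisations of the free mechanistic parameters
#' and the training hyperparameters by Latin hypercube sampling: every
#' continuous dimension is stratified into `n_starts` equal-probability
#' strata, each hit exactly once. Mechanistic parameters are sampled
#' log-uniformly within their bounds; the learning rate and the weight-decay
#' strength log-uniformly over their ranges, with `lambda = 0`
#' ("no regularisation") occupying the lowest `lambda_none_share` of its
#' stratification axis; discrete hyperparameters are mapped from their own
#' LHS axes onto the listed levels.
#'
#' @param n_starts Number of starts, `>= 1`.
#' @param ranges A list as returned by [multistart_ranges()].
#' @param parameters A [parameter_set()] giving the mechanistic bounds.
#' @param seed Integer; the draw is deterministic given the seed.
#' @return A list of length `n_starts`; each element has `theta` (named
#'   mechanistic values), `hyper` (a [ude_hyper()]) and `seed` (a child seed
#'   for the weight initialisation).
#' @export
sample_starts <- function(n_starts, ranges, parameters, seed = 1L) {
  stopifnot(n_starts >= 1)
  if (length(ranges) == 0) stop("empty hyperparameter ranges", call. = FALSE)
  free <- parameters$names[parameters$free]
  n_free <- length(free)
  k <- n_free + 6L # lr, lambda, layers, width, activation, normalisation
  u <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    lhs::randomLHS(n_starts, k)
  })

  log_map <- function(uu, range) exp(log(range[1]) + uu * diff(log(range)))
  pick <- function(uu, levels) levels[pmin(length(levels),
                                           floor(uu * length(levels)) + 1L)]

  bl <- parameters$b_l[free]; bu <- parameters$b_u[free]
  lapply(seq_len(n_starts), function(i) {
    theta <- parameters$values
    if (n_free > 0) {
      theta[free] <- exp(log(bl) + u[i, seq_len(n_free)] * (log(bu) - log(bl)))
    }
    u_lr <- u[i, n_free + 1L]; u_la <- u[i, n_free + 2L]
    p0 <- ranges$lambda_none_share %||% 0.2
    lambda <- if (u_la < p0) 0 else
      log_map((u_la - p0) / (1 - p0), ranges$lambda)
    hyper <- ude_hyper(
      n_hidden_layers = pick(u[i, n_free + 3L], ranges$n_hidden_layers),
      width = pick(u[i, n_free + 4L], ranges$width),
      activation = pick(u[i, n_free + 5L], ranges$activation),
      input_normalisation = pick(u[i, n_free + 6L],
                                 ranges$input_normalisation),
      learning_rate = log_map(u_lr, ranges$learning_rate),
      lambda = lambda
    )
    list(theta = theta, hyper = hyper,
         seed = as.integer((seed + 104729 * i) %% 2147483647L))
  })
}

#' Multi-start training
#'
#' Runs [train_single()] from each sampled start (each with its own
#' mechanistic initialisation, hyperparameters and child seed) and selects
#' the best model by the lowest plain NLL on all data used during training
#' (training plus validation partition). Failed starts are kept in the
#' archive with their status; if every start fails an error summarising the
#' failures is raised.
#'
#' @param problem A `ude_problem`.
#' @param data Measurement tibble (with `partition`).
#' @param n_starts Number of starts.
#' @param ranges Hyperparameter ranges, see [multistart_ranges()].
#' @param seed Master seed; start `i` derives a child seed from it.
#' @param budget,gradient,rtol,atol Passed to [train_single()].
#' @param starts Optional pre-sampled start list (overrides `n_starts`).
#' @return A `ude_multistart`: list with `fits`, a `summary` tibble and
#'   `best_index`.
#' @export
run_multistart <- function(problem, data, n_starts, ranges = multistart_ranges(),
                           seed = 1L, budget = c(adam = 500, total = 3000),
                           gradient = "auto", rtol = 1e-6, atol = 1e-8,
                           starts = NULL) {
  if (!"partition" %in% names(data)) data$partition <- "train"
  if (is.null(starts)) {
    starts <- sample_starts(n_starts, ranges, problem$parameters, seed)
  }
  fits <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    st <- starts[[i]]
    prob_i <- apply_hyper(problem, st$hyper)
    init <- list(
      theta = st$theta,
      w = if (!is.null(prob_i$ann)) ann_init(prob_i$ann$spec, st$seed) else NULL,
      w_obs = if (!is.null(prob_i$obs_ann))
        ann_init(prob_i$obs_ann$spec, st$seed + 1L) else NULL,
      sigma = NULL
    )
    init$sigma <- mle_sigma_at(prob_i, data, init)
    fits[[i]] <- tryCatch(
      train_single(prob_i, data, init = init, hyper = st$hyper,
                   budget = budget, gradient = gradient, rtol = rtol,
                   atol = atol, seed = st$seed),
      error = function(e) {
        structure(list(problem = prob_i, status = "error",
                       message = conditionMessage(e), hyper = st$hyper,
                       seed = st$seed, full_nll = Inf,
                       train_nll = Inf, validation_nll = Inf),
                  class = "ude_fit")
      }
    )
  }
  summary <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble::tibble(
      start = i, seed = f$seed, status = f$status,
      n_hidden_layers = f$hyper$n_hidden_layers, width = f$hyper$width,
      activation = f$hyper$activation,
      input_normalisation = f$hyper$input_normalisation,
      learning_rate = f$hyper$learning_rate, lambda = f$hyper$lambda,
      train_nll = f$train_nll %||% Inf,
      validation_nll = f$validation_nll %||% Inf,
      full_nll = f$full_nll %||% Inf
    )
  }))
  ok <- is.finite(summary$full_nll)
  if (!any(ok)) {
    stop("all starts failed: ",
         paste(utils::head(summary$status, 5), collapse = ", "),
         call. = FALSE)
  }
  best <- which.min(ifelse(ok, summary$full_nll, Inf))
  summary$best <- seq_len(nrow(summary)) == best
  structure(list(fits = fits, summary = summary, best_index = best,
                 seed = seed),
            class = "ude_multistart")
}

default_sigma <- function(problem, data) {
  tr <- data[data$partition == "train", , drop = FALSE]
  vapply(problem$obs_names, function(o) {
    m <- tr$measurement[tr$observable == o]
    s <- if (length(m) > 1) sd(m) else abs(m)
    max(s, 1e-3, na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.ude_multistart <- function(x, ...) {
  cat(sprintf("<ude_multistart> %d starts, best = #%d (full-data NLL %.4g)\n",
              nrow(x$summary), x$best_index,
              x$summary$full_nll[x$best_index]))
  invisible(x)
}

#' Best fit of a multi-start run
#'
#' @param x A `ude_multistart`.
#' @return The best `ude_fit` (lowest full-data NLL).
#' @export
best_fit <- function(x) {
  stopifnot(inherits(x, "ude_multistart"))
  x$fits[[x$best_index]]
}

#' Write a multi-start archive to disk
#'
#' One JSON per start (parameters, hyperparameters, traces) plus an index
#' TSV with per-start status and likelihoods, best start flagged.
#'
#' @param x A `ude_multistart`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multistart <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(x$fits)) {
    f <- x$fits[[i]]
    out <- list(
      start = i, status = f$status, seed = f$seed,
      hyperparameters = unclass(f$hyper),
      theta = as.list(f$theta), sigma = as.list(f$sigma),
      w = f$w, w_obs = f$w_obs,
      train_nll = f$train_nll, validation_nll = f$validation_nll,
      full_nll = f$full_nll,
      trace = if (!is.null(f$trace)) as.list(f$trace) else NULL
    )
    jsonlite::write_json(out, file.path(dir, sprintf("start_%04d.json", i)),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  readr::write_tsv(x$summary, file.path(dir, "index.tsv"))
  invisible(dir)
}
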