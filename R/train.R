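#' Hyperparameter bundle for one training run
#'
#' @param n_hidden_layers,width,activation,input_normalisation Network
#'   architecture knobs (see [ann_spec()]).
#' @param learning_rate Initial ADAM learning rate.
#' @param lambda Weight-decay strength; 0 disables regularisation.
#' @return A `ude_hyper` list.
#' @export
ude_hyper <- function(n_hidden_layers = 1, width = 5, activation = "tanh",
                      input_normalisation = FALSE, learning_rate = 1e-2,
                      lambda = 0) {
  stopifnot(learning_rate > 0, lambda >= 0)
  structure(
    list(n_hidden_layers = as.integer(n_hidden_layers),
         width = as.integer(width),
         activation = match.arg(activation, ACTIVATIONS),
         input_normalisation = isTRUE(input_normalisation),
         learning_rate = learning_rate, lambda = lambda),
    class = "ude_hyper"
  )
}

# rebuild a registry problem with the architecture requested by `hyper`
apply_hyper <- function(problem, hyper) {
  tmpl <- problem$ann %||% problem$obs_ann
  if (is.null(tmpl) || is.null(hyper)) return(problem)
  spec <- ann_spec(tmpl$spec$n_inputs, tmpl$spec$n_outputs,
                   n_hidden_layers = hyper$n_hidden_layers,
                   width = hyper$width, activation = hyper$activation,
                   input_normalisation = hyper$input_normalisation)
  if (problem$name %in% ude_problems()) {
    return(ude_problem(problem$name, spec = spec))
  }
  if (!is.null(problem$ann)) problem$ann$spec <- spec else
    problem$obs_ann$spec <- spec
  problem
}

default_init <- function(problem, data, seed) {
  lay <- par_layout(problem)
  spec_dyn <- problem$ann$spec
  spec_obs <- problem$obs_ann$spec
  w <- if (!is.null(spec_dyn)) ann_init(spec_dyn, seed) else numeric(0)
  w_obs <- if (!is.null(spec_obs)) ann_init(spec_obs, seed + 1L) else numeric(0)
  sigma <- mle_sigma_at(problem, data,
                        list(theta = problem$parameters$values, w = w,
                             w_obs = w_obs))
  pack_params(problem, theta = problem$parameters$values, w = w,
              w_obs = w_obs, sigma = sigma)
}

# conditional-MLE noise initialisation: the RMS residual of the initial
# predictions per observable (the stationary point of the likelihood in
# sigma), falling back to the sample SD when the first simulation fails
mle_sigma_at <- function(problem, data, params) {
  tr <- data[data$partition == "train", , drop = FALSE]
  fallback <- default_sigma(problem, data)
  pred <- tryCatch(
    ude_predict(problem, params, sort(unique(tr$time))),
    error = function(e) NULL
  )
  if (is.null(pred) || !isTRUE(attr(pred, "success"))) return(fallback)
  j <- dplyr::inner_join(tr, pred, by = c("time", "observable"))
  s <- optimal_sigma(split(j$measurement - j$prediction, j$observable))
  out <- fallback
  ok <- intersect(names(s), names(out))
  out[ok] <- pmax(s[ok], 1e-6)
  out
}

#' Train a UDE from a single start
#'
#' Minimises the regularised negative log-likelihood with ADAM for the first
#' `budget["adam"]` epochs and BFGS for the remainder (up to
#' `budget["total"]` epochs in all). The validation NLL (without the
#' regularisation penalty) is evaluated at every epoch, and early stopping
#' returns the parameters at its minimum; the last iterate is kept as
#' `final_params`. One BFGS gradient evaluation counts as one epoch.
#'
#' @param problem A `ude_problem`.
#' @param data Measurement tibble with `time`, `observable`, `measurement`
#'   and a `partition` column (`"train"`/`"validation"`).
#' @param init Packed parameter vector or list (`theta`, `w`, `w_obs`,
#'   `sigma`); default: reference parameters, Glorot/zero network weights
#'   seeded by `seed`, per-observable sample SD as initial noise.
#' @param hyper A [ude_hyper()], or `NULL` (default) to train the problem as
#'   given with the default learning rate and no regularisation. When a
#'   hyperparameter bundle is supplied, its architecture fields are applied
#'   to the problem's network (via the registry when possible).
#' @param budget Named vector `c(adam = ..., total = ...)`.
#' @param gradient,rtol,atol Passed to [ude_objective()].
#' @param seed Integer; seeds the default weight initialisation and is
#'   recorded in the result.
#' @return A `ude_fit`.
#' @export
train_single <- function(problem, data, init = NULL, hyper = NULL,
                         budget = c(adam = 500, total = 3000),
                         gradient = "auto", rtol = 1e-6, atol = 1e-8,
                         seed = 1L) {
  if (!"partition" %in% names(data)) data$partition <- "train"
  problem <- apply_hyper(problem, hyper)
  obj <- ude_objective(problem, data, lambda = hyper$lambda %||% 0,
                       rtol = rtol, atol = atol, gradient = gradient)
  lay <- obj$layout
  p <- if (is.null(init)) default_init(problem, data, seed) else {
    if (is.numeric(init)) init else do.call(pack_params, c(list(problem), init))
  }
  stopifnot(length(p) == lay$total)

  has_val <- any(data$partition == "validation")
  n_adam <- as.integer(budget[["adam"]])
  n_total <- as.integer(budget[["total"]])
  # preallocated trace columns; a tibble is assembled once at the end
  tr_n <- n_total + 16L
  tr_stage <- character(tr_n)
  tr_value <- tr_tnll <- tr_vnll <- numeric(tr_n)
  epoch <- 0L
  best <- list(val = Inf, p = p, epoch = 0L)
  status <- "budget_exhausted"

  note <- function(value, train_nll, val_nll, stage) {
    epoch <<- epoch + 1L
    if (epoch <= tr_n) {
      tr_stage[epoch] <<- stage
      tr_value[epoch] <<- value
      tr_tnll[epoch] <<- train_nll
      tr_vnll[epoch] <<- if (is.null(val_nll)) NA_real_ else val_nll
    }
    score <- if (has_val) val_nll else value
    if (is.finite(score) && score < best$val) {
      best <<- list(val = score, p = p, epoch = epoch)
    }
  }

  # --- ADAM stage
  lr <- hyper$learning_rate %||% 1e-2
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- numeric(lay$total); v <- numeric(lay$total)
  failed <- FALSE
  for (it in seq_len(min(n_adam, n_total))) {
    res <- obj$fn_gr(p)
    if (!res$success) {
      failed <- TRUE
      if (it == 1L) status <- "simulation_failed"
      break
    }
    note(res$value, res$train_nll, res$val_nll, "adam")
    g <- res$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^it)
    vhat <- v / (1 - b2^it)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
  }

  # --- BFGS stage
  if (!failed && epoch < n_total) {
    fn_opt <- function(pp) {
      val <- obj$fn(pp)
      if (!is.finite(val)) 1e12 else val
    }
    gr_opt <- function(pp) {
      res <- obj$fn_gr(pp)
      if (res$success) {
        p <<- pp
        note(res$value, res$train_nll, res$val_nll, "bfgs")
      }
      res$grad
    }
    maxit <- n_total - epoch
    fit <- tryCatch(
      optim(p, fn_opt, gr_opt, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      p <- fit$par
      if (fit$convergence == 0) status <- "converged"
    }
  }

  if (epoch == 0L && status != "simulation_failed") status <- "simulation_failed"
  n_rec <- min(epoch, tr_n)
  trace <- tibble::tibble(
    epoch = seq_len(n_rec), stage = tr_stage[seq_len(n_rec)],
    train_objective = tr_value[seq_len(n_rec)],
    train_nll = tr_tnll[seq_len(n_rec)],
    validation_nll = tr_vnll[seq_len(n_rec)]
  )
  best_p <- if (is.finite(best$val)) best$p else p
  final_eval <- obj$eval_all(best_p)
  new_ude_fit(problem, data, obj, best_p, p, trace, status, hyper, seed,
              final_eval)
}

new_ude_fit <- function(problem, data, obj, best_p, final_p, trace, status,
                        hyper, seed, final_eval) {
  up <- unpack_params(problem, best_p)
  structure(
    list(problem = problem, data = data,
         best_params = best_p, final_params = final_p,
         theta = up$theta, w = up$w, w_obs = up$w_obs, sigma = up$sigma,
         trace = trace, status = status, hyper = hyper, seed = seed,
         lambda = obj$lambda,
         train_nll = final_eval$train_nll,
         validation_nll = final_eval$val_nll,
         full_nll = obj$nll_on(best_p, "all"),
         n_data = nrow(data),
         n_params = obj$layout$total),
    class = "ude_fit"
  )
}

#' @export
print.ude_fit <- function(x, ...) {
  cat(sprintf("<ude_fit> %s | status: %s | epochs: %d\n", x$problem$name,
              x$status, nrow(x$trace)))
  cat(sprintf("  train NLL %.4g | validation NLL %.4g | full-data NLL %.4g\n",
              x$train_nll, x$validation_nll, x$full_nll))
  invisible(x)
}

#' Two-stage training: mechanistic model first, then the UDE
#'
#' For UDEs that strictly extend a consistent mechanistic model (Scenario 3
#' style augmentation), balancing the components by initialisation: stage 1
#' fits the mechanistic problem alone; stage 2 starts the UDE from the
#' stage-1 mechanistic estimates (shared parameter names are carried over,
#' network weights start at the zero-output initialisation) and fits
#' everything jointly.
#'
#' @param problem_ode Mechanistic `ude_problem`.
#' @param problem_ude Extending `ude_problem` (shares parameter names with
#'   `problem_ode`).
#' @param data Measurement tibble.
#' @param hyper A [ude_hyper()] for stage 2.
#' @param budget_ode,budget_ude Epoch budgets per stage.
#' @param ... Passed to [train_single()].
#' @return The stage-2 `ude_fit`, with the stage-1 fit archived in
#'   `$stage1`.
#' @export
train_two_stage <- function(problem_ode, problem_ude, data,
                            hyper = ude_hyper(),
                            budget_ode = c(adam = 500, total = 3000),
                            budget_ude = c(adam = 500, total = 3000), ...) {
  stage1 <- train_single(problem_ode, data, hyper = ude_hyper(
    learning_rate = hyper$learning_rate, lambda = 0
  ), budget = budget_ode, ...)
  if (stage1$status == "simulation_failed") {
    stop("stage-1 (mechanistic) training failed to simulate", call. = FALSE)
  }
  problem_ude <- apply_hyper(problem_ude, hyper)
  theta <- problem_ude$parameters$values
  shared <- intersect(names(theta), names(stage1$theta))
  theta[shared] <- stage1$theta[shared]
  # keep handed-over values strictly inside their bounds
  ps <- problem_ude$parameters
  theta <- pmin(pmax(theta, ps$b_l * 1.000001), ps$b_u * 0.999999)
  init <- list(
    theta = theta,
    w = if (!is.null(problem_ude$ann))
      ann_init(problem_ude$ann$spec, stage1$seed) else NULL,
    w_obs = if (!is.null(problem_ude$obs_ann))
      ann_init(problem_ude$obs_ann$spec, stage1$seed + 1L) else NULL,
    sigma = stage1$sigma
  )
  stage2 <- train_single(problem_ude, data, init = init, hyper = hyper,
                         budget = budget_ude, ...)
  stage2$stage1 <- stage1
  stage2
}
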