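#' Integrate a UDE problem
#'
#' Solves the problem's dynamics at the requested times. Generic problems go
#' through \pkg{deSolve} (`ode45` for the non-stiff class, `lsoda` for the
#' stiff class); the glycolysis family additionally has a compiled
#' Dormand-Prince 5(4) fast path used automatically when no oracle override
#' is spliced in. Solver failures (step-size collapse, non-finite states,
#' blow-up) are reported through `success = FALSE` rather than raised, so
#' multi-start batches survive pathological parameter draws.
#'
#' @param problem A `ude_problem`.
#' @param params Either a packed parameter vector (see [pack_params()]), or a
#'   list with elements `theta` (named, natural scale), `w`, `w_obs`.
#' @param times Strictly increasing, non-negative output times.
#' @param solver `"nonstiff"`, `"stiff"`, or `NULL` for the problem default.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param max_steps Step budget for the compiled path.
#' @return A `ude_trajectory`: list with `data` (tibble: `time` plus one
#'   column per state), `success`, `failure_reason`.
#' @export
ude_integrate <- function(problem, params = NULL, times, solver = NULL,
                          rtol = 1e-6, atol = 1e-8, max_steps = 50000L) {
  stopifnot(inherits(problem, "ude_problem"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop("`times` must be non-negative and strictly increasing", call. = FALSE)
  }
  up <- as_unpacked(problem, params)
  solver <- solver %||% problem$solver

  if (identical(problem$fast, "glycolysis") && is.null(problem$ann$fun)) {
    sol <- glyc_fast_solve(problem, up, times, rtol, atol, max_steps,
                           sens_cons = integer(0), sens_ann = FALSE)
    return(new_trajectory(problem, times, sol$states, sol$success, sol$reason))
  }

  func <- function(t, y, parms) {
    list(problem_rhs(problem, t, y, up$theta, up$w))
  }
  method <- if (solver == "stiff") "lsoda" else "ode45"
  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = problem$x0, times = union_times(times), func = func, parms = NULL,
      method = method, rtol = rtol, atol = atol
    )),
    error = function(e) NULL
  )
  if (is.null(out) || nrow(out) < length(union_times(times)) ||
      any(!is.finite(out[, -1]))) {
    states <- matrix(NA_real_, length(times), length(problem$state_names))
    return(new_trajectory(problem, times, states, FALSE, "integration failed"))
  }
  keep <- match(times, out[, 1])
  states <- unname(out[keep, -1, drop = FALSE])
  new_trajectory(problem, times, states, TRUE, NULL)
}

# prepend t = 0 if absent (deSolve needs the initial time in `times`)
union_times <- function(times) {
  if (times[1] > 0) c(0, times) else times
}

as_unpacked <- function(problem, params) {
  if (is.null(params)) {
    params <- pack_params(problem)
  }
  if (is.numeric(params)) return(unpack_params(problem, params))
  lay <- par_layout(problem)
  list(theta = params$theta %||% problem$parameters$values,
       w = params$w %||% numeric(lay$n_w),
       w_obs = params$w_obs %||% numeric(lay$n_wo),
       sigma = params$sigma %||% rep(1, lay$n_sig))
}

new_trajectory <- function(problem, times, states, success, reason) {
  colnames(states) <- problem$state_names
  structure(
    list(data = tibble::as_tibble(cbind(tibble::tibble(time = times),
                                        tibble::as_tibble(states))),
         success = success, failure_reason = reason),
    class = "ude_trajectory"
  )
}

#' @export
print.ude_trajectory <- function(x, ...) {
  cat(sprintf("<ude_trajectory> %s (%d times)\n",
              if (x$success) "success" else paste0("FAILED: ", x$failure_reason),
              nrow(x$data)))
  print(x$data, ...)
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' One `time` column plus one column per state.
#'
#' @param trajectory A `ude_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(trajectory$data, path)
  invisible(path)
}

# compiled glycolysis solve; up is an unpacked parameter list
glyc_fast_solve <- function(problem, up, times, rtol, atol, max_steps,
                            sens_cons = integer(0), sens_ann = FALSE) {
  cons <- unname(up$theta[GLYC_CONS_ORDER])
  use_ann <- !is.null(problem$ann)
  if (use_ann) {
    spec <- problem$ann$spec
    glyc_solve_cpp(times, unname(problem$x0), cons,
                   problem$fast_opts$include_k5, TRUE, up$w, ann_dims(spec),
                   ann_act_id(spec), spec$input_normalisation,
                   as.integer(sens_cons), sens_ann, rtol, atol,
                   as.integer(max_steps))
  } else {
    glyc_solve_cpp(times, unname(problem$x0), cons,
                   problem$fast_opts$include_k5, FALSE, numeric(0),
                   c(7L, 1L), 0L, FALSE, as.integer(sens_cons), FALSE,
                   rtol, atol, as.integer(max_steps))
  }
}

#' Predict observables of a UDE problem
#'
#' Integrates the dynamics and applies the (possibly network-augmented)
#' observable mapping.
#'
#' @inheritParams ude_integrate
#' @return A tibble with columns `time`, `observable`, `prediction`; zero
#'   rows with attribute `success = FALSE` if the simulation failed.
#' @export
ude_predict <- function(problem, params = NULL, times, solver = NULL,
                        rtol = 1e-6, atol = 1e-8) {
  up <- as_unpacked(problem, params)
  traj <- ude_integrate(problem, params, times, solver, rtol, atol)
  if (!traj$success) {
    out <- tibble::tibble(time = numeric(0), observable = character(0),
                          prediction = numeric(0))
    attr(out, "success") <- FALSE
    return(out)
  }
  states <- as.matrix(traj$data[problem$state_names])
  preds <- vapply(seq_along(times), function(i) {
    problem_observables(problem, times[i], states[i, ], up$theta, up$w_obs)
  }, numeric(length(problem$obs_names)))
  out <- tibble::tibble(
    time = rep(times, each = length(problem$obs_names)),
    observable = rep(problem$obs_names, length(times)),
    prediction = as.numeric(preds)
  )
  attr(out, "success") <- TRUE
  out
}
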