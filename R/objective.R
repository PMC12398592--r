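#' Negative log-likelihood under additive Gaussian noise
#'
#' Measurements are modelled as the model output plus independent Gaussian
#' noise with an observable-specific standard deviation,
#' \deqn{J = \tfrac12 \sum_k \left[\log(2\pi\sigma_{s(k)}^2) +
#'   (y_k - \bar y_k)^2/\sigma_{s(k)}^2\right],}
#' summing over measurement records \eqn{k} with observable \eqn{s(k)}.
#' Any non-finite prediction yields `+Inf` (the objective of a failed
#' simulation).
#'
#' @param predictions Numeric vector of model outputs, aligned with the rows
#'   of `data`.
#' @param data Tibble/data frame with at least columns `observable` and
#'   `measurement`.
#' @param sigma Named positive vector of noise standard deviations, one per
#'   observable.
#' @return The negative log-likelihood (scalar).
#' @export
nll <- function(predictions, data, sigma) {
  stopifnot(length(predictions) == nrow(data), all(sigma > 0))
  if (any(!is.finite(predictions))) return(Inf)
  s <- sigma[data$observable]
  r <- data$measurement - predictions
  0.5 * sum(log(2 * pi * s^2) + r^2 / s^2)
}

#' Weight-decay regularised training objective
#'
#' Adds the L2 penalty `lambda * ||theta_ann||^2 / n_ann` to a negative
#' log-likelihood. Normalising by the network parameter count keeps the
#' penalty comparable across architectures sampled in a multi-start run.
#'
#' @param nll_value Negative log-likelihood.
#' @param theta_ann Numeric vector of network weights and biases.
#' @param lambda Regularisation strength, `>= 0` (0 disables the penalty).
#' @param n_ann Parameter count used for normalisation (defaults to
#'   `length(theta_ann)`).
#' @return The penalised objective value.
#' @export
regularised_loss <- function(nll_value, theta_ann, lambda,
                             n_ann = length(theta_ann)) {
  stopifnot(lambda >= 0)
  if (lambda == 0 || n_ann == 0) return(nll_value)
  nll_value + lambda * sum(theta_ann^2) / n_ann
}

#' Closed-form optimal noise parameters
#'
#' For fixed predictions the Gaussian NLL is minimised in each observable's
#' standard deviation at the root-mean-square residual. Useful as a check of
#' the jointly estimated noise and to initialise `sigma`.
#'
#' @param residuals Either a named list of numeric residual vectors (one per
#'   observable) or a data frame with columns `observable` and `residual`.
#' @return Named numeric vector of standard deviations.
#' @export
optimal_sigma <- function(residuals) {
  if (is.data.frame(residuals)) {
    residuals <- split(residuals$residual, residuals$observable)
  }
  if (any(lengths(residuals) == 0)) {
    stop("every observable needs at least one residual", call. = FALSE)
  }
  vapply(residuals, function(r) sqrt(mean(r^2)), numeric(1))
}

# --- objective/gradient builder ---------------------------------------------

#' Build the training objective of a UDE problem on a dataset
#'
#' Returns a set of closures over the packed parameter vector
#' `p = (rho, w, w_obs, log sigma)`: the regularised training objective
#' `fn(p)`, its gradient `gr(p)`, the plain validation NLL `val_nll(p)`
#' (early stopping monitors the unpenalised likelihood), and the plain NLL
#' on any partition. Gradients come from forward sensitivity analysis — a
#' compiled sensitivity integrator for the glycolysis family, a
#' deSolve-based augmented system otherwise — or, on request, from central
#' finite differences through the solver (`gradient = "fd"`, the pragmatic
#' choice for stiff problems where the augmented system is large).
#'
#' @param problem A `ude_problem`.
#' @param data Measurement tibble with columns `time`, `observable`,
#'   `measurement` and (optionally) `partition` (`"train"`/`"validation"`;
#'   missing partition means everything is training data).
#' @param lambda Weight-decay strength.
#' @param rtol,atol Solver tolerances.
#' @param gradient `"auto"`, `"adjoint"`, `"sensitivity"` or `"fd"`. The
#'   adjoint method (one forward solve with dense output plus one backward
#'   adjoint solve with parameter quadratures) has a cost independent of the
#'   network size and is the default on the compiled glycolysis path;
#'   forward sensitivities are the default elsewhere and serve as the
#'   cross-check.
#' @param solver Override of the problem's solver class.
#' @param max_steps Step budget per solve on the compiled path; a start whose
#'   dynamics exhaust it counts as a simulation failure (objective `+Inf`),
#'   which keeps multi-start batches from stalling on pathological draws.
#' @return A `ude_objective` list of closures and metadata.
#' @export
ude_objective <- function(problem, data, lambda = 0, rtol = 1e-6, atol = 1e-8,
                          gradient = c("auto", "adjoint", "sensitivity", "fd"),
                          solver = NULL, max_steps = 8000L) {
  gradient <- match.arg(gradient)
  if (!"partition" %in% names(data)) data$partition <- "train"
  bad <- setdiff(unique(data$observable), problem$obs_names)
  if (length(bad)) {
    stop("unknown observables in data: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$time, .data$observable)
  lay <- par_layout(problem)
  ps <- problem$parameters
  t_all <- sort(unique(data$time))
  t_idx <- match(data$time, t_all)
  o_idx <- match(data$observable, problem$obs_names)
  is_train <- data$partition == "train"
  n_ann <- lay$n_w + lay$n_wo
  use_fast <- identical(problem$fast, "glycolysis") && is.null(problem$ann$fun)
  if (gradient == "auto") gradient <- if (use_fast) "adjoint" else "sensitivity"
  if (gradient == "adjoint" && !use_fast) gradient <- "sensitivity"

  # predictions for every record; optionally d pred / d (theta_free, w, w_obs)
  eval_records <- function(up, need_sens = FALSE) {
    if (use_fast) {
      free_idx <- match(ps$names[ps$free], GLYC_CONS_ORDER) - 1L
      sol <- glyc_fast_solve(problem, up, t_all, rtol, atol, max_steps,
                             sens_cons = if (need_sens) free_idx else integer(0),
                             sens_ann = need_sens && lay$n_w > 0)
      if (!sol$success) return(list(success = FALSE))
      obs_state <- match(problem$obs_names, GLYC_STATES)
      pred <- sol$states[cbind(t_idx, obs_state[o_idx])]
      out <- list(success = TRUE, pred = pred)
      if (need_sens) {
        n_par <- lay$n_rho + lay$n_w
        sens <- array(sol$sens, dim = c(length(t_all), 7, max(n_par, 1)))
        D <- matrix(0, nrow(data), lay$n_rho + lay$n_w + lay$n_wo)
        for (k in seq_len(nrow(data))) {
          D[k, seq_len(n_par)] <- sens[t_idx[k], obs_state[o_idx[k]], ]
        }
        out$dpred <- D
      }
      return(out)
    }
    generic_eval_records(problem, up, t_all, t_idx, o_idx, need_sens,
                         rtol, atol, solver %||% problem$solver)
  }

  rho_to_theta_jac <- function(up) ps_dvalues(ps, up$rho)

  # adjoint gradient on the compiled path: states + total model gradient in
  # one call; the sigma gradient and transform chain rule are applied here
  adjoint_call <- function(up) {
    free_idx <- match(ps$names[ps$free], GLYC_CONS_ORDER) - 1L
    obs_state <- match(problem$obs_names, GLYC_STATES)
    spec <- problem$ann$spec
    s_rec <- up$sigma[o_idx]
    res <- glyc_adjoint_cpp(
      t_all, unname(problem$x0), unname(up$theta[GLYC_CONS_ORDER]),
      problem$fast_opts$include_k5, !is.null(problem$ann),
      if (is.null(spec)) numeric(0) else up$w,
      if (is.null(spec)) c(7L, 1L) else ann_dims(spec),
      if (is.null(spec)) 0L else ann_act_id(spec),
      !is.null(spec) && spec$input_normalisation,
      as.integer(free_idx), lay$n_w > 0,
      as.integer(t_idx - 1L), as.integer(obs_state[o_idx] - 1L),
      data$measurement, ifelse(is_train, 1 / s_rec^2, 0),
      rtol, atol, as.integer(max_steps)
    )
    if (!res$success) return(list(success = FALSE))
    pred <- res$states[cbind(t_idx, obs_state[o_idx])]
    g <- numeric(lay$total)
    gm <- res$grad
    g[lay$i_rho] <- gm[seq_len(lay$n_rho)] * rho_to_theta_jac(up)
    if (lay$n_w > 0) g[lay$i_w] <- gm[lay$n_rho + seq_len(lay$n_w)] +
      if (lambda > 0 && n_ann > 0) 2 * lambda * up$w / n_ann else 0
    r <- pred - data$measurement
    for (oo in seq_along(problem$obs_names)) {
      sel <- is_train & o_idx == oo
      g[lay$i_sig[oo]] <- sum(1 - r[sel]^2 / up$sigma[[oo]]^2)
    }
    list(success = TRUE, pred = pred, grad = g)
  }

  objective_parts <- function(p, need_sens = FALSE) {
    up <- unpack_params(problem, p)
    # exp() under/overflow of log sigma renders the likelihood undefined
    if (any(!is.finite(up$sigma)) || any(up$sigma <= 0)) {
      return(list(success = FALSE))
    }
    ev <- eval_records(up, need_sens)
    if (!ev$success) return(list(success = FALSE))
    list(success = TRUE, up = up, ev = ev,
         resid = ev$pred - data$measurement,
         s = up$sigma[o_idx])
  }

  fn <- function(p) {
    parts <- objective_parts(p)
    if (!parts$success) return(Inf)
    value <- nll(parts$ev$pred[is_train], data[is_train, ],
                 parts$up$sigma)
    regularised_loss(value, c(parts$up$w, parts$up$w_obs), lambda, n_ann)
  }

  gr_sens <- function(p) {
    parts <- objective_parts(p, need_sens = TRUE)
    if (!parts$success) {
      g <- rep(0, lay$total); attr(g, "failed") <- TRUE; return(g)
    }
    grad_from_parts(parts)
  }

  adjoint_parts <- function(p) {
    up <- unpack_params(problem, p)
    if (any(!is.finite(up$sigma)) || any(up$sigma <= 0)) {
      return(list(success = FALSE))
    }
    res <- adjoint_call(up)
    if (!res$success) return(list(success = FALSE))
    list(success = TRUE, up = up, ev = list(pred = res$pred),
         grad = res$grad)
  }

  gr_adj <- function(p) {
    parts <- adjoint_parts(p)
    if (!parts$success) {
      g <- rep(0, lay$total); attr(g, "failed") <- TRUE; return(g)
    }
    parts$grad
  }

  gr_fd <- function(p) {
    g <- numeric(lay$total)
    failed <- FALSE
    for (j in seq_len(lay$total)) {
      h <- 1e-6 * max(1, abs(p[j]))
      pp <- p; pp[j] <- p[j] + h; f1 <- fn(pp)
      pp[j] <- p[j] - h; f2 <- fn(pp)
      if (!is.finite(f1) || !is.finite(f2)) { failed <- TRUE; g[j] <- 0 }
      else g[j] <- (f1 - f2) / (2 * h)
    }
    if (failed) attr(g, "failed") <- TRUE
    g
  }

  value_from_parts <- function(parts) {
    train_nll <- nll(parts$ev$pred[is_train], data[is_train, ], parts$up$sigma)
    val_nll <- if (any(!is_train)) {
      nll(parts$ev$pred[!is_train], data[!is_train, ], parts$up$sigma)
    } else NA_real_
    list(train_nll = train_nll,
         value = regularised_loss(train_nll, c(parts$up$w, parts$up$w_obs),
                                  lambda, n_ann),
         val_nll = val_nll)
  }

  grad_from_parts <- function(parts) {
    up <- parts$up
    r <- parts$resid; s <- parts$s
    wgt <- ifelse(is_train, r / s^2, 0)
    g_model <- drop(crossprod(parts$ev$dpred, wgt))
    g <- numeric(lay$total)
    g[lay$i_rho] <- g_model[lay$i_rho] * rho_to_theta_jac(up)
    if (lay$n_w > 0) g[lay$i_w] <- g_model[lay$i_w]
    if (lay$n_wo > 0) g[lay$i_wo] <- g_model[lay$i_wo]
    for (oo in seq_along(problem$obs_names)) {
      sel <- is_train & o_idx == oo
      g[lay$i_sig[oo]] <- sum(1 - r[sel]^2 / s[sel]^2)
    }
    if (lambda > 0 && n_ann > 0) {
      g[lay$i_w] <- g[lay$i_w] + 2 * lambda * up$w / n_ann
      g[lay$i_wo] <- g[lay$i_wo] + 2 * lambda * up$w_obs / n_ann
    }
    g
  }

  # one sensitivity solve yielding objective value, gradient and both NLLs
  fn_gr <- function(p) {
    if (gradient == "fd") {
      parts <- objective_parts(p)
      if (!parts$success) {
        return(list(success = FALSE, value = Inf, grad = rep(0, lay$total),
                    train_nll = Inf, val_nll = Inf))
      }
      v <- value_from_parts(parts)
      return(c(list(success = TRUE, grad = gr_fd(p)), v))
    }
    if (gradient == "adjoint") {
      parts <- adjoint_parts(p)
      if (!parts$success) {
        return(list(success = FALSE, value = Inf, grad = rep(0, lay$total),
                    train_nll = Inf, val_nll = Inf))
      }
      return(c(list(success = TRUE, grad = parts$grad),
               value_from_parts(parts)))
    }
    parts <- objective_parts(p, need_sens = TRUE)
    if (!parts$success) {
      return(list(success = FALSE, value = Inf, grad = rep(0, lay$total),
                  train_nll = Inf, val_nll = Inf))
    }
    c(list(success = TRUE, grad = grad_from_parts(parts)),
      value_from_parts(parts))
  }

  # one plain solve yielding the objective value and both NLLs
  eval_all <- function(p) {
    parts <- objective_parts(p)
    if (!parts$success) {
      return(list(success = FALSE, value = Inf, train_nll = Inf,
                  val_nll = Inf))
    }
    c(list(success = TRUE), value_from_parts(parts))
  }

  nll_on <- function(p, partition = c("train", "validation", "all")) {
    partition <- match.arg(partition)
    sel <- switch(partition, train = is_train, validation = !is_train,
                  all = rep(TRUE, nrow(data)))
    if (!any(sel)) return(NA_real_)
    parts <- objective_parts(p)
    if (!parts$success) return(Inf)
    nll(parts$ev$pred[sel], data[sel, ], parts$up$sigma)
  }

  structure(
    list(fn = fn,
         gr = switch(gradient, fd = gr_fd, adjoint = gr_adj, gr_sens),
         fn_gr = fn_gr, eval_all = eval_all,
         nll_on = nll_on,
         val_nll = function(p) nll_on(p, "validation"),
         layout = lay, lambda = lambda, n_ann = n_ann, data = data,
         problem = problem, gradient = gradient),
    class = "ude_objective"
  )
}

# generic forward-sensitivity evaluation via deSolve on the augmented system
generic_eval_records <- function(problem, up, t_all, t_idx, o_idx, need_sens,
                                 rtol, atol, solver) {
  n_s <- length(problem$state_names)
  n_o <- length(problem$obs_names)
  ps <- problem$parameters
  free_names <- ps$names[ps$free]
  n_free <- length(free_names)
  n_w <- if (!is.null(problem$ann)) ann_n_params(problem$ann$spec) else 0L
  n_wo <- if (!is.null(problem$obs_ann)) ann_n_params(problem$obs_ann$spec) else 0L
  method <- if (solver == "stiff") "lsoda" else "ode45"

  if (!need_sens) {
    traj <- ude_integrate(problem, up, t_all, solver, rtol, atol)
    if (!traj$success) return(list(success = FALSE))
    states <- as.matrix(traj$data[problem$state_names])
    pred <- vapply(seq_along(t_all), function(i) {
      problem_observables(problem, t_all[i], states[i, ], up$theta, up$w_obs)
    }, numeric(n_o))
    pred <- matrix(pred, nrow = n_o)
    return(list(success = TRUE,
                pred = pred[cbind(o_idx, t_idx)]))
  }

  n_dyn <- n_free + n_w # dynamic sensitivity parameters
  rhs_x <- function(t, x, theta, w) problem_rhs(problem, t, x, theta, w)

  aug <- function(t, y, parms) {
    x <- y[seq_len(n_s)]
    f <- rhs_x(t, x, up$theta, up$w)
    if (n_dyn == 0) return(list(f))
    S <- matrix(y[-seq_len(n_s)], n_s, n_dyn)
    # state Jacobian by central differences of the full RHS (incl. ANN)
    Jx <- matrix(0, n_s, n_s)
    for (j in seq_len(n_s)) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      Jx[, j] <- (rhs_x(t, xp, up$theta, up$w) -
                    rhs_x(t, xm, up$theta, up$w)) / (2 * h)
    }
    G <- matrix(0, n_s, n_dyn)
    for (j in seq_len(n_free)) {
      nm <- free_names[j]
      h <- 1e-7 * max(1, abs(up$theta[[nm]]))
      tp <- up$theta; tp[[nm]] <- tp[[nm]] + h
      tm <- up$theta; tm[[nm]] <- tm[[nm]] - h
      G[, j] <- (rhs_x(t, x, tp, up$w) - rhs_x(t, x, tm, up$w)) / (2 * h)
    }
    if (n_w > 0 && is.null(problem$ann$fun)) {
      u <- problem$ann$inputs(t, x, up$theta)
      jac <- ann_jacobians(problem$ann$spec, up$w, u)
      G[, n_free + seq_len(n_w)] <- problem$ann$placement %*% jac$jac_w
    }
    dS <- Jx %*% S + G
    list(c(f, as.numeric(dS)))
  }

  y0 <- c(problem$x0, numeric(n_s * n_dyn))
  out <- tryCatch(
    suppressWarnings(deSolve::ode(y = y0, times = union_times(t_all),
                                  func = aug, parms = NULL, method = method,
                                  rtol = rtol, atol = atol)),
    error = function(e) NULL
  )
  if (is.null(out) || nrow(out) < length(union_times(t_all)) ||
      any(!is.finite(out[, -1]))) {
    return(list(success = FALSE))
  }
  keep <- match(t_all, out[, 1])
  X <- out[keep, 1 + seq_len(n_s), drop = FALSE]
  Sarr <- array(out[keep, -seq_len(1 + n_s)], dim = c(length(t_all), n_s, n_dyn))

  n_p <- n_free + n_w + n_wo
  pred <- numeric(length(t_idx))
  D <- matrix(0, length(t_idx), n_p)
  obs_at <- function(t, x, theta) {
    problem_observables(problem, t, x, theta, up$w_obs)
  }
  for (i in seq_along(t_all)) {
    x <- X[i, ]; t <- t_all[i]
    y <- obs_at(t, x, up$theta)
    # d h / d x (central differences)
    Hx <- matrix(0, n_o, n_s)
    for (j in seq_len(n_s)) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      Hx[, j] <- (obs_at(t, xp, up$theta) - obs_at(t, xm, up$theta)) / (2 * h)
    }
    Ht <- matrix(0, n_o, n_free)
    for (j in seq_len(n_free)) {
      nm <- free_names[j]
      h <- 1e-7 * max(1, abs(up$theta[[nm]]))
      tp <- up$theta; tp[[nm]] <- tp[[nm]] + h
      tm <- up$theta; tm[[nm]] <- tm[[nm]] - h
      Ht[, j] <- (obs_at(t, x, tp) - obs_at(t, x, tm)) / (2 * h)
    }
    Dt <- matrix(0, n_o, n_p)
    if (n_dyn > 0) {
      Si <- matrix(Sarr[i, , ], n_s, n_dyn)
      Dt[, seq_len(n_dyn)] <- Hx %*% Si
    }
    if (n_free > 0) {
      Dt[, seq_len(n_free)] <- Dt[, seq_len(n_free), drop = FALSE] + Ht
    }
    if (n_wo > 0 && is.null(problem$obs_ann$fun)) {
      u <- problem$obs_ann$inputs(t, x, up$theta)
      jac <- ann_jacobians(problem$obs_ann$spec, up$w_obs, u)
      Dt[, n_free + n_w + seq_len(n_wo)] <-
        problem$obs_ann$placement %*% jac$jac_w
    }
    sel <- which(t_idx == i)
    for (k in sel) {
      pred[k] <- y[o_idx[k]]
      D[k, ] <- Dt[o_idx[k], ]
    }
  }
  list(success = TRUE, pred = pred, dpred = D)
}
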