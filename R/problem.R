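#' Construct a UDE problem
#'
#' A UDE problem couples a mechanistic right-hand side with optional neural
#' network terms entering either the dynamics (additively, through a
#' stoichiometric placement matrix) or the observable mapping. The dynamics
#' are \deqn{dx/dt = f_M(t, x, \theta_M) + B\, f_{ANN}(u(t, x)),}
#' and the observables \eqn{\bar y = h_M(t, x, \theta_M) + B_o\, h_{ANN}(u_o)}.
#'
#' Most users construct problems through the registry, [ude_problem()] with a
#' problem name; this constructor is the extension point for custom systems.
#'
#' @param name Problem identifier.
#' @param state_names Character vector of state identifiers.
#' @param x0 Named numeric initial state (assumed known, not estimated).
#' @param rhs_mech Function `(t, x, theta) -> dx/dt` (numeric, length n_s);
#'   `theta` is the full named mechanistic parameter vector on natural scale.
#' @param observables Function `(t, x, theta) -> named numeric` of length
#'   `n_o`, the mechanistic part of the observable map.
#' @param obs_names Character vector of observable identifiers.
#' @param parameters A [parameter_set()] of the mechanistic parameters.
#' @param ann Optional list describing an ANN term in the dynamics:
#'   `spec` (an [ann_spec()]), `inputs` (`(t, x, theta) -> numeric`),
#'   `placement` (n_s x n_outputs matrix `B`), and optionally `fun`
#'   (a function `(inputs) -> outputs` overriding the network, used to splice
#'   in known "oracle" terms for verification).
#' @param obs_ann Optional analogous list for the observable mapping with an
#'   `n_o x n_outputs` placement matrix.
#' @param horizon Numeric length-2 time window the problem's data live on.
#' @param solver Default solver class, `"nonstiff"` or `"stiff"`.
#' @param fast Internal tag enabling a compiled fast path (`"glycolysis"`).
#' @param fast_opts List of options for the fast path.
#' @return A `ude_problem` object.
#' @export
new_ude_problem <- function(name, state_names, x0, rhs_mech, observables,
                            obs_names, parameters, ann = NULL, obs_ann = NULL,
                            horizon = c(0, 1), solver = "nonstiff",
                            fast = NULL, fast_opts = list()) {
  stopifnot(length(x0) == length(state_names))
  if (!is.null(ann)) {
    stopifnot(is.matrix(ann$placement),
              nrow(ann$placement) == length(state_names),
              ncol(ann$placement) == ann$spec$n_outputs)
  }
  if (!is.null(obs_ann)) {
    stopifnot(is.matrix(obs_ann$placement),
              nrow(obs_ann$placement) == length(obs_names),
              ncol(obs_ann$placement) == obs_ann$spec$n_outputs)
  }
  structure(
    list(name = name, state_names = state_names,
         x0 = setNames(as.numeric(x0), state_names),
         rhs_mech = rhs_mech, observables = observables,
         obs_names = obs_names, parameters = parameters, ann = ann,
         obs_ann = obs_ann, horizon = horizon,
         solver = match.arg(solver, c("nonstiff", "stiff")),
         fast = fast, fast_opts = fast_opts),
    class = "ude_problem"
  )
}

#' @export
print.ude_problem <- function(x, ...) {
  cat(sprintf("<ude_problem> %s: %d states, %d observables, %d free parameters\n",
              x$name, length(x$state_names), length(x$obs_names),
              sum(x$parameters$free)))
  if (!is.null(x$ann)) {
    cat("  dynamics ANN: "); print(x$ann$spec)
  }
  if (!is.null(x$obs_ann)) {
    cat("  observable ANN: "); print(x$obs_ann$spec)
  }
  invisible(x)
}

#' Problem registry
#'
#' `ude_problems()` lists the built-in problems; `ude_problem(name, ...)`
#' builds one. Available problems: the fully mechanistic glycolysis
#' oscillator (`"glycolysis"`), its UDE variant with the ATP consumption term
#' replaced by a network (`"glycolysis_ude"`), the mechanistic STAT5
#' dimerisation model (`"stat5"`), and its four UDE scenarios
#' (`"stat5_scenario1"` ... `"stat5_scenario4"`).
#'
#' @param name Problem name from `ude_problems()`.
#' @param ... Passed to the specific builder (e.g. `ann_spec` arguments).
#' @return `ude_problem()` returns a `ude_problem`; `ude_problems()` a
#'   character vector.
#' @export
ude_problem <- function(name, ...) {
  builders <- list(
    glycolysis = glycolysis_problem,
    glycolysis_ude = glycolysis_ude,
    stat5 = stat5_problem,
    stat5_scenario1 = function(...) stat5_scenario(1, ...),
    stat5_scenario2 = function(...) stat5_scenario(2, ...),
    stat5_scenario3 = function(...) stat5_scenario(3, ...),
    stat5_scenario4 = function(...) stat5_scenario(4, ...)
  )
  name <- match.arg(name, names(builders))
  builders[[name]](...)
}

#' @rdname ude_problem
#' @export
ude_problems <- function() {
  c("glycolysis", "glycolysis_ude", "stat5", paste0("stat5_scenario", 1:4))
}

#' Splice an oracle function in place of a problem's network
#'
#' Replaces the dynamics network by an arbitrary function of the network
#' inputs. Used to verify that a UDE with the exact missing term recovers the
#' reference ODE.
#'
#' @param problem A `ude_problem` with a dynamics ANN.
#' @param fun Function mapping the ANN input vector to the ANN output vector.
#' @return The modified problem.
#' @export
set_ann_oracle <- function(problem, fun) {
  stopifnot(inherits(problem, "ude_problem"), !is.null(problem$ann))
  problem$ann$fun <- fun
  problem$fast <- NULL # oracle functions take the generic path
  problem
}

# full RHS including any ANN term (generic R path)
problem_rhs <- function(problem, t, x, theta, w = NULL) {
  dx <- problem$rhs_mech(t, x, theta)
  if (!is.null(problem$ann)) {
    u <- problem$ann$inputs(t, x, theta)
    out <- if (!is.null(problem$ann$fun)) {
      problem$ann$fun(u)
    } else {
      ann_forward(problem$ann$spec, w, u)
    }
    dx <- dx + as.numeric(problem$ann$placement %*% out)
  }
  dx
}

# observables including any observable-ANN term
problem_observables <- function(problem, t, x, theta, w_obs = NULL) {
  y <- problem$observables(t, x, theta)
  if (!is.null(problem$obs_ann)) {
    u <- problem$obs_ann$inputs(t, x, theta)
    out <- if (!is.null(problem$obs_ann$fun)) {
      problem$obs_ann$fun(u)
    } else {
      ann_forward(problem$obs_ann$spec, w_obs, u)
    }
    y <- y + as.numeric(problem$obs_ann$placement %*% out)
  }
  y
}

# --- parameter vector packing ------------------------------------------------
# optimiser coordinate layout: [rho (free mech), w_ann, w_obs_ann, log sigma]

n_ann_params <- function(problem) {
  (if (!is.null(problem$ann)) ann_n_params(problem$ann$spec) else 0L) +
    (if (!is.null(problem$obs_ann)) ann_n_params(problem$obs_ann$spec) else 0L)
}

par_layout <- function(problem) {
  n_rho <- sum(problem$parameters$free)
  n_w <- if (!is.null(problem$ann)) ann_n_params(problem$ann$spec) else 0L
  n_wo <- if (!is.null(problem$obs_ann)) ann_n_params(problem$obs_ann$spec) else 0L
  n_sig <- length(problem$obs_names)
  list(n_rho = n_rho, n_w = n_w, n_wo = n_wo, n_sig = n_sig,
       i_rho = seq_len(n_rho), i_w = n_rho + seq_len(n_w),
       i_wo = n_rho + n_w + seq_len(n_wo),
       i_sig = n_rho + n_w + n_wo + seq_len(n_sig),
       total = n_rho + n_w + n_wo + n_sig)
}

#' Pack and unpack optimiser parameter vectors
#'
#' Training works on a single unbounded coordinate vector
#' `p = (rho, w, w_obs, log sigma)`: the free mechanistic parameters on the
#' tanh-transformed scale, the network weights, and the log noise SDs.
#' `pack_params()` assembles it from natural-scale pieces; `unpack_params()`
#' recovers them.
#'
#' @param problem A `ude_problem`.
#' @param theta Named natural-scale mechanistic values (defaults to the
#'   problem's reference values).
#' @param w,w_obs Network weight vectors (default zero).
#' @param sigma Positive noise SDs per observable (default 1).
#' @return `pack_params()`: numeric vector; `unpack_params()`: list with
#'   `rho`, `theta`, `w`, `w_obs`, `log_sigma`, `sigma`.
#' @export
pack_params <- function(problem, theta = problem$parameters$values, w = NULL,
                        w_obs = NULL, sigma = NULL) {
  lay <- par_layout(problem)
  ps <- problem$parameters
  rho <- inverse_transform(theta[ps$names][ps$free], ps$b_l[ps$free],
                           ps$b_u[ps$free], ps$a[ps$free])
  if (is.null(w)) w <- numeric(lay$n_w)
  if (is.null(w_obs)) w_obs <- numeric(lay$n_wo)
  if (is.null(sigma)) sigma <- rep(1, lay$n_sig)
  c(rho, w, w_obs, log(sigma))
}

#' @rdname pack_params
#' @param p Packed parameter vector.
#' @export
unpack_params <- function(problem, p) {
  lay <- par_layout(problem)
  stopifnot(length(p) == lay$total)
  ps <- problem$parameters
  theta <- ps_values(ps, p[lay$i_rho])
  list(rho = p[lay$i_rho], theta = theta, w = p[lay$i_w], w_obs = p[lay$i_wo],
       log_sigma = p[lay$i_sig],
       sigma = setNames(exp(p[lay$i_sig]), problem$obs_names))
}
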