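# Yeast glycolysis oscillator (Ruoff-type core model): seven species
# (S1 glucose pool, S2/S3/S4 intermediates, N2 NADH, A3 ATP, S4_ex
# extracellular pyruvate/acetaldehyde pool) with conserved NAD and adenosine
# totals N and A. With the published parameterisation the system shows stable
# limit-cycle oscillations; species N2 and A3 are observed directly.

GLYC_CONS_ORDER <- c("J0", "k1", "k2", "k3", "k4", "k5", "k6", "K1",
                     "kappa", "phi", "k_ex", "N", "A")
GLYC_STATES <- c("S1", "S2", "S3", "S4", "N2", "A3", "S4_ex")

ref_table <- function(file) {
  path <- system.file("extdata", file, package = "udefit")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Reference parameterisation of the glycolysis model
#'
#' Published reference values of the kinetic constants (model units, time in
#' minutes) together with the estimation bounds used by the training
#' pipeline (one decade either side of the reference value). The adenosine
#' pool total `A` is held fixed; the remaining twelve parameters are free.
#' Values are shipped as a plain-text fixture and read at call time.
#'
#' @param free Optional logical/character override of which parameters are
#'   free (default as shipped).
#' @return A [parameter_set()].
#' @export
glycolysis_parameters <- function(free = NULL) {
  tab <- ref_table("glycolysis_reference_parameters.tsv")
  tab <- tab[match(GLYC_CONS_ORDER, tab$parameter), ]
  fr <- tab$free
  if (!is.null(free)) {
    fr <- if (is.character(free)) tab$parameter %in% free else rep_len(free, nrow(tab))
  }
  parameter_set(tab$parameter, tab$value, tab$b_l, tab$b_u, free = fr)
}

#' Initial state of the glycolysis model
#'
#' A state on (close to) the reference limit cycle, treated as known during
#' estimation. Shipped as a plain-text fixture.
#'
#' @return Named numeric vector of the seven species.
#' @export
glycolysis_x0 <- function() {
  tab <- ref_table("glycolysis_initial_state.tsv")
  setNames(tab$value, tab$state)[GLYC_STATES]
}

#' Glycolysis right-hand side
#'
#' Time derivatives of the seven glycolysis species. ATP inhibition of the
#' first reaction uses the Hill-type factor `A3 / (1 + (A3/K1)^4)`. With
#' `include_k5 = FALSE` the ATP consumption term `-k5 * A3` is removed from
#' the A3 equation; this truncated system is the mechanistic backbone of the
#' glycolysis UDE.
#'
#' @param t Time (unused; the system is autonomous).
#' @param x Named or positional numeric state `(S1, S2, S3, S4, N2, A3,
#'   S4_ex)`.
#' @param theta Named numeric vector with entries `J0, k1..k6, K1, kappa,
#'   phi, k_ex, N, A`.
#' @param include_k5 Keep the ATP consumption term? Default `TRUE`.
#' @return Numeric length-7 derivative vector.
#' @export
glycolysis_rhs <- function(t, x, theta, include_k5 = TRUE) {
  S1 <- x[[1]]; S2 <- x[[2]]; S3 <- x[[3]]; S4 <- x[[4]]
  N2 <- x[[5]]; A3 <- x[[6]]; S4_ex <- x[[7]]
  J0 <- theta[["J0"]]; k1 <- theta[["k1"]]; k2 <- theta[["k2"]]
  k3 <- theta[["k3"]]; k4 <- theta[["k4"]]; k5 <- theta[["k5"]]
  k6 <- theta[["k6"]]; K1 <- theta[["K1"]]; kappa <- theta[["kappa"]]
  phi <- theta[["phi"]]; k_ex <- theta[["k_ex"]]
  N <- theta[["N"]]; A <- theta[["A"]]

  v1 <- k1 * S1 * A3 / (1 + (A3 / K1)^4)
  vN <- k2 * S2 * (N - N2)
  vA <- k3 * S3 * (A - A3)
  c(J0 - v1,
    2 * v1 - vN - k6 * S2 * N2,
    vN - vA,
    vA - k4 * S4 * N2 - kappa * (S4 - S4_ex),
    vN - k4 * S4 * N2 - k6 * S2 * N2,
    -2 * v1 + 2 * vA - (if (include_k5) k5 * A3 else 0),
    phi * kappa * (S4 - S4_ex) - k_ex * S4_ex)
}

glyc_observables <- function(t, x, theta) {
  c(N2 = x[[5]], A3 = x[[6]])
}

#' Mechanistic glycolysis problem
#'
#' The full reference ODE with twelve free parameters (all kinetic constants
#' and the NAD pool total; the adenosine total is fixed) and direct
#' observation of `N2` and `A3`. Training data cover `t` in `[0, 1.5]` min,
#' roughly one oscillation period; predictions are assessed on `(1.5, 5]`.
#'
#' @param parameters Optional [parameter_set()] override.
#' @return A `ude_problem`.
#' @export
glycolysis_problem <- function(parameters = glycolysis_parameters()) {
  new_ude_problem(
    name = "glycolysis",
    state_names = GLYC_STATES, x0 = glycolysis_x0(),
    rhs_mech = function(t, x, theta) glycolysis_rhs(t, x, theta, include_k5 = TRUE),
    observables = glyc_observables, obs_names = c("N2", "A3"),
    parameters = parameters, horizon = c(0, 5), solver = "nonstiff",
    fast = "glycolysis", fast_opts = list(include_k5 = TRUE)
  )
}

#' Glycolysis UDE: ATP consumption replaced by a network
#'
#' Removes the `-k5 * A3` term from the A3 equation and adds a neural
#' network output in its place. The network receives all seven state
#' variables, so recovering the data-generating process requires it to learn
#' a dependence on the ATP species alone. `k5` disappears from the estimated
#' parameter list (eleven free mechanistic parameters remain).
#'
#' @param spec An [ann_spec()] with 7 inputs and 1 output.
#' @param parameters Optional [parameter_set()] override (must not free `k5`).
#' @return A `ude_problem`.
#' @export
glycolysis_ude <- function(spec = ann_spec(7, 1, n_hidden_layers = 1, width = 5),
                           parameters = NULL) {
  if (spec$n_inputs != 7 || spec$n_outputs != 1) {
    stop("glycolysis UDE network must map 7 state inputs to 1 output",
         call. = FALSE)
  }
  if (is.null(parameters)) {
    parameters <- glycolysis_parameters(
      free = setdiff(GLYC_CONS_ORDER, c("k5", "A"))
    )
  }
  if (parameters$free[["k5"]]) {
    stop("k5 is replaced by the network and cannot be free", call. = FALSE)
  }
  placement <- matrix(0, 7, 1, dimnames = list(GLYC_STATES, NULL))
  placement["A3", 1] <- 1
  new_ude_problem(
    name = "glycolysis_ude",
    state_names = GLYC_STATES, x0 = glycolysis_x0(),
    rhs_mech = function(t, x, theta) glycolysis_rhs(t, x, theta, include_k5 = FALSE),
    observables = glyc_observables, obs_names = c("N2", "A3"),
    parameters = parameters,
    ann = list(spec = spec,
               inputs = function(t, x, theta) as.numeric(x),
               placement = placement),
    horizon = c(0, 5), solver = "nonstiff",
    fast = "glycolysis", fast_opts = list(include_k5 = FALSE)
  )
}
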