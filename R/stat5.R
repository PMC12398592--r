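# STAT5 dimerisation after erythropoietin stimulation (Boehm-type model):
# cytoplasmic STAT5A/STAT5B monomers are phosphorylated under a decaying Epo
# input, dimerise (pApA, pBpB, pApB), are imported into the nucleus
# (nucpApA, nucpBpB, nucpApB) and exported back as monomers. Compartment
# volumes and the isotope-label fraction specC17 are fixed at their printed
# values. Measurements are relative phosphorylation/abundance ratios.

STAT5_STATES <- c("STAT5A", "STAT5B", "pApA", "pBpB", "pApB",
                  "nucpApA", "nucpBpB", "nucpApB")
STAT5_OBS <- c("pSTAT5A_rel", "pSTAT5B_rel", "rSTAT5A_rel")

STAT5_V_CYT <- 1.4
STAT5_V_NUC <- 0.45
STAT5_SPECC17 <- 0.107
STAT5_RATIO <- 0.693    # initial STAT5A fraction of the total pool
STAT5_TOTAL <- 207.6    # total STAT5 concentration at t = 0

#' Reference parameterisation of the STAT5 dimerisation model
#'
#' Published nominal values of the six kinetic rates (units 1/min, except the
#' import/phosphorylation rates in their native units) with the benchmark
#' estimation bounds `[1e-5, 1e5]`. The three augmentation export rates used
#' by Scenario 3 are included with a nominal value inside the bounds. Shipped
#' as a plain-text fixture and read at call time.
#'
#' @param scenario Integer 0 (base model) or 1--4; selects which parameters
#'   are part of the set.
#' @return A [parameter_set()].
#' @export
stat5_parameters <- function(scenario = 0) {
  tab <- ref_table("stat5_reference_parameters.tsv")
  base <- c("Epo_degradation_BaF3", "k_exp_hetero", "k_exp_homo",
            "k_imp_hetero", "k_imp_homo", "k_phos")
  keep <- if (scenario == 3) c(base, "k_exp_aug_A", "k_exp_aug_B",
                               "k_exp_aug_AB") else base
  tab <- tab[match(keep, tab$parameter), ]
  parameter_set(tab$parameter, tab$value, tab$b_l, tab$b_u, free = tab$free)
}

#' Initial state of the STAT5 model
#'
#' Monomers start at the measured total split by the labelling ratio; all
#' dimer species start at zero.
#'
#' @return Named numeric vector of the eight species.
#' @export
stat5_x0 <- function() {
  setNames(c(STAT5_TOTAL * STAT5_RATIO, STAT5_TOTAL * (1 - STAT5_RATIO),
             0, 0, 0, 0, 0, 0), STAT5_STATES)
}

#' Erythropoietin stimulus
#'
#' Exponentially decaying Epo concentration,
#' `1.25e-7 * exp(-Epo_degradation_BaF3 * t)`.
#'
#' @param t Time (minutes), `t >= 0`.
#' @param Epo_degradation_BaF3 Decay rate (1/min).
#' @return Concentration (units of the model input).
#' @export
epo_input <- function(t, Epo_degradation_BaF3) {
  1.25e-07 * exp(-Epo_degradation_BaF3 * t)
}

#' STAT5 dimerisation right-hand side
#'
#' Time derivatives of the eight STAT5 species under the decaying Epo input.
#'
#' @param t Time (minutes).
#' @param x State vector `(STAT5A, STAT5B, pApA, pBpB, pApB, nucpApA,
#'   nucpBpB, nucpApB)`.
#' @param theta Named parameter vector with the six kinetic rates.
#' @return Numeric length-8 derivative vector.
#' @export
stat5_rhs <- function(t, x, theta) {
  A <- x[[1]]; B <- x[[2]]; pApA <- x[[3]]; pBpB <- x[[4]]; pApB <- x[[5]]
  nA <- x[[6]]; nB <- x[[7]]; nAB <- x[[8]]
  kph <- theta[["k_phos"]]
  kih <- theta[["k_imp_homo"]]; kie <- theta[["k_imp_hetero"]]
  keh <- theta[["k_exp_homo"]]; kee <- theta[["k_exp_hetero"]]
  E <- epo_input(t, theta[["Epo_degradation_BaF3"]])
  r <- STAT5_V_NUC / STAT5_V_CYT
  ri <- STAT5_V_CYT / STAT5_V_NUC
  c(-2 * E * A^2 * kph - E * A * B * kph + 2 * r * keh * nA + r * kee * nAB,
    -E * A * B * kph - 2 * E * B^2 * kph + r * kee * nAB + 2 * r * keh * nB,
    E * A^2 * kph - kih * pApA,
    E * B^2 * kph - kih * pBpB,
    E * A * B * kph - kie * pApB,
    ri * kih * pApA - keh * nA,
    ri * kih * pBpB - keh * nB,
    ri * kie * pApB - kee * nAB)
}

#' STAT5 observable mapping
#'
#' Relative phosphorylation degrees of STAT5A and STAT5B and the relative
#' STAT5A abundance, in percent, computed from the cytoplasmic species and
#' the fixed label fraction `specC17 = 0.107`.
#'
#' @param x State vector (length >= 5; uses STAT5A, STAT5B, pApA, pBpB,
#'   pApB).
#' @param specC17 Label fraction, default the printed value.
#' @return Named numeric length-3 vector
#'   `(pSTAT5A_rel, pSTAT5B_rel, rSTAT5A_rel)`.
#' @export
stat5_observables <- function(x, specC17 = STAT5_SPECC17) {
  A <- x[[1]]; B <- x[[2]]; pApA <- x[[3]]; pBpB <- x[[4]]; pApB <- x[[5]]
  s <- specC17
  c(pSTAT5A_rel = (100 * pApB + 200 * pApA * s) /
      (pApB + A * s + 2 * pApA * s),
    pSTAT5B_rel = -(100 * pApB - 200 * pBpB * (s - 1)) /
      ((B * (s - 1) - pApB) + 2 * pBpB * (s - 1)),
    rSTAT5A_rel = (100 * pApB + 100 * A * s + 200 * pApA * s) /
      (2 * pApB + A * s + 2 * pApA * s - B * (s - 1) - 2 * pBpB * (s - 1)))
}

stat5_obs_fn <- function(t, x, theta) stat5_observables(x)

#' Mechanistic STAT5 problem
#'
#' The eight-state reference ODE with six free kinetic rates, observed
#' through the three relative ratios at measurement times up to 240 min.
#'
#' @param parameters Optional [parameter_set()] override.
#' @return A `ude_problem`.
#' @export
stat5_problem <- function(parameters = stat5_parameters()) {
  new_ude_problem(
    name = "stat5", state_names = STAT5_STATES, x0 = stat5_x0(),
    rhs_mech = stat5_rhs, observables = stat5_obs_fn, obs_names = STAT5_OBS,
    parameters = parameters, horizon = c(0, 240), solver = "stiff"
  )
}

#' STAT5 UDE scenarios
#'
#' Four ways of replacing or augmenting parts of the STAT5 model with a
#' network:
#'
#' * **Scenario 1** replaces the nuclear pApA export/dissociation flux. The
#'   single network output enters the STAT5A equation as
#'   `+2 (V_nuc/V_cyt) f_ANN` and the nucpApA equation as `-f_ANN`, so the
#'   flux conserves total monomer count across compartments by construction.
#'   Inputs: all eight states.
#' * **Scenario 2** lets the network supply the entire pApB derivative.
#'   Inputs: the eight states plus the current Epo stimulus.
#' * **Scenario 3** keeps the full mechanism and appends three augmentation
#'   species `K_A, K_B, K_AB` (initially zero) whose dynamics come from a
#'   six-output network; the augmentation species feed back into the monomer
#'   equations through mass-action export terms with rates `k_exp_aug_*`, and
#'   three further outputs perturb the nuclear dimer equations. Inputs:
#'   `nucpApA, nucpApB, nucpBpB, K_A, K_B, K_AB`.
#' * **Scenario 4** keeps the dynamics fully mechanistic and replaces the
#'   `rSTAT5A_rel` observable by a network of all eight states.
#'
#' @param scenario Integer 1--4.
#' @param spec An [ann_spec()] with dimensions matching the scenario
#'   (defaults to the canonical 3-layer, 5-neuron tanh network for
#'   scenarios 1--3 and a 1-layer network for scenario 4).
#' @param parameters Optional [parameter_set()] override.
#' @return A `ude_problem`.
#' @export
stat5_scenario <- function(scenario, spec = NULL, parameters = NULL) {
  stopifnot(scenario %in% 1:4)
  dims_needed <- list(c(8L, 1L), c(9L, 1L), c(6L, 6L), c(8L, 1L))[[scenario]]
  if (is.null(spec)) {
    spec <- if (scenario == 4) {
      ann_spec(dims_needed[1], dims_needed[2], n_hidden_layers = 1, width = 5)
    } else {
      ann_spec(dims_needed[1], dims_needed[2], n_hidden_layers = 3, width = 5,
               activation = "tanh")
    }
  }
  if (spec$n_inputs != dims_needed[1] || spec$n_outputs != dims_needed[2]) {
    stop(sprintf("scenario %d needs a %d -> %d network", scenario,
                 dims_needed[1], dims_needed[2]), call. = FALSE)
  }
  if (is.null(parameters)) {
    parameters <- stat5_parameters(scenario = if (scenario == 3) 3 else 0)
  }
  name <- paste0("stat5_scenario", scenario)

  if (scenario == 1) {
    # drop the pApA export flux from both equations; the network replaces it
    rhs <- function(t, x, theta) {
      dx <- stat5_rhs(t, x, theta)
      keh <- theta[["k_exp_homo"]]
      r <- STAT5_V_NUC / STAT5_V_CYT
      dx[1] <- dx[1] - 2 * r * keh * x[[6]]
      dx[6] <- dx[6] + keh * x[[6]]
      dx
    }
    placement <- matrix(0, 8, 1, dimnames = list(STAT5_STATES, NULL))
    placement["STAT5A", 1] <- 2 * STAT5_V_NUC / STAT5_V_CYT
    placement["nucpApA", 1] <- -1
    return(new_ude_problem(
      name = name, state_names = STAT5_STATES, x0 = stat5_x0(),
      rhs_mech = rhs, observables = stat5_obs_fn, obs_names = STAT5_OBS,
      parameters = parameters,
      ann = list(spec = spec, inputs = function(t, x, theta) as.numeric(x),
                 placement = placement),
      horizon = c(0, 240), solver = "stiff"
    ))
  }

  if (scenario == 2) {
    rhs <- function(t, x, theta) {
      dx <- stat5_rhs(t, x, theta)
      dx[5] <- 0 # the network supplies the whole pApB derivative
      dx
    }
    placement <- matrix(0, 8, 1, dimnames = list(STAT5_STATES, NULL))
    placement["pApB", 1] <- 1
    return(new_ude_problem(
      name = name, state_names = STAT5_STATES, x0 = stat5_x0(),
      rhs_mech = rhs, observables = stat5_obs_fn, obs_names = STAT5_OBS,
      parameters = parameters,
      ann = list(spec = spec,
                 inputs = function(t, x, theta) {
                   c(as.numeric(x),
                     epo_input(t, theta[["Epo_degradation_BaF3"]]))
                 },
                 placement = placement),
      horizon = c(0, 240), solver = "stiff"
    ))
  }

  if (scenario == 3) {
    states <- c(STAT5_STATES, "K_A", "K_B", "K_AB")
    rhs <- function(t, x, theta) {
      dx8 <- stat5_rhs(t, x[1:8], theta)
      kA <- theta[["k_exp_aug_A"]]; kB <- theta[["k_exp_aug_B"]]
      kAB <- theta[["k_exp_aug_AB"]]
      dx8[1] <- dx8[1] + kA * x[[9]] + kAB * x[[11]]
      dx8[2] <- dx8[2] + kB * x[[10]] + kAB * x[[11]]
      c(dx8, -kA * x[[9]], -kB * x[[10]], -kAB * x[[11]])
    }
    placement <- matrix(0, 11, 6, dimnames = list(states, NULL))
    placement["nucpApA", 1] <- 1
    placement["nucpBpB", 2] <- 1
    placement["nucpApB", 3] <- 1
    placement["K_A", 4] <- 1
    placement["K_B", 5] <- 1
    placement["K_AB", 6] <- 1
    return(new_ude_problem(
      name = name, state_names = states,
      x0 = c(stat5_x0(), K_A = 0, K_B = 0, K_AB = 0),
      rhs_mech = rhs,
      observables = function(t, x, theta) stat5_observables(x[1:8]),
      obs_names = STAT5_OBS, parameters = parameters,
      ann = list(spec = spec,
                 inputs = function(t, x, theta) {
                   as.numeric(x[c(6, 8, 7, 9, 10, 11)])
                 },
                 placement = placement),
      horizon = c(0, 240), solver = "stiff"
    ))
  }

  # scenario 4: network observable replaces rSTAT5A_rel
  obs_mech <- function(t, x, theta) {
    y <- stat5_observables(x)
    y["rSTAT5A_rel"] <- 0
    y
  }
  placement <- matrix(0, 3, 1, dimnames = list(STAT5_OBS, NULL))
  placement["rSTAT5A_rel", 1] <- 1
  new_ude_problem(
    name = name, state_names = STAT5_STATES, x0 = stat5_x0(),
    rhs_mech = stat5_rhs, observables = obs_mech, obs_names = STAT5_OBS,
    parameters = parameters,
    obs_ann = list(spec = spec, inputs = function(t, x, theta) as.numeric(x),
                   placement = placement),
    horizon = c(0, 240), solver = "stiff"
  )
}
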