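# Mechanistic models and their UDE variants

test_that("glycolysis RHS reproduces hand-evaluated derivatives", {
  th <- c(J0 = 1, k1 = 1, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0, K1 = 1,
          kappa = 0, phi = 0, k_ex = 0, N = 1, A = 4)
  x <- c(S1 = 1, S2 = 0, S3 = 0, S4 = 0, N2 = 0, A3 = 1, S4_ex = 0)
  dx <- glycolysis_rhs(0, x, th)
  expect_equal(dx[1], 1 - 1 * 1 * (1 / (1 + 1))) # 0.5
  # all states zero: dS1/dt = J0, dS4_ex/dt = 0
  th2 <- glycolysis_parameters()$values
  dx0 <- glycolysis_rhs(0, rep(0, 7), th2)
  expect_equal(dx0[1], th2[["J0"]])
  expect_equal(dx0[7], 0)
  # Hill factor vanishes as A3 grows
  xb <- x; xb[6] <- 1e8
  expect_lt(abs(glycolysis_rhs(0, xb, th)[1] - 1), 1e-12)
})

test_that("reference glycolysis parameterisation sustains oscillations", {
  tt <- seq(0, 5, length.out = 500)
  tr <- ude_integrate(glycolysis_problem(), times = tt)
  expect_true(tr$success)
  for (obs in c("N2", "A3")) {
    v <- tr$data[[obs]]
    peaks <- sum(diff(sign(diff(v))) < 0)
    expect_gte(peaks, 3)
  }
})

test_that("glycolysis UDE at zero network equals the truncated ODE, and the
           exact-term oracle restores the full ODE", {
  prob_ude <- glycolysis_ude()
  w0 <- ann_init(prob_ude$ann$spec, 1)
  tt <- seq(0, 5, length.out = 101)
  k5 <- glycolysis_parameters()$values[["k5"]]

  # zero-init ANN -> truncated ODE (independent deSolve integration)
  truncated <- function(t, x, parms) {
    list(glycolysis_rhs(t, x, parms, include_k5 = FALSE))
  }
  ref <- deSolve::ode(glycolysis_x0(), tt, truncated,
                      glycolysis_parameters()$values, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  tr0 <- ude_integrate(prob_ude, list(w = w0), tt, rtol = 1e-10, atol = 1e-12)
  expect_true(tr0$success)
  expect_equal(as.matrix(tr0$data[-1]), unname(ref[, -1]),
               tolerance = 1e-6, ignore_attr = TRUE)

  # oracle network g(x) = -k5 * A3 -> full reference ODE
  prob_or <- set_ann_oracle(prob_ude, function(u) -k5 * u[6])
  tr1 <- ude_integrate(prob_or, list(w = w0), tt, rtol = 1e-10, atol = 1e-12)
  full <- deSolve::ode(glycolysis_x0(), tt, function(t, x, parms) {
    list(glycolysis_rhs(t, x, parms, include_k5 = TRUE))
  }, glycolysis_parameters()$values, method = "ode45",
  rtol = 1e-10, atol = 1e-12)
  ref_states <- unname(full[, -1])
  rel <- abs(as.matrix(tr1$data[-1]) - ref_states) / (abs(ref_states) + 1e-10)
  expect_lt(max(rel), 1e-6)

  # k5 is not in the UDE's free parameter list: 11 free, not 12
  expect_equal(sum(prob_ude$parameters$free), 11)
  expect_false("k5" %in% prob_ude$parameters$names[prob_ude$parameters$free])
})

test_that("Epo input decays exponentially from its printed amplitude", {
  expect_equal(epo_input(0, 0.3), 1.25e-07)
  expect_equal(epo_input(10, 0), 1.25e-07)
  expect_equal(epo_input(1 / 0.3, 0.3), 1.25e-07 * exp(-1))
})

test_that("STAT5 RHS matches hand evaluations and conserves monomer mass", {
  th <- stat5_parameters()$values
  expect_equal(stat5_rhs(0, rep(0, 8), th), rep(0, 8))
  # single-species hand check
  k <- 2.5
  th2 <- th; th2[["k_phos"]] <- k; th2[["Epo_degradation_BaF3"]] <- 0
  E <- 1.25e-07
  dx <- stat5_rhs(0, c(1, 0, 0, 0, 0, 0, 0, 0), th2)
  expect_equal(dx[1], -2 * E * k)
  expect_equal(dx[3], E * k)
  # conservation along a trajectory
  prob <- stat5_problem()
  tt <- seq(0, 240, length.out = 50)
  tr <- ude_integrate(prob, times = tt, rtol = 1e-10, atol = 1e-12)
  expect_true(tr$success)
  X <- as.matrix(tr$data[-1])
  total <- 1.4 * (X[, 1] + X[, 2] + 2 * (X[, 3] + X[, 4] + X[, 5])) +
    0.45 * 2 * (X[, 6] + X[, 7] + X[, 8])
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-6)
})

test_that("STAT5 observables reproduce hand-evaluated ratios", {
  y <- stat5_observables(c(1, 0, 1, 0, 0))
  expect_equal(unname(y["pSTAT5A_rel"]), 200 / 3, tolerance = 1e-12)
  y2 <- stat5_observables(c(5, 0, 0, 0, 0))
  expect_equal(unname(y2["pSTAT5A_rel"]), 0)
  y3 <- stat5_observables(c(1, 1, 0, 0, 0))
  expect_equal(unname(y3["rSTAT5A_rel"]), 10.7, tolerance = 1e-12)
})

test_that("every scenario with zero network reduces to its mechanistic
           backbone (independent integration of the printed equations)", {
  states8 <- c("STAT5A", "STAT5B", "pApA", "pBpB", "pApB",
               "nucpApA", "nucpBpB", "nucpApB")
  tt <- seq(0, 240, length.out = 30)
  th <- stat5_parameters(scenario = 3)$values
  backbones <- c("s1_backbone", "s2_backbone", "full", "full")
  for (sc in 1:4) {
    prob <- stat5_scenario(sc)
    w0 <- if (!is.null(prob$ann)) ann_init(prob$ann$spec, 1) else NULL
    wo0 <- if (!is.null(prob$obs_ann)) ann_init(prob$obs_ann$spec, 1) else NULL
    tr <- ude_integrate(prob, list(w = w0, w_obs = wo0), tt,
                        rtol = 1e-9, atol = 1e-11)
    expect_true(tr$success, info = paste("scenario", sc))
    ref <- deSolve::ode(
      stat5_x0(), tt,
      function(t, x, parms) list(ref_stat5_rhs(t, x, th, backbones[sc])),
      NULL, method = "lsoda", rtol = 1e-9, atol = 1e-11
    )
    X <- as.matrix(tr$data[states8])
    R <- unname(ref[, -1])
    expect_equal(X, R, tolerance = 1e-5, ignore_attr = TRUE,
                 info = paste("scenario", sc))
  }
})

test_that("scenario 2 with the exact phosphorylation oracle matches the ODE", {
  th <- stat5_parameters()$values
  prob <- stat5_scenario(2)
  # oracle: u = (8 states, BaF3_Epo); true pApB RHS
  prob <- set_ann_oracle(prob, function(u) {
    u[9] * u[1] * u[2] * th[["k_phos"]] - th[["k_imp_hetero"]] * u[5]
  })
  tt <- seq(0, 240, length.out = 25)
  tr <- ude_integrate(prob, times = tt, rtol = 1e-9, atol = 1e-11)
  ref <- ude_integrate(stat5_problem(), times = tt, rtol = 1e-9, atol = 1e-11)
  expect_true(tr$success)
  expect_equal(tr$data$pApB, ref$data$pApB, tolerance = 1e-5)
})

test_that("scenario dimension mismatches are rejected", {
  expect_error(stat5_scenario(1, spec = ann_spec(3, 1)), "8 -> 1")
  expect_error(stat5_scenario(3, spec = ann_spec(6, 1)), "6 -> 6")
  expect_error(glycolysis_ude(ann_spec(6, 1)), "7 state inputs")
})
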