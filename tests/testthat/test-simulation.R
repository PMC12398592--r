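# Integration and loss gradients

test_that("integration reproduces the closed-form exponential decay", {
  prob <- toy_problem(ann = FALSE)
  tt <- seq(0, 4, length.out = 20)
  tr <- ude_integrate(prob, times = tt)
  expect_true(tr$success)
  expect_equal(tr$data$x, exp(-0.5 * tt), tolerance = 1e-6)
})

test_that("stiff and nonstiff solvers agree on the glycolysis model", {
  prob <- glycolysis_problem()
  prob$fast <- NULL # force the deSolve path for both solver classes
  tt <- seq(0, 3, length.out = 50)
  a <- ude_integrate(prob, times = tt, solver = "nonstiff",
                     rtol = 1e-8, atol = 1e-10)
  b <- ude_integrate(prob, times = tt, solver = "stiff",
                     rtol = 1e-8, atol = 1e-10)
  expect_true(a$success && b$success)
  ma <- as.matrix(a$data[-1]); mb <- as.matrix(b$data[-1])
  expect_lt(max(abs(ma - mb) / (abs(mb) + 1e-8)), 1e-4)
})

test_that("compiled and deSolve integrators self-converge under tolerance tightening", {
  prob <- glycolysis_problem()
  tt <- seq(0, 5, length.out = 40)
  loose <- ude_integrate(prob, times = tt, rtol = 1e-5, atol = 1e-7)
  tight <- ude_integrate(prob, times = tt, rtol = 1e-9, atol = 1e-11)
  diff <- max(abs(as.matrix(loose$data[-1]) - as.matrix(tight$data[-1])))
  expect_lt(diff, 1e-4) # well below the loose tolerance's scale
})

test_that("exploding network weights yield success = FALSE, not an error", {
  prob <- glycolysis_ude(ann_spec(7, 1, 1, 5, "relu"))
  w <- rep(50, ann_n_params(prob$ann$spec)) # blow-up dynamics
  tr <- ude_integrate(prob, list(w = w), seq(0, 5, length.out = 20))
  expect_false(tr$success)
  expect_true(nzchar(tr$failure_reason))
  obj <- ude_objective(prob, tibble::tibble(
    time = c(0.5, 1), observable = "A3", measurement = c(0.6, 0.7),
    partition = "train"
  ))
  expect_identical(obj$fn(pack_params(prob, w = w)), Inf)
})

test_that("invalid time vectors are rejected", {
  prob <- toy_problem(ann = FALSE)
  expect_error(ude_integrate(prob, times = c(1, 0.5)), "increasing")
  expect_error(ude_integrate(prob, times = c(-1, 1)), "non-negative")
})

test_that("sensitivity gradients match central finite differences on a toy UDE", {
  prob <- toy_problem(ann = TRUE)
  set.seed(11)
  w <- ann_init(prob$ann$spec, 2) + rnorm(ann_n_params(prob$ann$spec), 0, 0.2)
  data <- tibble::tibble(
    time = c(0.4, 0.9, 1.7, 2.5, 3.6), observable = "x",
    measurement = exp(-0.7 * c(0.4, 0.9, 1.7, 2.5, 3.6)),
    partition = "train"
  )
  obj <- ude_objective(prob, data, lambda = 0.3, rtol = 1e-10, atol = 1e-12,
                       gradient = "sensitivity")
  p0 <- pack_params(prob, theta = c(k = 0.5), w = w, sigma = c(x = 0.2))
  g <- obj$gr(p0)
  fd <- vapply(seq_along(p0), function(j) {
    h <- 1e-5 * max(1, abs(p0[j]))
    pp <- p0; pp[j] <- p0[j] + h; f1 <- obj$fn(pp)
    pp[j] <- p0[j] - h; f2 <- obj$fn(pp)
    (f1 - f2) / (2 * h)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-4)
  # trivial scalar sanity: d(theta^2)/dtheta via the same FD recipe
  expect_equal((3 + 1e-6)^2 - (3 - 1e-6)^2, 2e-6 * 6, tolerance = 1e-9)
})

test_that("adjoint and forward-sensitivity gradients agree on the compiled
           path, across architectures", {
  ds <- generate_glycolysis_dataset(data_setting(8, 10, seed = 9),
                                    test_points = 2L)
  set.seed(5)
  for (cfg in list(c(1, 3, "tanh"), c(2, 5, "swish"),
                   c(3, 10, "gaussian-rbf"))) {
    prob <- glycolysis_ude(ann_spec(7, 1, as.integer(cfg[1]),
                                    as.integer(cfg[2]), cfg[3]))
    w <- ann_init(prob$ann$spec, 1) +
      rnorm(ann_n_params(prob$ann$spec), 0, 0.05)
    p0 <- pack_params(prob, w = w, sigma = c(N2 = 0.1, A3 = 0.3))
    gA <- ude_objective(prob, ds$measurements, lambda = 0.4,
                        gradient = "adjoint", rtol = 1e-8, atol = 1e-10)$gr(p0)
    gS <- ude_objective(prob, ds$measurements, lambda = 0.4,
                        gradient = "sensitivity", rtol = 1e-8,
                        atol = 1e-10)$gr(p0)
    expect_lt(max(abs(gA - gS) / pmax(abs(gS), 1e-6)), 1e-4)
  }
})

test_that("compiled glycolysis gradient matches finite differences", {
  ds <- generate_glycolysis_dataset(data_setting(8, 5, seed = 5))
  prob <- glycolysis_ude(ann_spec(7, 1, 1, 3, "tanh"))
  set.seed(2)
  w <- ann_init(prob$ann$spec, 1) + rnorm(ann_n_params(prob$ann$spec), 0, 0.1)
  p0 <- pack_params(prob, w = w, sigma = c(N2 = 0.1, A3 = 0.3))
  obj <- ude_objective(prob, ds$measurements, lambda = 1,
                       rtol = 1e-9, atol = 1e-11)
  g <- obj$gr(p0)
  fd <- vapply(seq_along(p0), function(j) {
    h <- 1e-5 * max(1, abs(p0[j]))
    pp <- p0; pp[j] <- p0[j] + h; f1 <- obj$fn(pp)
    pp[j] <- p0[j] - h; f2 <- obj$fn(pp)
    (f1 - f2) / (2 * h)
  }, numeric(1))
  rel <- abs(g - fd) / pmax(abs(fd), 1e-5)
  expect_lt(max(rel), 1e-4)
  # gradient wrt the zeroed output layer is generically nonzero:
  # the chain rule through the hidden layers keeps the network trainable
  w0 <- ann_init(prob$ann$spec, 3)
  g0 <- obj$gr(pack_params(prob, w = w0, sigma = c(N2 = 0.1, A3 = 0.3)))
  lay <- udefit:::par_layout(prob)
  expect_gt(max(abs(g0[lay$i_w])), 1e-8)
})

test_that("zero-network UDE integrates identically to its mechanistic twin", {
  # same solver, same code path: trajectories agree to solver precision
  prob <- glycolysis_ude()
  w0 <- ann_init(prob$ann$spec, 4)
  tt <- seq(0, 5, length.out = 30)
  a <- ude_integrate(prob, list(w = w0), tt)
  prob_mech <- glycolysis_problem(
    glycolysis_parameters(free = setdiff(udefit:::GLYC_CONS_ORDER,
                                         c("k5", "A")))
  )
  prob_mech$fast_opts$include_k5 <- FALSE
  b <- ude_integrate(prob_mech, times = tt)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("trajectories export to CSV and read back identically", {
  prob <- toy_problem(ann = FALSE)
  tr <- ude_integrate(prob, times = seq(0, 2, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tr$data), tolerance = 1e-12)
})
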