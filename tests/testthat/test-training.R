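# Single-start training, two-stage training, multi-start orchestration

test_that("noise-free decay data recovers the rate constant within 1%", {
  prob <- toy_problem(ann = FALSE)
  data <- toy_decay_data(k = 0.7, times = seq(0.2, 3.8, length.out = 10))
  fit <- train_single(prob, data, init = list(theta = c(k = 0.3),
                                              sigma = c(x = 0.1)),
                      hyper = ude_hyper(learning_rate = 0.05),
                      budget = c(adam = 100, total = 300),
                      rtol = 1e-9, atol = 1e-11)
  expect_lt(abs(fit$theta[["k"]] - 0.7) / 0.7, 0.01)
})

test_that("early stopping returns the minimum of the validation trace", {
  prob <- toy_problem(ann = TRUE)
  data <- toy_decay_data(k = 0.9, times = seq(0.2, 3.8, length.out = 12),
                         noise = 0.05)
  data$partition <- rep(c("train", "validation"), 6)
  fit <- train_single(prob, data, hyper = ude_hyper(learning_rate = 0.05),
                      budget = c(adam = 60, total = 120), seed = 3)
  tr <- fit$trace
  expect_true(all(is.finite(tr$validation_nll)))
  best_traced <- min(tr$validation_nll)
  # validation NLL at the returned parameters equals the traced minimum
  obj <- ude_objective(fit$problem, data, lambda = 0)
  expect_equal(obj$nll_on(fit$best_params, "validation"), best_traced,
               tolerance = 1e-6)
  # with validation == training, early stopping degenerates to best-so-far
  data2 <- data; data2$partition <- "train"
  fit2 <- train_single(prob, data2, hyper = ude_hyper(learning_rate = 0.05),
                       budget = c(adam = 40, total = 80), seed = 3)
  expect_equal(min(fit2$trace$train_objective),
               obj_val <- ude_objective(fit2$problem, data2, lambda = 0)$fn(
                 fit2$best_params),
               tolerance = 1e-6)
})

test_that("dominant regularisation silences the network", {
  ds <- generate_glycolysis_dataset(data_setting(16, 5, seed = 6))
  prob <- glycolysis_ude(ann_spec(7, 1, 1, 3, "tanh"))
  # all-train data: the selected iterate minimises the penalised objective,
  # isolating the weight-decay effect from early-stopping noise
  meas <- ds$measurements
  meas$partition <- "train"
  fit <- train_single(prob, meas,
                      hyper = ude_hyper(learning_rate = 0.02, lambda = 1e6),
                      budget = c(adam = 100, total = 400), seed = 2)
  expect_lt(sqrt(sum(fit$w^2)), 1e-3)
  # predictions coincide with the mechanistic backbone at those parameters
  tt <- seq(0, 1.5, length.out = 10)
  with_ann <- ude_predict(fit$problem, fit$best_params, tt)
  prob0 <- fit$problem; prob0$ann <- NULL; prob0$fast_opts$include_k5 <- FALSE
  p0 <- fit$best_params[-udefit:::par_layout(fit$problem)$i_w]
  without <- ude_predict(prob0, p0, tt)
  expect_equal(with_ann$prediction, without$prediction, tolerance = 1e-4)
})

test_that("persistent simulation failure is reported as a status, not an error", {
  prob <- glycolysis_ude(ann_spec(7, 1, 1, 3, "relu"))
  bad_w <- rep(60, ann_n_params(prob$ann$spec))
  ds <- generate_glycolysis_dataset(data_setting(8, 5, seed = 1),
                                    test_points = 2L)
  fit <- train_single(prob, ds$measurements,
                      init = list(w = bad_w, sigma = c(N2 = 1, A3 = 1)),
                      budget = c(adam = 10, total = 20))
  expect_identical(fit$status, "simulation_failed")
})

test_that("two-stage training hands over mechanistic estimates and cannot
           lose likelihood at the handoff", {
  prob_ode <- toy_problem(ann = FALSE)
  prob_ude <- toy_problem(ann = TRUE)
  data <- toy_decay_data(k = 0.6, times = seq(0.2, 3.8, length.out = 12),
                         noise = 0.02)
  data$partition <- rep(c("train", "train", "validation"), 4)
  fit <- train_two_stage(prob_ode, prob_ude, data,
                         hyper = ude_hyper(learning_rate = 0.03),
                         budget_ode = c(adam = 60, total = 120),
                         budget_ude = c(adam = 40, total = 80),
                         rtol = 1e-8, atol = 1e-10)
  expect_s3_class(fit, "ude_fit")
  expect_false(is.null(fit$stage1))
  # stage-2 first iterate equals the mechanistic optimum (zero network),
  # so its best training objective is at most stage 1's final value
  expect_lte(min(fit$trace$train_objective),
             fit$stage1$train_nll + 1e-6)
  # stage-1 trace is archived separately, not merged into stage 2's
  expect_false(identical(fit$trace, fit$stage1$trace))
})

test_that("scenario-3 style augmentation trains through the two-stage path", {
  # miniature check on the stiff dimerisation problem: short horizon,
  # few records, finite-difference gradients
  prob_ode <- stat5_problem()
  prob_ude <- stat5_scenario(3, spec = ann_spec(6, 6, 1, 3))
  times <- c(2.5, 10, 30)
  truth <- ude_predict(prob_ode, NULL, times)
  set.seed(12)
  data <- tibble::tibble(time = truth$time, observable = truth$observable,
                         measurement = truth$prediction +
                           rnorm(nrow(truth), 0, 2),
                         partition = rep(c("train", "train", "validation"),
                                         each = 3))
  fit <- train_two_stage(prob_ode, prob_ude, data,
                         hyper = ude_hyper(learning_rate = 0.01, lambda = 0.2),
                         budget_ode = c(adam = 3, total = 5),
                         budget_ude = c(adam = 3, total = 5),
                         gradient = "fd", rtol = 1e-6, atol = 1e-8)
  expect_s3_class(fit, "ude_fit")
  # the handoff reproduces the stage-1 optimum up to solver-level noise in
  # the augmented (11-state vs 8-state) integration
  expect_lte(min(fit$trace$train_objective), fit$stage1$train_nll + 1e-3)
})

test_that("latin hypercube starts stratify every continuous dimension", {
  ps <- parameter_set(c("a", "b"), c(1, 1), c(0.1, 0.5), c(10, 2))
  ranges <- multistart_ranges("glycolysis")
  starts <- sample_starts(4, ranges, ps, seed = 5)
  expect_length(starts, 4)
  # one draw per quartile on the log scale of each parameter
  for (nm in c("a", "b")) {
    th <- vapply(starts, function(s) s$theta[[nm]], numeric(1))
    u <- (log(th) - log(ps$b_l[[nm]])) /
      (log(ps$b_u[[nm]]) - log(ps$b_l[[nm]]))
    expect_identical(sort(findInterval(u, c(0, .25, .5, .75, 1),
                                       rightmost.closed = TRUE)), 1:4)
  }
  # determinism and seed sensitivity
  expect_identical(sample_starts(4, ranges, ps, seed = 5), starts)
  expect_false(identical(sample_starts(4, ranges, ps, seed = 6), starts))
  # discrete hyperparameters come from the advertised sets
  many <- sample_starts(64, ranges, ps, seed = 2)
  hy <- lapply(many, `[[`, "hyper")
  expect_true(all(vapply(hy, `[[`, 1L, "n_hidden_layers") %in% 1:4))
  expect_true(all(vapply(hy, `[[`, 1L, "width") %in% c(3L, 5L, 10L)))
  expect_true(all(vapply(hy, `[[`, "", "activation") %in%
                    c("tanh", "relu", "gaussian-rbf", "swish")))
  lam <- vapply(hy, `[[`, 1, "lambda")
  expect_true(any(lam == 0)) # the no-regularisation level is sampled
  expect_true(all(lam == 0 | (lam >= 1e-4 & lam <= 1e-1)))
  lr <- vapply(hy, `[[`, 1, "learning_rate")
  expect_true(all(lr >= 1e-4 & lr <= 1e-1))
  expect_error(sample_starts(4, list(), ps), "empty")
})

test_that("multi-start selection returns the smallest full-data likelihood", {
  ds <- generate_glycolysis_dataset(data_setting(8, 10, seed = 2),
                                    test_points = 2L)
  prob <- glycolysis_ude()
  ms <- run_multistart(prob, ds$measurements, n_starts = 3, seed = 4,
                       budget = c(adam = 20, total = 40))
  s <- ms$summary
  ok <- is.finite(s$full_nll)
  expect_true(any(ok))
  expect_equal(ms$best_index, which.min(ifelse(ok, s$full_nll, Inf)))
  expect_true(all(s$full_nll[ms$best_index] <= s$full_nll[ok]))
  expect_identical(best_fit(ms), ms$fits[[ms$best_index]])
  # determinism: identical seed reproduces the summary
  ms2 <- run_multistart(prob, ds$measurements, n_starts = 3, seed = 4,
                        budget = c(adam = 20, total = 40))
  expect_equal(ms$summary, ms2$summary, tolerance = 1e-10)
})

test_that("a single start reduces to train_single", {
  prob <- toy_problem(ann = TRUE)
  data <- toy_decay_data(noise = 0.02)
  data$partition <- c("train", "train", "validation", "train", "validation")
  ranges <- multistart_ranges("glycolysis")
  starts <- sample_starts(1, ranges, prob$parameters, seed = 9)
  ms <- run_multistart(prob, data, starts = starts,
                       budget = c(adam = 20, total = 30))
  prob1 <- udefit:::apply_hyper(prob, starts[[1]]$hyper)
  init1 <- list(theta = starts[[1]]$theta,
                w = ann_init(prob1$ann$spec, starts[[1]]$seed))
  direct <- train_single(
    prob1, data,
    init = c(init1, list(sigma = udefit:::mle_sigma_at(prob1, data, init1))),
    hyper = starts[[1]]$hyper, budget = c(adam = 20, total = 30),
    seed = starts[[1]]$seed
  )
  expect_equal(best_fit(ms)$full_nll, direct$full_nll, tolerance = 1e-10)
})

test_that("the unregularised UDE nests its mechanistic backbone across
           paired starts", {
  # the UDE's model class contains the mechanistic model (zero network), so
  # with lambda = 0 its best training NLL over matched starts cannot be
  # meaningfully worse than the mechanistic model's
  data <- toy_decay_data(k = 0.8, times = seq(0.2, 3.8, length.out = 9),
                         noise = 0.05, seed = 4)
  prob_ude <- toy_problem(ann = TRUE)
  prob_ode <- toy_problem(ann = FALSE)
  set.seed(21)
  k_inits <- exp(runif(20, log(0.05), log(5)))
  best <- function(problem) {
    min(vapply(seq_along(k_inits), function(i) {
      w <- if (!is.null(problem$ann)) ann_init(problem$ann$spec, i) else NULL
      fit <- train_single(problem, data,
                          init = list(theta = c(k = k_inits[i]), w = w,
                                      sigma = c(x = 0.1)),
                          budget = c(adam = 20, total = 60), seed = i)
      fit$train_nll
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lte(best(prob_ude), best(prob_ode) + 1e-6)
})

test_that("multi-start archives write one JSON per start plus an index", {
  ds <- generate_glycolysis_dataset(data_setting(8, 10, seed = 3),
                                    test_points = 2L)
  prob <- glycolysis_ude()
  ms <- run_multistart(prob, ds$measurements, n_starts = 2, seed = 1,
                       budget = c(adam = 10, total = 15))
  dir <- withr::local_tempdir()
  write_multistart(ms, dir)
  expect_true(file.exists(file.path(dir, "start_0001.json")))
  expect_true(file.exists(file.path(dir, "start_0002.json")))
  idx <- readr::read_tsv(file.path(dir, "index.tsv"), show_col_types = FALSE)
  expect_equal(nrow(idx), 2)
  expect_equal(idx$full_nll[idx$best], min(idx$full_nll))
})
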