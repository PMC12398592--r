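# Assessment metrics

test_that("nmae averages per-record normalised errors", {
  expect_equal(nmae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nmae(1, 2), 0.5)
  expect_equal(nmae(c(1, 4), c(2, 4)), 0.25)
  # raw-sum variant and scale invariance
  expect_equal(nmae(c(1, 4), c(2, 4), mean_over = "none"), 0.5)
  set.seed(2)
  y <- runif(10, 1, 3); p <- y + rnorm(10, 0, 0.2)
  expect_equal(nmae(5 * p, 5 * y), nmae(p, y), tolerance = 1e-12)
  expect_error(nmae(1, 0), "zero")
})

test_that("success classification uses a strict threshold", {
  expect_true(classify_success(0.14))
  expect_false(classify_success(0.16))
  expect_false(classify_success(0.15)) # boundary: strictly below
  expect_false(classify_success(Inf))
})

test_that("information criteria reproduce the published model comparison", {
  expect_equal(aic(138.22, 9), 294.44, tolerance = 1e-10)
  expect_equal(bic(138.22, 9, 48), 311.28, tolerance = 1e-3)
  expect_equal(aic(86.88, 153), 479.76, tolerance = 1e-10)
  expect_equal(bic(86.88, 153, 48), 766.0, tolerance = 1e-3)
  expect_equal(aic(0, 0), 0)
  expect_error(bic(1, 2, 0), "n_data")
})

test_that("chi-squared region is a downward-closed likelihood band", {
  nlls <- c(100, 101, 101.9, 102.5, 110)
  inr <- chi2_region(nlls, alpha = 0.95, df = 1)
  thr <- 0.5 * qchisq(0.95, 1) # ~1.9207
  expect_identical(inr, nlls <= 100 + thr)
  expect_true(inr[1])                       # the best fit is always inside
  expect_false(chi2_region(c(0, 10))[2])    # +10 is far outside for df = 1
  expect_true(chi2_region(c(0, 1))[2])      # +1.0 < 1.9207
  # monotone: lowering an NLL can only keep it inside
  expect_true(all(inr[order(nlls)] == cummin(inr[order(nlls)])))
})

test_that("oscillation metrics recover analytic sinusoid properties", {
  tt <- seq(1.5, 5, length.out = 600)
  m <- oscillation_metrics(tt, sin(2 * pi * 2 * tt))
  expect_true(m$sustained)
  expect_equal(m$frequency, 2, tolerance = 0.02)
  expect_equal(m$amplitude, 2, tolerance = 0.02)
  # strongly damped -> not sustained
  md <- oscillation_metrics(tt, exp(-3 * tt) * sin(2 * pi * 2 * tt))
  expect_false(md$sustained)
  # constant -> nothing detected
  mc <- oscillation_metrics(tt, rep(1, length(tt)))
  expect_false(mc$sustained)
  expect_equal(mc$amplitude, 0)
  # closeness flags against truth
  m2 <- oscillation_metrics(tt, 1.1 * sin(2 * pi * 2 * tt),
                            truth = sin(2 * pi * 2 * tt))
  expect_true(m2$close_amplitude && m2$close_frequency && m2$close_sustained)
  expect_error(oscillation_metrics(tt[1:3], rnorm(3)), "too short")
})

test_that("parameter error sums squared log-space deviations", {
  th <- c(a = 2, b = 0.1)
  expect_equal(parameter_error(th, th), 0)
  expect_equal(parameter_error(c(a = 2 * exp(1), b = 0.1), th), 1,
               tolerance = 1e-12)
  expect_equal(parameter_error(c(a = 20, b = 0.1), th), log(10)^2,
               tolerance = 1e-12)
  expect_error(parameter_error(c(a = -1, b = 1), c(a = 1, b = 1)), "positive")
})

test_that("sigma recovery is the relative deviation", {
  expect_equal(unname(sigma_recovery(c(a = 1), c(a = 1))), 0)
  expect_equal(unname(sigma_recovery(c(a = 1.5), c(a = 1))), 0.5)
  expect_equal(unname(sigma_recovery(c(a = 0.5), c(a = 1))), 0.5)
})

test_that("evaluating an oracle-equipped fit reports near-zero test error", {
  # a 'fit' whose network is the exact missing term must extrapolate the
  # truth, giving NMAE ~ solver error and a success flag
  ds <- generate_glycolysis_dataset(data_setting(16, 5, seed = 4),
                                    test_points = 50L)
  prob <- glycolysis_ude()
  k5 <- glycolysis_parameters()$values[["k5"]]
  prob <- set_ann_oracle(prob, function(u) -k5 * u[6])
  p <- pack_params(prob, sigma = ds$sigma)
  fake_fit <- structure(
    list(problem = prob, best_params = p,
         theta = prob$parameters$values, sigma = ds$sigma,
         full_nll = 0, n_params = length(p), n_data = 32),
    class = "ude_fit"
  )
  ev <- evaluate_fit(fake_fit, ds,
                     true_theta = prob$parameters$values[prob$parameters$free])
  expect_lt(ev$test_nmae, 1e-3)
  expect_true(ev$success)
  expect_equal(ev$parameter_error, 0, tolerance = 1e-12)
  # the truth itself oscillates on the test window (N2 fits three full
  # peaks inside (1.5, 5]; the slower A3 phase only exposes two there)
  expect_true(ev$oscillation$N2$truth$sustained)
})
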