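#' Normalised mean absolute error against noise-free truth
#'
#' Mean over all records of `|prediction - truth| / truth`. Used as the test
#' loss on the extrapolation window, where the glycolysis observables are
#' bounded away from zero.
#'
#' @param predictions,truth Aligned numeric vectors; `truth` must be nonzero.
#' @param mean_over Either `"records"` (default: the mean, reported
#'   everywhere) or `"none"` (the raw double sum).
#' @return Scalar error.
#' @export
nmae <- function(predictions, truth, mean_over = c("records", "none")) {
  mean_over <- match.arg(mean_over)
  stopifnot(length(predictions) == length(truth))
  if (any(truth == 0)) stop("truth contains zeros; NMAE undefined", call. = FALSE)
  e <- abs(predictions - truth) / truth
  if (mean_over == "records") mean(e) else sum(e)
}

#' Success classification of a fit
#'
#' A fit counts as successful when its test NMAE lies strictly below the
#' threshold (default 0.15).
#'
#' @param test_nmae Test error.
#' @param threshold Success threshold.
#' @return Logical.
#' @export
classify_success <- function(test_nmae, threshold = 0.15) {
  is.finite(test_nmae) & test_nmae < threshold
}

#' Information criteria
#'
#' `aic = 2 * nll + 2 * n_params`; `bic = n_params * log(n_data) + 2 * nll`.
#' Both trade off likelihood against the number of independently adjusted
#' parameters; BIC penalises parameters more strongly for `n_data >= 8`.
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param n_params Number of free parameters (mechanistic + network + noise).
#' @param n_data Number of data points.
#' @return Scalar criterion value.
#' @export
aic <- function(nll, n_params) {
  stopifnot(n_params >= 0)
  2 * nll + 2 * n_params
}

#' @rdname aic
#' @export
bic <- function(nll, n_params, n_data) {
  stopifnot(n_params >= 0)
  if (n_data <= 0) stop("bic needs n_data > 0", call. = FALSE)
  n_params * log(n_data) + 2 * nll
}

#' Chi-squared confidence-region membership
#'
#' Flags which fits of a multi-start batch lie inside the `alpha` confidence
#' region around the best fit: a fit is in-region iff its NLL is within half
#' the chi-squared quantile of the best NLL (likelihood-ratio band).
#'
#' @param nlls Numeric vector of NLL values (or a `ude_multistart`, whose
#'   full-data NLLs are used).
#' @param alpha Confidence level, default 0.95.
#' @param df Degrees of freedom of the band, default 1.
#' @return Logical vector, `TRUE` for in-region.
#' @export
chi2_region <- function(nlls, alpha = 0.95, df = 1) {
  if (inherits(nlls, "ude_multistart")) nlls <- nlls$summary$full_nll
  if (!any(is.finite(nlls))) stop("no finite NLLs", call. = FALSE)
  nlls <= min(nlls, na.rm = TRUE) + 0.5 * qchisq(alpha, df)
}

#' Oscillation recovery metrics
#'
#' Detects peaks and troughs on a densely evaluated prediction window and
#' summarises: `sustained` (at least 3 peaks whose last amplitude retains at
#' least half of the first), `amplitude` (mean peak-to-trough span) and
#' `frequency` (reciprocal median inter-peak interval). When a reference
#' signal is supplied, each property additionally gets a `close_*` flag
#' (within ±20% of the truth by default; sustained must simply match).
#'
#' @param times Dense, increasing evaluation grid.
#' @param values Predicted signal on `times`.
#' @param truth Optional reference signal on the same grid.
#' @param rel_tol Closeness tolerance for amplitude/frequency.
#' @return A list of metrics (and closeness flags when `truth` is given).
#' @export
oscillation_metrics <- function(times, values, truth = NULL, rel_tol = 0.2) {
  stopifnot(length(times) == length(values))
  if (length(times) < 8) stop("window too short for peak detection", call. = FALSE)
  one <- function(v) {
    d <- diff(v)
    s <- sign(d)
    s[s == 0] <- 1
    turns <- which(diff(s) != 0) + 1L
    peaks <- turns[d[turns - 1] > 0]
    troughs <- turns[d[turns - 1] < 0]
    if (length(peaks) < 2 || length(troughs) < 1) {
      return(list(sustained = FALSE, amplitude = 0, frequency = NA_real_,
                  n_peaks = length(peaks)))
    }
    pk <- v[peaks]; tr <- v[troughs]
    amp <- mean(pk) - mean(tr)
    span1 <- abs(pk[1] - mean(tr))
    spanL <- abs(pk[length(pk)] - mean(tr))
    sustained <- length(peaks) >= 3 && spanL >= 0.5 * span1
    freq <- 1 / median(diff(times[peaks]))
    list(sustained = sustained, amplitude = amp, frequency = freq,
         n_peaks = length(peaks))
  }
  m <- one(values)
  if (!is.null(truth)) {
    mt <- one(truth)
    close_rel <- function(a, b) {
      is.finite(a) && is.finite(b) && b != 0 && abs(a - b) / abs(b) <= rel_tol
    }
    m$truth <- mt
    m$close_sustained <- identical(m$sustained, mt$sustained)
    m$close_amplitude <- close_rel(m$amplitude, mt$amplitude)
    m$close_frequency <- close_rel(m$frequency, mt$frequency)
  }
  m
}

#' Log-space parameter estimation error
#'
#' Sum of squared differences between estimated and true parameters on the
#' natural-log scale, the standard accuracy summary for rate constants that
#' vary over orders of magnitude.
#'
#' @param estimated,true Named positive parameter vectors (matched by name
#'   when both are named).
#' @return Scalar sum of squared log errors.
#' @export
parameter_error <- function(estimated, true) {
  if (!is.null(names(estimated)) && !is.null(names(true))) {
    common <- intersect(names(estimated), names(true))
    estimated <- estimated[common]; true <- true[common]
  }
  stopifnot(length(estimated) == length(true))
  if (any(estimated <= 0) || any(true <= 0)) {
    stop("parameters must be strictly positive for log-space errors",
         call. = FALSE)
  }
  sum((log(estimated) - log(true))^2)
}

#' Relative noise-recovery error
#'
#' `|sigma_hat - sigma| / sigma` per observable.
#'
#' @param estimated,true Positive noise SDs (named vectors matched by name).
#' @return Numeric vector of relative deviations.
#' @export
sigma_recovery <- function(estimated, true) {
  if (!is.null(names(estimated)) && !is.null(names(true))) {
    estimated <- estimated[names(true)]
  }
  stopifnot(all(true > 0))
  abs(estimated - true) / true
}

#' Evaluate a fitted UDE against a synthetic dataset
#'
#' Computes the full assessment report for a glycolysis-style fit: test
#' NMAE on the noise-free extrapolation window, the success flag, AIC/BIC
#' from the full-data NLL, oscillation recovery per observable, and (when
#' reference parameters / noise levels are available) the log-space
#' parameter error and the relative noise-recovery error.
#'
#' @param fit A `ude_fit`.
#' @param dataset The `ude_dataset` it was trained on.
#' @param true_theta Optional named true parameter vector.
#' @param threshold Success threshold on the test NMAE.
#' @return An `ude_evaluation` list.
#' @export
evaluate_fit <- function(fit, dataset, true_theta = NULL, threshold = 0.15) {
  problem <- fit$problem
  truth_te <- dataset$truth[dataset$truth$window == "test", , drop = FALSE]
  t_test <- sort(unique(truth_te$time))
  pred <- ude_predict(problem, fit$best_params, t_test)
  if (isTRUE(attr(pred, "success"))) {
    joined <- dplyr::inner_join(
      truth_te, pred, by = c("time", "observable")
    )
    test_nmae <- nmae(joined$prediction, joined$value)
    osc <- lapply(setNames(problem$obs_names, problem$obs_names), function(o) {
      sel <- joined$observable == o
      oscillation_metrics(joined$time[sel], joined$prediction[sel],
                          joined$value[sel])
    })
  } else {
    test_nmae <- Inf
    osc <- NULL
  }
  n_train_records <- sum(!is.na(dataset$measurements$measurement))
  rep <- list(
    test_nmae = test_nmae,
    success = classify_success(test_nmae, threshold),
    aic = aic(fit$full_nll, fit$n_params),
    bic = bic(fit$full_nll, fit$n_params, n_train_records),
    oscillation = osc,
    sigma = fit$sigma
  )
  if (!is.null(true_theta)) {
    est <- fit$theta[fit$problem$parameters$free]
    rep$parameter_error <- parameter_error(est, true_theta)
  }
  if (!is.null(dataset$sigma) && all(dataset$sigma > 0)) {
    rep$sigma_relative_error <- sigma_recovery(fit$sigma, dataset$sigma)
  }
  structure(rep, class = "ude_evaluation")
}

#' @export
print.ude_evaluation <- function(x, ...) {
  cat(sprintf("<ude_evaluation> test NMAE %.4g (%s) | AIC %.4g | BIC %.4g\n",
              x$test_nmae, if (x$success) "success" else "failure",
              x$aic, x$bic))
  invisible(x)
}
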