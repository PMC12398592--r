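#' Tidy a fitted UDE
#'
#' One row per estimated quantity: the mechanistic parameters (natural
#' scale, with bounds) and the observation-noise SDs. Network weights are
#' summarised by [glance()]; access them via `fit$w`.
#'
#' @param x A `ude_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `estimate`, `b_l`, `b_u`.
#' @export
tidy.ude_fit <- function(x, ...) {
  ps <- x$problem$parameters
  dplyr::bind_rows(
    tibble::tibble(term = ps$names, type = "mechanistic",
                   estimate = unname(x$theta[ps$names]),
                   free = unname(ps$free),
                   b_l = unname(ps$b_l), b_u = unname(ps$b_u)),
    tibble::tibble(term = paste0("sigma_", names(x$sigma)), type = "noise",
                   estimate = unname(x$sigma), free = TRUE,
                   b_l = NA_real_, b_u = NA_real_)
  )
}

#' One-row summary of a fitted UDE
#'
#' @param x A `ude_fit`.
#' @param ... Unused.
#' @return A one-row tibble: status, epochs, the three NLLs, lambda, weight
#'   norm, parameter/data counts and AIC/BIC.
#' @export
glance.ude_fit <- function(x, ...) {
  w_all <- c(x$w, x$w_obs)
  tibble::tibble(
    status = x$status, epochs = if (!is.null(x$trace)) nrow(x$trace) else 0L,
    train_nll = x$train_nll, validation_nll = x$validation_nll,
    full_nll = x$full_nll, lambda = x$lambda %||% 0,
    ann_weight_norm = if (length(w_all)) sqrt(sum(w_all^2)) else 0,
    n_params = x$n_params, n_data = x$n_data,
    aic = aic(x$full_nll, x$n_params),
    bic = bic(x$full_nll, x$n_params, x$n_data)
  )
}

#' Plot a fitted UDE against its measurements
#'
#' Dense model predictions with the training and validation measurements
#' overlaid, one facet per observable.
#'
#' @param object A `ude_fit`.
#' @param times Optional dense prediction grid (defaults to 200 points over
#'   the data range).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ude_fit <- function(object, times = NULL, ...) {
  data <- object$data
  if (is.null(times)) {
    times <- seq(min(data$time), max(data$time), length.out = 200)
  }
  pred <- ude_predict(object$problem, object$best_params, times)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prediction)) +
    ggplot2::geom_point(
      data = data,
      ggplot2::aes(y = .data$measurement, colour = .data$partition)
    ) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time", y = "observable", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of a multi-start run
#'
#' Sorted full-data NLL per start, the standard convergence diagnostic for
#' multi-start maximum likelihood.
#'
#' @param object A `ude_multistart`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ude_multistart <- function(object, ...) {
  s <- object$summary[is.finite(object$summary$full_nll), , drop = FALSE]
  s <- dplyr::arrange(s, .data$full_nll)
  s$rank <- seq_len(nrow(s))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$rank, y = .data$full_nll)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sorted start", y = "full-data NLL") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic dataset with its noise-free truth
#'
#' @param object A `ude_dataset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ude_dataset <- function(object, ...) {
  ggplot2::ggplot(object$truth,
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$window)) +
    ggplot2::geom_point(
      data = object$measurements,
      ggplot2::aes(y = .data$measurement, colour = .data$partition)
    ) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time", y = "observable", colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
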