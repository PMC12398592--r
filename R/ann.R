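ACTIVATIONS <- c("tanh", "relu", "gaussian-rbf", "swish")

#' Specify a feed-forward neural network
#'
#' Describes the fully connected network used as the data-driven term of a
#' UDE: input/output widths, number of hidden layers, hidden width, the
#' activation function, and whether inputs are log-normalised (see
#' [normalise_input()]). Hidden layers share a common width and activation;
#' the output layer is linear.
#'
#' @param n_inputs,n_outputs Positive integers.
#' @param n_hidden_layers Number of hidden layers, 1--4.
#' @param width Neurons per hidden layer, one of 3, 5, 10 in the canonical
#'   multi-start grid (other positive widths are accepted).
#' @param activation One of `"tanh"`, `"relu"`, `"gaussian-rbf"`, `"swish"`.
#'   The Gaussian radial basis activation is `exp(-z^2)`, swish is
#'   `z * sigmoid(z)`.
#' @param input_normalisation Logical; log-transform inputs before the first
#'   layer.
#' @return An `ann_spec` object.
#' @export
ann_spec <- function(n_inputs, n_outputs, n_hidden_layers = 1, width = 5,
                     activation = "tanh", input_normalisation = FALSE) {
  activation <- match.arg(activation, ACTIVATIONS)
  stopifnot(n_inputs >= 1, n_outputs >= 1, n_hidden_layers >= 1, width >= 1)
  structure(
    list(n_inputs = as.integer(n_inputs), n_outputs = as.integer(n_outputs),
         n_hidden_layers = as.integer(n_hidden_layers),
         width = as.integer(width), activation = activation,
         input_normalisation = isTRUE(input_normalisation)),
    class = "ann_spec"
  )
}

#' @export
print.ann_spec <- function(x, ...) {
  cat(sprintf("<ann_spec> %d -> %s -> %d, %s%s (%d parameters)\n",
              x$n_inputs,
              paste(rep(x$width, x$n_hidden_layers), collapse = "-"),
              x$n_outputs, x$activation,
              if (x$input_normalisation) ", log-normalised inputs" else "",
              ann_n_params(x)))
  invisible(x)
}

ann_dims <- function(spec) {
  as.integer(c(spec$n_inputs, rep(spec$width, spec$n_hidden_layers),
               spec$n_outputs))
}

ann_act_id <- function(spec) match(spec$activation, ACTIVATIONS) - 1L

#' Number of weights and biases implied by an `ann_spec`
#'
#' @param spec An [ann_spec()].
#' @return Integer parameter count.
#' @export
ann_n_params <- function(spec) {
  d <- ann_dims(spec)
  sum(d[-1] * (d[-length(d)] + 1L))
}

#' Initialise network parameters
#'
#' Hidden-layer weights are drawn from the Glorot (Xavier) uniform
#' distribution, `U(-sqrt(6/(fan_in+fan_out)), +sqrt(...))`; the output-layer
#' weights and all biases are set to zero. A zero output layer makes the
#' network output identically zero at initialisation, so a freshly
#' initialised UDE coincides with its purely mechanistic backbone.
#'
#' @param spec An [ann_spec()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Numeric vector of length `ann_n_params(spec)` (per layer: the
#'   weight matrix in column-major order, then the biases).
#' @export
ann_init <- function(spec, seed = 1L) {
  d <- ann_dims(spec)
  L <- length(d) - 1L
  w <- vector("list", L)
  local_seed <- function(code) { # local RNG, leave global stream untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    code
  }
  local_seed({
    for (l in seq_len(L)) {
      fan_in <- d[l]; fan_out <- d[l + 1L]
      if (l < L) {
        lim <- sqrt(6 / (fan_in + fan_out))
        W <- runif(fan_out * fan_in, -lim, lim)
      } else {
        W <- numeric(fan_out * fan_in) # zero output layer
      }
      w[[l]] <- c(W, numeric(fan_out)) # zero biases
    }
  })
  unlist(w)
}

#' Evaluate a feed-forward network
#'
#' Plain fully connected forward pass with a linear output layer. If the spec
#' requests input normalisation, each input passes through
#' [normalise_input()] first.
#'
#' @param spec An [ann_spec()].
#' @param params Flat parameter vector, as produced by [ann_init()].
#' @param x Numeric input vector of length `spec$n_inputs`.
#' @return Numeric output vector of length `spec$n_outputs`.
#' @export
ann_forward <- function(spec, params, x) {
  if (length(params) != ann_n_params(spec)) {
    stop("parameter vector length does not match the spec", call. = FALSE)
  }
  if (length(x) != spec$n_inputs) {
    stop("input length does not match n_inputs", call. = FALSE)
  }
  mlp_forward_cpp(params, ann_dims(spec), ann_act_id(spec),
                  spec$input_normalisation, as.numeric(x))
}

# output value plus Jacobians wrt inputs and weights (internal)
ann_jacobians <- function(spec, params, x) {
  mlp_jacobians_cpp(params, ann_dims(spec), ann_act_id(spec),
                    spec$input_normalisation, as.numeric(x))
}

#' Log-normalise a network input
#'
#' `log(x + c)` for positive `x` and `log(c)` otherwise, with `c = 1e-20`,
#' so the logarithm is defined for any input the ODE solver may produce
#' (including transiently negative states).
#'
#' @param x Numeric vector.
#' @param c Small positive constant, default `1e-20`.
#' @return Numeric vector.
#' @export
normalise_input <- function(x, c = 1e-20) {
  out <- rep.int(log(c), length(x))
  pos <- which(x > 0)
  out[pos] <- log(x[pos] + c)
  out
}
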