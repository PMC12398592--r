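# Shared fixtures: a minimal one-state decay UDE and small datasets,
# built in code at test time.

toy_problem <- function(ann = TRUE, b = c(0.01, 10), k = 0.5) {
  ps <- parameter_set("k", k, b[1], b[2])
  ann_part <- if (ann) {
    list(spec = ann_spec(1, 1, n_hidden_layers = 1, width = 3),
         inputs = function(t, x, theta) as.numeric(x),
         placement = matrix(1, 1, 1))
  } else NULL
  new_ude_problem(
    name = "toy_decay", state_names = "x", x0 = c(x = 1),
    rhs_mech = function(t, x, theta) -theta[["k"]] * x[[1]],
    observables = function(t, x, theta) c(x = x[[1]]),
    obs_names = "x", parameters = ps, ann = ann_part,
    horizon = c(0, 4), solver = "nonstiff"
  )
}

toy_decay_data <- function(k = 0.7, times = c(0.4, 0.9, 1.7, 2.5, 3.6),
                           noise = 0, seed = 1, partition = "train") {
  y <- exp(-k * times)
  if (noise > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noise)
  }
  tibble::tibble(time = times, observable = "x", measurement = y,
                 partition = partition)
}

# independently re-typed dimerisation equations (the oracle for the model
# layer); `variant` selects which terms a scenario's backbone removes
ref_stat5_rhs <- function(t, x, th, variant = "full") {
  Vc <- 1.4; Vn <- 0.45
  A <- x[1]; B <- x[2]; pAA <- x[3]; pBB <- x[4]; pAB <- x[5]
  nAA <- x[6]; nBB <- x[7]; nAB <- x[8]
  E <- 1.25e-07 * exp(-th[["Epo_degradation_BaF3"]] * t)
  kph <- th[["k_phos"]]
  dA <- -2 * E * A^2 * kph - E * A * B * kph +
    2 * (Vn / Vc) * th[["k_exp_homo"]] * nAA +
    (Vn / Vc) * th[["k_exp_hetero"]] * nAB
  dB <- -E * A * B * kph - 2 * E * B^2 * kph +
    (Vn / Vc) * th[["k_exp_hetero"]] * nAB +
    2 * (Vn / Vc) * th[["k_exp_homo"]] * nBB
  dpAA <- E * A^2 * kph - th[["k_imp_homo"]] * pAA
  dpBB <- E * B^2 * kph - th[["k_imp_homo"]] * pBB
  dpAB <- E * A * B * kph - th[["k_imp_hetero"]] * pAB
  dnAA <- (Vc / Vn) * th[["k_imp_homo"]] * pAA - th[["k_exp_homo"]] * nAA
  dnBB <- (Vc / Vn) * th[["k_imp_homo"]] * pBB - th[["k_exp_homo"]] * nBB
  dnAB <- (Vc / Vn) * th[["k_imp_hetero"]] * pAB - th[["k_exp_hetero"]] * nAB
  if (variant == "s1_backbone") {
    dA <- dA - 2 * (Vn / Vc) * th[["k_exp_homo"]] * nAA
    dnAA <- dnAA + th[["k_exp_homo"]] * nAA
  }
  if (variant == "s2_backbone") dpAB <- 0
  c(dA, dB, dpAA, dpBB, dpAB, dnAA, dnBB, dnAB)
}

fd_gradient <- function(fn, p, h_rel = 1e-5) {
  vapply(seq_along(p), function(j) {
    h <- h_rel * max(1, abs(p[j]))
    pp <- p; pp[j] <- p[j] + h; f1 <- fn(pp)
    pp[j] <- p[j] - h; f2 <- fn(pp)
    (f1 - f2) / (2 * h)
  }, numeric(1))
}
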