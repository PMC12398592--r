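---
title: "Hybrid mechanistic/neural ODE models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid mechanistic/neural ODE models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`udefit` trains *universal differential equations* (UDEs): ordinary
differential equation models of biochemical networks whose right-hand side
(or observable mapping) is the sum of a mechanistic term and a feed-forward
neural network,

$$\frac{dx}{dt} = f_M(t, x, \theta_M) + f_{\mathrm{ANN}}(t, x, \theta_{\mathrm{ANN}}),
\qquad \bar y = h_M(t, x, \theta_M) + h_{\mathrm{ANN}}(t, x, \theta_{\mathrm{ANN}}),$$

with known initial state $x_0$. The mechanistic parameters $\theta_M$ carry
the biological interpretation; the network absorbs processes that are
unknown or deliberately removed. This vignette documents the statistical
model, the training pipeline, and every numerical or design decision a
maintainer might want to revisit.

## The two built-in systems

**Glycolysis.** A seven-species yeast glycolysis oscillator (glucose pool,
three intermediates, NADH, ATP, and an extracellular pool) with conserved
NAD and adenosine totals. At the published reference parameters the system
sits on a stable limit cycle with a period of roughly 1.1 minutes; the
species `N2` (NADH) and `A3` (ATP) are observed directly. The UDE variant
removes the ATP consumption term $-k_5 A_3$ from the ATP equation and adds a
single-output network receiving all seven states, so the network must
rediscover a dependence on ATP alone. `k5` consequently leaves the estimated
parameter list (11 free mechanistic parameters instead of 12). Reference
values are shipped as a plain-text fixture
(`inst/extdata/glycolysis_reference_parameters.tsv`, from the original
publication of the model); the estimation bounds span one decade either
side of each reference value — a package choice giving every rate a
plausible two-decade search range. Any oscillatory parameterisation serves
the package's property tests equally well.

**STAT5 dimerisation.** The eight-species erythropoietin-driven STAT5A/B
phosphorylation, dimerisation and nuclear shuttling model, with fixed
compartment volumes ($V_{cyt} = 1.4$, $V_{nuc} = 0.45$), a fixed label
fraction ($specC17 = 0.107$), six estimated rate constants spanning ten
orders of magnitude, and three highly nonlinear relative-abundance
observables. Four UDE scenarios replace or augment parts of the model:

1. the nuclear pApA export flux, constrained so the network flux conserves
   total monomer count across compartments (the single output enters the
   STAT5A equation as $+2 (V_{nuc}/V_{cyt}) f_{\mathrm{ANN}}$ and the
   nucpApA equation as $-f_{\mathrm{ANN}}$);
2. the entire pApB derivative (network inputs: all states plus the decaying
   Epo stimulus);
3. three augmentation species $K_A, K_B, K_{AB}$ with network dynamics,
   feeding back into the monomer equations through mass-action export terms
   (initial values of the augmentation species are set to zero — the natural
   choice for species that represent not-yet-populated pools — and the
   network input order is nucpApA, nucpApB, nucpBpB, $K_A$, $K_B$,
   $K_{AB}$);
4. a network observable replacing the relative STAT5A abundance ratio while
   the dynamics stay fully mechanistic.

The real measurements for this system are not bundled; `read_measurements()`
ingests them from the community benchmark TSV dialect (`observableId`,
`time`, `measurement`) and applies the 4:1 train:validation split by time
point.

## Statistical model

Measurements carry additive Gaussian noise with an observable-specific
standard deviation $\sigma_s$ estimated jointly with all other parameters,

$$J(\theta \mid \mathcal D) = \frac12 \sum_{k} \left[ \log(2\pi\sigma_{s(k)}^2)
 + \frac{(y_k - \bar y_k)^2}{\sigma_{s(k)}^2} \right],$$

summed over measurement records. The training objective adds weight decay on
the network parameters, $J + \lambda \lVert\theta_{\mathrm{ANN}}\rVert_2^2 /
n_{\mathrm{ANN}}$; normalising by the parameter count keeps $\lambda$
comparable across the architectures visited by a multi-start run. Two
deliberate readings are baked in:

* the per-record sum runs over *observables*, matching the per-observable
  noise model (the alternative reading, over state variables, would pair
  noise parameters with unobserved states);
* the penalty uses the count-normalised form; the validation score used for
  early stopping is the *plain* NLL without the penalty, because the penalty
  is a training-time device and held-out likelihood is what early stopping
  should protect.

$\sigma$ is optimised as $\log\sigma$ so positivity holds by construction.
`optimal_sigma()` provides the closed-form stationary point (per-observable
RMS residual) used by tests and as a sanity check.

## Bounded parameter transform

Rate constants are positive, bounded, and vary over orders of magnitude.
Each free mechanistic parameter is estimated on an unbounded coordinate
$\rho$ through a scaled hyperbolic tangent

$$\theta = b_l + \frac{\tanh(\rho - a) + 1}{2} (b_u - b_l),$$

which between the bounds approximates a log reparameterisation. The offset
$a$ anchors $\theta = 1$ at $\rho = 0$ whenever the bounds bracket 1
(`choose_offset()`), mirroring the zero-to-one anchoring of a
log-transform. When 1 lies outside the bounds the anchor is unattainable;
we use $a = 0$, placing the bound midpoint at $\rho = 0$ — a well-defined
initialisation with no further claim attached.

## Networks

Fully connected networks with 1–4 hidden layers of 3, 5 or 10 neurons and a
linear output layer. Activations: `tanh`, `relu`, Gaussian radial basis
(defined as $e^{-z^2}$) and swish ($z\,\mathrm{sigmoid}(z)$) — the standard
definitions in the deep-learning ecosystems this grid mirrors. Optional
input normalisation maps each input through $\log(x + c)$ for $x > 0$ and
$\log c$ otherwise, $c = 10^{-20}$, so the logarithm survives transiently
non-positive solver states; $c$ is exposed for other problems.

Initialisation draws hidden-layer weights from the Glorot uniform
distribution and zeroes the output-layer weights *and all biases*. Zeroing
every bias is the conservative convention; zeroing the output layer alone
already guarantees the key property, namely that a freshly initialised UDE
coincides exactly with its mechanistic backbone. The Glorot/zero split per
layer makes the would-be Glorot draw of the output layer irrelevant — it is
overwritten by zeros either way.

## Simulation and gradients

Generic problems integrate through `deSolve` (`ode45` for the non-stiff
class, `lsoda` for the stiff STAT5 family). The glycolysis family
additionally has a compiled Dormand–Prince 5(4) integrator with embedded
forward sensitivity equations (analytic state/parameter Jacobians of the
mechanistic terms, backpropagated network Jacobians), which is what makes
hundreds of multi-start training runs affordable on a single CPU. Failed
integrations — step-size collapse, non-finite states, exhausted step budget
— return `success = FALSE` and map to an objective value of $+\infty$, so a
multi-start batch discards the start instead of crashing. The training-time
step budget (default 8000 accepted/rejected steps per solve) exists for
exactly this reason: pathological parameter draws otherwise consume
arbitrary time before failing.

Gradients of the objective come from sensitivity analysis in one of three
flavours, selected by `gradient =` in [ude_objective()]:

* **Adjoint** (default on the compiled glycolysis path): one forward solve
  stored with the integrator's dense-output interpolant, then one backward
  solve of the adjoint system $\dot\lambda = -J_x^\top \lambda$ with jumps
  of the weighted residuals at the data times and parameter quadratures
  $\int \lambda^\top (\partial f/\partial p)\,dt$ accumulated alongside.
  For network weights the quadrature integrand is a single
  backpropagation, so the gradient cost is independent of the network
  size — the property that makes multi-start training with hundreds of
  weights affordable on one CPU.
* **Forward sensitivities**: the augmented system $\dot S = J_x S + J_p$
  integrated alongside the states (compiled for glycolysis, deSolve-based
  for generic problems). On the generic path the mechanistic Jacobians are
  formed by central differences *of the algebraic right-hand side* (not
  through the solver), accurate to roughly square-root-of-epsilon relative
  error; network Jacobians are analytic backpropagation. This is the
  cross-check route for the adjoint.
* **Finite differences through the solver** (`gradient = "fd"`): the
  pragmatic option for the stiff STAT5 scenarios, where the augmented
  system in interpreted R would dominate the run time.

The chain rule maps $d\bar y/d\theta$ through the tanh transform
($d\theta/d\rho$); the $\log\sigma$ gradient is analytic. Correctness
contract, verified in the tests: adjoint and forward-sensitivity gradients
agree with each other and with central finite differences to $10^{-4}$
relative.

Default solver tolerances are `rtol = 1e-6`, `atol = 1e-8` (tighter for
oracle comparisons in the tests); both are configuration knobs, and
self-convergence under 10-fold tightening is property-tested.

## Training procedure

`train_single()` minimises the regularised objective with ADAM (learning
rate from the hyperparameter bundle; $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$ — community defaults) for the first `budget["adam"]`
epochs, then hands the iterate to BFGS (`stats::optim`) until convergence
or `budget["total"]` epochs. One BFGS gradient evaluation counts as one
epoch for budget accounting, and the validation NLL is recorded at every
gradient evaluation; early stopping returns the parameters at the
validation minimum while the final iterate is kept alongside. With no
validation partition, early stopping degenerates to best-so-far on the
training objective. A start whose very first simulation fails reports
`status = "simulation_failed"`.

`train_two_stage()` implements the augmentation-scenario strategy: fit the
mechanistic model alone, then start the full UDE from the stage-1 estimates
(shared parameter names carried over, network at its zero-output
initialisation, noise parameters inherited). Because the first stage-2
iterate reproduces the stage-1 optimum exactly, the stage-2 training
objective can only improve on it — a nesting property the tests assert.

## Multi-start orchestration

`sample_starts()` draws joint initialisations by Latin hypercube sampling
(`lhs::randomLHS`): every continuous dimension is stratified into
`n_starts` equal-probability strata, hit exactly once. Mechanistic
parameters are sampled log-uniformly within their bounds and mapped to
$\rho$ by the inverse transform — log-uniform being the field's standard
for rate constants spanning decades. The learning rate and $\lambda$ are
log-uniform over their printed ranges; "no regularisation" is one extra
discrete level occupying, by default, the lowest fifth of the $\lambda$
stratification axis (the canonical grid specifies "none or a range"
without a mixture weight; the share is configurable). Discrete hyperparameters
(depth, width, activation, input normalisation) map their own LHS axes onto
the listed levels. Start $i$ derives a child seed from the master seed, so
runs are reproducible and order-independent; the child seed drives the
weight initialisation.

`run_multistart()` trains every start independently and selects the best
model by the smallest plain NLL on *all* data used during training
(training plus validation partition) evaluated at the early-stopped
parameters. Archives (`write_multistart()`) hold one JSON per start plus an
index TSV with the best start flagged.

## Synthetic data

`generate_glycolysis_dataset()` emulates the synthetic study design:
noise-free reference trajectories sampled on a uniform, endpoint-inclusive
grid of 8/16/31/46/61 points per observable over the training window
$t \in [0, 1.5]$ (46 points hence $\Delta t = 1/30$), corrupted with
additive Gaussian noise at 5/10/20/35% levels, plus a dense noise-free test
grid on $(1.5, 5]$ (default 100 points per observable) for extrapolation
error. "x% noise" needs a referent; the convention here is
$\sigma_s = (\text{noise}/100) \cdot \overline{|\bar y_s|}$ over the
training grid — a single per-observable additive scale consistent with the
error model. It is configurable and flagged as an interpretation.

Splits follow the canonical bookkeeping: the known initial-condition record
always trains and is counted in the total; the remaining points split 4:3
(8 points), 7:8 (16), and 1:1 otherwise, with odd remainders giving the
extra point to training (46 → 23:22 plus the initial record; a
deterministic tie-break). Validation points are placed by even spacing in
time-order — reproducible without randomness — and the same time points are
held out for every observable.

What the generator does *not* emulate: non-Gaussian or heteroscedastic
noise, missing records, per-observable time grids, or uncertainty in the
initial state. Passing tests on this generator therefore demonstrate
correctness of the pipeline under the stated noise model, not robustness to
real-data pathologies.

## Evaluation

* **NMAE** — mean over observables and test-grid times of
  $|y - \hat y| / y$ against noise-free truth on $(1.5, 5]$. The source
  formula is printed as a bare double sum; the mean is implemented (the
  reported magnitudes and the word "mean" support it) and the raw-sum
  variant stays available via `mean_over = "none"`. Truth values of zero
  raise an error; the glycolysis observables stay bounded away from zero.
* **Success** — strictly `NMAE < 0.15`, the threshold used to classify a
  fit as successful; the boundary case 0.15 counts as failure.
* **AIC/BIC** — $2J + 2n_\theta$ and $n_\theta \log n_d + 2J$ on the
  full-data NLL.
* **Confidence region** — a fit is inside the 95% region around the best
  fit iff its NLL is within $\tfrac12 \chi^2_{0.95}(df)$ of the best;
  $df = 1$ by default (a likelihood-ratio band on the best-model
  comparison; the df is configurable).
* **Oscillation recovery** — peak detection on the dense test grid;
  *sustained* means at least three peaks with the last peak retaining at
  least half the first peak's amplitude; amplitude is mean peak-to-trough;
  frequency the reciprocal median inter-peak interval; "close to truth"
  means within ±20%. All four cutoffs are package choices, exposed as
  arguments rather than constants, since "sustained" and "close" have no
  unique quantitative definition.
* **Parameter error** — $\sum_i (\log\hat\theta_i - \log\theta_i)^2$;
  **noise recovery** — $|\hat\sigma - \sigma| / \sigma$ per observable.

## Problem sizes in the shipped tests

Studies of this kind are typically run with $10^4$ or more optimisation
starts per data setting on a cluster. The package's test suite exercises
the identical pipeline at desk scale, sizes chosen as the smallest that
make the qualitative claims reproducible on one CPU: the success-threshold study
uses 100 starts at up to 700 epochs each on the (46 points, 5% noise)
setting; the regularisation-benefit study uses two paired 50-start runs
(λ ∈ [1,10] versus λ = 0, identical Latin hypercube otherwise) at up to 500
epochs on noise-free 61-point data; the noise-calibration check uses 1000
realisations. Stochastic conclusions at these budgets are directional, not
estimates of the original success rates.

## Known limitations

* The compiled fast path (and hence the adjoint gradient) covers the
  glycolysis family only; STAT5 training in pure R is practical for small
  budgets and the finite-difference gradient, not for full-scale
  multi-starts.
* No profile likelihoods or bootstrap uncertainty; joint $\sigma$
  estimation is the only uncertainty treatment.
* The network never sees time as an input except through scenario 2's
  stimulus; purely time-dependent missing mechanisms would need an extended
  input map.
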