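---
title: "Measuring information flow in cellular networks: models, gains and design choices"
author: "netflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring information flow in cellular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netflux)
```

# The problem

A cell relays extracellular signals — hormones, cytokines, stress cues —
through cascades of protein interactions down to transcription factors
(TFs), which in turn drive a gene regulatory network (GRN). How *strongly*
a given ligand's signal reaches a given TF, or how strongly one gene's
expression perturbs another's, is not directly measurable. netflux
estimates these quantities indirectly from expression data: it identifies
a linear model of the network and then computes worst-case input-to-output
gains — *signal transductivity* for ligand-to-protein channels and
*information transductivity* for gene-to-gene channels. Comparing the
per-TF gains between two conditions (say, normal and leukemic cells)
highlights the channels whose information flow the disease has rewired.

# The models

## Temporal (time-course) data

Protein expression `y(t)` over the coupling pathways follows the linear
recursion

$$y(t+1) = C\,y(t) + H + B\,u(t) - B_m m(t) + w(t),$$

where `C` holds interaction abilities between proteins, `H` basal levels,
`B` the binding abilities of the extracellular signals `u(t)` (ligands
bind receptors, so most rows of `B` are zero), and the optional
nonnegative `B_m` couples inhibitory epigenetic series `m(t)` with an
explicit minus sign so that inhibition is never conflated with
activation. `w(t)` is noise plus modeling error. Subtracting the
basal-only trajectory isolates the *information flow*
$\tilde y(t+1) = \sum_{j\le t} C^{t-j} B u(j)$, the input-driven part of
the response from a zero initial condition (`flowResponse()`).

A GRN is modeled the same way without basal or exogenous terms:
`x(t+1) = A x(t) + v(t)`, where `a[i,j]` is the regulatory ability of gene
`j` on gene `i` (positive = activator, negative = inhibitor).

## Sample (single-time-point) data

When observations are independent samples instead of a time course, the
recursion is replaced by its fixed point, `y = C y + H + B u + w`, giving
the static transfer $T = (I - C)^{-1} B$ from inputs to expression
(`steadyStateSample()`, `staticTransfer()`).

# Transductivity as a system gain

## Dynamic mode: the bounded real lemma

For a stable channel (state matrix spectral radius below one) the
transductivity is the worst-case energy amplification from input to
output. The package computes it through the discrete bounded real lemma:
the channel gain is at most $\sqrt\rho$ exactly when some Lyapunov matrix
$P \succ 0$ makes the block matrix

$$\begin{bmatrix} A'PA - P + D'D & A'PB \\ B'PA & B'PB - \rho I \end{bmatrix}$$

negative semidefinite (`brlMatrix()`). `minDynamicGain()` minimizes
$\rho$ over this constraint and reports the gain $\sqrt{\rho_{\min}}$,
the raw bound $\rho_{\min}$, and the certificate `P`.

Two implementation choices matter here:

* **Feasibility is decided spectrally, inside a bisection.** For a given
  level $\gamma = \sqrt\rho$, the LMI admits a feasible `P` exactly when
  $\gamma$ exceeds the worst frequency gain of the channel, which in turn
  holds exactly when (i) $\gamma$ beats the transfer gain at probe
  frequencies and (ii) the associated $2n \times 2n$ symplectic pencil has
  no unit-circle generalized eigenvalues — no frequency at which a
  singular value of the transfer crosses $\gamma$. This algebraic test is
  exact (no iterative SDP tolerance), cheap at these problem sizes, and
  drives a bisection to a relative tolerance of 1e-8 on the level.
* **The certificate comes from the Riccati equation.** At the optimum the
  LMI block is only semidefinite, so the certificate is recovered a
  relative margin of 1e-6 above $\rho_{\min}$ as the stabilizing solution
  of the associated H-infinity-type Riccati equation, found by
  Newton/Hewer iteration (each step a small Stein equation solved by
  Kronecker vectorization). The resulting `P` is symmetric positive
  definite and renders the block negative semidefinite at the certified
  level.

Unstable channels are reported as gain `Inf` with `feasible = FALSE`
rather than raising, so batch tables over many channels always complete.
The bound certified by `P` holds for every finite horizon, i.e. for all
inputs of bounded energy on any window.

An independent cross-check, `hinfOracle()`, estimates the same gain by a
dense frequency sweep (default 4096 grid points on $[0, \pi]$, sharpened
by local univariate optimization). It shares no code with the LMI route;
the test suite requires agreement within 0.1% on batches of random stable
systems.

## Static mode: singular values

For sample data no dynamics remain, and the transductivity is the largest
singular value of the static transfer (absolute value when scalar):
$\sigma_{\max}(D (I-C)^{-1} B)$ for a pathway channel,
$|D_i (I - A_j)^{-1} B_j|$ for a gene-to-gene channel
(`staticTransductivity()`). `(I - C)` must be invertible at a condition
number below 1e12; worse conditioning raises an error with the estimate.

## Gene-to-gene channels

To measure gene `j`'s influence on gene `i`, the GRN is rearranged so
that `x_j` acts as the input: column `j` of `A` becomes the input vector
`B_j` and is zeroed in the state matrix `A_j`, and the output selector
`D_i` picks gene `i` (`extractGrnChannel()`). This decomposition is exact
— `A_j X + B_j x_j` reproduces `A X` for every state — and it is the only
reading under which a single edge `j -> i` of weight `a` yields
transductivity `|a|` and a directed chain yields the product of its edge
weights, consistent with the interpretation of `a[i,j]` as a regulatory
ability. (The alternative reading, feeding a unit vector through the
output row, would give every single-edge channel a gain of one regardless
of the edge weight.) Self-channels `i = j` are computed and flagged, not
forbidden.

```{r chain}
ids <- paste0("g", 1:3)
A <- matrix(0, 3, 3, dimnames = list(ids, ids))
A["g2", "g1"] <- 0.5
A["g3", "g2"] <- 0.4
g <- GRNModel(A, semantics = "static")
gain(staticTransductivity(g, target = "g3", source = "g1"))  # 0.5 * 0.4
```

Both the raw LMI bound `rho` (an energy ratio) and its square root (an
amplitude gain, on the same scale as the static singular-value formula)
are reported in every result, since conventions differ between the two
data modes.

# Identification by recursive least squares

Each node is identified separately from its own regression: in temporal
mode `y_i(t+1)` on `[y(t), u(t), -m(t), 1]`, in sample mode `y_i(k)` on
the same covariates at `k` (GRNs drop the input and intercept terms). The
estimator is recursive least squares (RLS) — innovation
$\varepsilon = y - \phi'\theta$, covariance update
$P \leftarrow P - P\phi\phi'P/(1 + \phi'P\phi)$ (symmetrized every step),
then $\theta \leftarrow \theta + P\phi\varepsilon$ with the new `P` — run
in multiple refinement rounds: each round warm-starts `theta` from the
previous round and resets `P` to `P0Scale * I`, until the max-norm
parameter change drops below `tol` (default 1e-8) or `maxRounds`
(default 50) is reached.

One full pass equals the ridge-regularized batch solution with penalty
`1/P0Scale` centered at the round's initial parameters, so the rounds
form a contraction onto the ordinary least-squares solution on full-rank
problems. This makes `P0Scale` a trade-off: the default 1e3 provides mild
regularization for noisy data, while precision studies on noise-free data
use a larger value (1e6 in this package's tests) so the ridge bias
contracts to machine level within the round budget.

Three design choices deserve explanation:

* **Static diagonal.** The sample-data regression of `y_i` on all node
  expressions includes `y_i` itself, which admits the trivial perfect fit
  $\theta = e_i$ and makes `c[i,i]` unidentifiable. The default therefore
  fixes `c[i,i] = 0` in static mode; `includeStaticDiagonal = TRUE`
  restores the literal regression with a loud warning.
* **Masking removes columns.** A `NetworkStructure` mask (standing in for
  a curated topology) removes undeclared coefficients from the regression
  rather than zeroing them afterwards, avoiding bias from unidentifiable
  columns. Estimated inhibitor couplings that come out negative are
  clamped to zero and flagged, preserving the nonnegativity of `B_m`.
* **Sample order.** RLS at finitely many rounds depends on observation
  order; samples are exchangeable, so a seeded `shuffle` option is
  provided. Converged fits agree across orders.

Residual diagnostics (`residualDiagnostics()`) recompute the modeling
error $\hat w = y - \phi\hat\theta$ and its Pearson correlation with each
regressor series, summarizing the fraction with `|r| <= 0.2`; for a
well-specified fit the residuals are near-orthogonal to the regressors
and that fraction approaches one. Nodes fitted exactly (residual standard
deviation below 1e-10 of the response scale) are reported with
correlation 0 and a `negligible_residual` flag, since there is no residual
signal to correlate.

## Identifiability in sample mode

Noise-free steady states lie in the affine span of the inputs, so the
unmasked static regressors `[y_{-i}, u, 1]` are exactly collinear for any
network with two or more nodes: the full `(C, B)` pair is not recoverable
from noise-free sample data, only the composite transfer. Exact static
recovery therefore requires a structure mask under which every node's
regression is full rank — for example a signalling DAG in which ligands
bind only receptors and each downstream node has at most as many parents
as there are independent upstream signals. The masked recovery tests are
built that way; with noise, the per-sample disturbances provide the
missing excitation and the masked fit is consistent for DAG topologies.

# The synthetic-data module

`randomStableNetwork()` draws sparse mixed-sign coupling matrices (edge
probability `edgeDensity`, including self-regulation terms — the
degradation/decay entries standard in linear expression models) and
rescales them to an exact spectral radius target (default 0.7), so
temporal models are stable and all gains finite. Acyclic draws, being
nilpotent, cannot be rescaled; they receive diagonal decay entries first.
A draw with no edges at all returns a zero matrix with a warning. For
pathway models each input binds one receptor node, and any node the
inputs cannot reach is wired to a reached one — an unreached node would
idle at its basal fixed point and contribute no identifiable variation,
whereas real coupling pathways relay receptor signals to every
downstream protein.

`generateDataset()` realizes the study conditions: temporal mode
simulates the recursion from the basal fixed point driven by the chosen
input process (i.i.d. Gaussian by default, since persistent excitation is
needed for identification and no canonical ligand profile exists;
impulse, step and sinusoid are provided for closed-form checks), GRN
trajectories start from a random unit-scale initial state (their only
excitation source at zero noise), and sample mode pushes independent
input/noise draws through the steady-state solve. Defaults — 6 nodes, 2
inputs, density 0.3, radius 0.7, noise standard deviation 0.1, 100
observations — are stated as conventions for a small, well-excited
signalling module; none are derived from a specific biological dataset.

What the generator does *not* emulate: microarray platform effects
(probe-level noise, normalization artifacts), heavy-tailed or
heteroscedastic noise, nonlinearity, or unobserved regulators. Passing
recovery tests on these synthetic conditions demonstrates correctness of
the estimation and gain machinery under the model's own assumptions, not
robustness to real microarray pathologies.

`recoveryExperiment()` chains the whole pipeline — draw, simulate, fit
(against the true-topology mask, mirroring identification against a
curated network), measure gains — over replicates with per-replicate
seed offsets, reporting per-parameter bias and RMSE and true-vs-estimated
gains. It reproduces the expected consistency behavior: RMSE falls
monotonically with sample size and squared error grows with the noise
variance. The test suite runs these at 20 replicates with networks of 3-4
nodes and 50-1000 observations; the acceptance script uses the same
sizes.

# The differential workflow

`transductivityTable()` computes one gain per requested channel
(dispatching on model semantics), and `compareConditions()` joins two
condition-specific tables, reporting per channel both gains, their
difference and ratio, and a gain/loss flag, sorted by `|log ratio|`. At
zero noise, weakening a single edge changes exactly the channels whose
input-to-output paths traverse it — the synthetic analogue of comparing
normal against diseased cells. Ratios against a zero baseline are
reported as `Inf` with the raw gains preserved; the flag threshold
(`ratioTol`) defaults to 1e-6, appropriate for exact tables, and should
be widened (e.g. to 0.1) for noisily estimated ones.

# Numerical choices, degenerate inputs, limitations

* Bisection relative tolerance 1e-8; unit-circle tolerance 1e-6 for the
  pencil test (eigenvalues split off the circle like the square root of
  the level margin, so these scales are well separated); stability
  tolerance 1e-9; certificate margin 1e-6 with automatic relaxation if
  the Riccati iteration stalls at the boundary.
* Channels whose transfer is identically zero (first `n` Markov
  parameters vanish) short-circuit to gain 0 with a Lyapunov certificate
  from the plain Stein equation.
* A numerically singular pencil is treated as an infeasible level — it
  indicates the probe sits on a singular-value crossing — and the
  bisection moves on.
* Constant expression series, all-zero regressors, underdetermined
  sample counts and rank-deficient regressions do not stop a fit; they
  set per-node flags (`rank_deficient`, `no_information`,
  `underdetermined`) in the report.
* Everything is linear: saturation, multiplicative regulation and other
  nonlinear effects are out of scope, as are continuous-time models and
  unevenly sampled series. Estimation error scales with the data noise
  variance, as the consistency experiments show.
* Temporal data are assumed to be consecutive, equispaced observations;
  sample data exchangeable draws from a common condition.
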