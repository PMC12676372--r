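---
title: "Whole-volume quantitative MRI fitting: models, solvers and design choices"
author: "qmrfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-volume quantitative MRI fitting: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Quantitative MRI estimates physical tissue parameters (relaxation rates,
compartment fractions, diffusivities) by fitting a forward signal model to
multi-measurement data at every voxel. The conventional estimator is
voxel-wise nonlinear least squares,

$$\hat\theta_r = \arg\min_\theta \; \big\| w\,(s_{\mathrm{meas},r}(\phi) - s(\phi, \theta))\big\|_2^2,$$

repeated independently for each voxel $r$, with $\phi$ the acquisition
parameters (echo times, b-values) and $w$ an optional weighting. `qmrfit`
instead poses **one** optimisation problem over the entire masked volume,

$$\hat\Theta = \arg\min_\Theta \; \big\| M\, W\, (S_{\mathrm{meas}}(\phi) - S(\phi, \Theta)) \big\|_{L1\mid L2} + \lambda R(\Theta),$$

where $M$ is the signal mask, $W$ a weight map, $S$ the forward model
evaluated for all voxels at once, and $R$ an optional regulariser coupling
voxels spatially. The whole-volume formulation is what makes spatial
regularisation possible at all — a voxel-wise fit has no notion of its
neighbours — and it turns parameter estimation into the same kind of
first-order optimisation used to train neural networks.

Two solvers share one forward-model contract:

* `fitGradient()` — first-order gradient descent (Adam, SGDM, RMSProp) on
  the global objective, with exact gradients and hard box bounds via a
  scaled-logit reparameterisation;
* `fitMCMC()` — fully vectorised posterior sampling (Metropolis–Hastings
  with independent chains per voxel, or the affine-invariant ensemble
  sampler) under a Gaussian likelihood and a bound-truncated uniform prior,
  yielding per-voxel posterior mean/SD/IQR uncertainty maps.

A forward model is a deterministic function `(theta, grid) -> predicted
signal` whose output matches the measured data's shape; `forwardModel()`
wraps it with parameter names, box bounds and a default initialisation, and
`registerModel()` makes it available to both solvers and the command-line
interface by name. The built-ins are single-compartment R2\* relaxometry
(`"monoexp_r2s"`, $S = S_0 e^{-t R_2^*}$), a two-pool gradient-echo model
(`"twopool_gre"`, $S = S_0 (f e^{-t R_{2a}} + (1-f) e^{-t R_{2b}})$) used as
an ill-conditioned demonstration target, and the SENSE/CAIPI encoding
operator (`"sense"`) for parallel-imaging reconstruction.

## Gradients without an AD runtime

The reference implementation this design follows relies on automatic
differentiation. R has no comparable AD runtime among the package's
dependencies, so `qmrfit` obtains the same gradients by composition of
exact pieces:

* the data losses (masked mean of $|Wr|$ or $(Wr)^2$) have closed-form
  derivatives with respect to the prediction;
* the built-in models carry analytic Jacobians (checked against central
  differences in the test suite);
* all built-in regularisers (volumetric TV, graph TV, prior penalty) have
  analytic subgradients, with the $|x|$ derivative taken as 0 at ties;
* the SENSE operator is linear, so its gradient is the exact adjoint
  operator (verified by the adjoint identity to machine precision);
* the scaled-logit bound transform contributes the factor
  $(ub-lb)\,\sigma(z)(1-\sigma(z))$ by the chain rule.

A user model that does not provide a Jacobian falls back to a vectorised
central-difference Jacobian: each parameter map is perturbed wholesale by
$\pm 10^{-6}(ub-lb)$ and the per-element signal difference is used as the
derivative. This is exact (up to truncation error) for voxel-separable
models — the overwhelmingly common case in qMRI, where each voxel's
prediction depends only on that voxel's parameters — and costs two forward
evaluations per parameter per iteration. Models whose output couples voxels
(like the SENSE operator) must provide their own gradient; the
reconstruction front-end `reconGradient()` does so via `senseAdjoint()`.

## Bound handling

The gradient solver enforces box bounds through
$\theta = lb + (ub - lb)\,\mathrm{sigmoid}(z)$ and optimises $z$
unconstrained: bounds can never be violated mid-run, the map is smooth and
strictly monotone, and the bound midpoint corresponds to $z = 0$ (which is
also the default initialisation when neither the user nor the model supplies
one). The sampler instead treats the bounds as a truncated-uniform prior and
rejects any proposal with a parameter outside its box; this preserves
proposal symmetry and keeps the likelihood identical between the two MCMC
algorithms. Both mechanisms honour the same per-parameter `lower`/`upper`
specification.

## The optimisers and stopping rules

`fitOptions()` exposes the solver controls:

| option | meaning | default |
|---|---|---|
| `optimizer` | `adam`, `sgdm`, `rmsprop` | `adam` |
| `initialLearnRate` | update step size in the unconstrained space | 0.001 |
| `iteration` | iteration cap | 4000 |
| `tol` | stop when loss falls below this | 0 (off) |
| `convergenceValue` | stop when the loss slope flattens below this | 1e-8 |
| `convergenceWindow` | window for the slope estimate | 20 |
| `lossFunction` | `l1` or `l2` data loss | `l1` |
| `isOptimiseMemory` | gather parameters to masked voxels before evaluation | `TRUE` |

Adam uses the standard constants $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$; SGDM momentum and the RMSProp decay are 0.9. The three
stopping criteria are checked once per iteration, after the update, in a
fixed order: loss below `tol`, iteration cap, then the ordinary-least-squares
slope of the last `convergenceWindow` loss values compared as
$|\mathrm{slope}| < \texttt{convergenceValue}$. The slope is not evaluable
before the window fills, which counts as "not converged". The default
window of 20 iterations makes the slope robust to the small loss
fluctuations a constant-step optimiser produces.

Two normalisation decisions deserve emphasis, because the original design
leaves them open:

* **the data loss is a mean, not a sum**, over masked signal elements, so
  `tol` and regularisation weights do not change meaning when the mask
  grows;
* **TV is a mean over valid differences** for the same reason. Graph TV is
  the one exception: it is the plain per-vertex double sum, exactly as the
  surface formulation writes it, so each undirected edge contributes twice.

A practical consequence of the mean-normalised data loss is that
regularisation weights scale with the *squared signal amplitude* for the
`l2` loss: with signals of order $10^3$, a TV weight of order $10^4$–$10^5$
on a fraction map is the relevant range, not $10^{-3}$. The weight is a
user choice and the tests select it by a coarse sweep on the synthetic
phantom.

Execution is deterministic: there is no stochastic minibatching. "Stochastic"
in the gradient-descent family name refers to the optimiser heritage; full
batch evaluation keeps every run exactly reproducible.

Adam with a constant learning rate has an asymptotic oscillation floor
proportional to the learning rate, so the recovery experiments trade
iterations for accuracy explicitly: the noiseless recovery study uses
`initialLearnRate = 0.002` for 80&nbsp;000 iterations on an $8^3$ volume
(about 45 s on one CPU core), which lands every masked voxel well inside
0.1 % relative error; at realistic SNR the noise floor dominates long
before that and 10–20&nbsp;000 iterations at a 2–5× larger rate suffice.
Learning-rate schedules are deliberately out of scope.

## Memory-optimised evaluation

With `isOptimiseMemory = TRUE` (the default) the parameter maps are
gathered to a `(masked voxels) × parameters` list layout before the forward
evaluation, so the model never touches background voxels; when a spatial
regulariser is active the maps are scattered back to the native volume each
iteration to evaluate $R$ and its gradient. With the flag off, the model is
evaluated on full volumes and masking happens inside the loss only — the
two paths produce identical losses and fits (asserted in the tests), the
flag trades memory for reshuffling. Gather order is the column-major linear
index over the spatial dimensions, fixed and documented, so flat layouts
are reproducible across runs.

## The samplers and their accounting

Both MCMC algorithms use the Gaussian log-likelihood
$-\sum_m r_{vm}^2 / (2\sigma_v^2)$ with a **fixed, user-supplied** noise SD
(`noiseSd`, scalar or per-voxel map). $\sigma$ is deliberately not sampled:
the design keeps the likelihood identical across the two algorithms and
lets the conjugate-Gaussian toy validate both against a closed form. The
optional helper `estimateNoiseSd()` supplies a residual-based estimate from
a quick NLLS pre-fit when no better value is available.

* **Metropolis–Hastings**: `nProposals` independent chains per voxel
  (default 4), symmetric normal proposal with per-parameter SD `xStepSize`
  (default 5 % of the bound range), all voxels and chains advancing in
  lockstep.
* **Ensemble**: `Nwalkers` walkers per voxel (default 50) updated half by
  half with stretch moves $Y = X_j + z (X_k - X_j)$, $z$ drawn with density
  $\propto 1/\sqrt z$ on $[1/a, a]$ via $z = ((a-1)u + 1)^2 / a$, and
  acceptance factor $z^{d-1}$ times the likelihood ratio. The `stepSize`
  option is the stretch parameter $a$ (default 2). Walkers are initialised
  at the user/model init plus a uniform jitter of 1 % of the bound range
  (`walkerJitter`), because identical walkers cannot move.

Burn-in and thinning follow one retention rule (`retainSchedule()`): per
chain, discard the first `floor(burnin * iteration)` states and keep states
`burn + thinning, burn + 2*thinning, ...` — i.e.
`floor(iteration * (1 - burnin) / thinning)` retained states per chain. The
offset-by-`thinning` start is what makes both canonical configurations —
4 chains × 25&nbsp;000 iterations and 50 walkers × 2&nbsp;000 iterations,
each with 10 % burn-in and thinning 100 — retain exactly 900 posterior
samples.

### Reproducibility across execution strategies

The samplers are vectorised across voxels, but each voxel consumes an
independent random substream derived from the master seed
(`(seed + 1000003 · voxel) mod 2147483629`) in a documented order (MH: all
proposal normals as a `(parameters, chains, iterations)` array, then all
acceptance uniforms; ensemble: initialisation jitter, then per iteration
and half the stretch/partner/acceptance uniform blocks). A sequential
per-voxel reference loop that draws in the same order produces **bit-identical**
retained samples — asserted in the test suite — so results do not depend on
how the computation is batched.

## Regularisation

`composeRegularizers()` combines weighted terms $\sum_k \lambda_k R_k$:

* `tvTerm()` — anisotropic volumetric TV: mean absolute forward difference
  along the first 2 or 3 axes. Differences crossing the mask boundary or
  image edge are dropped (no replicate padding), so smoothing never leaks
  across tissue/air boundaries; a single-voxel mask contributes 0. The
  anisotropic (L1-of-differences) form was chosen over the isotropic one
  because it is directly verifiable against a brute-force nested-loop
  oracle, and the choice is isolated behind the term interface.
* `graphTvTerm()` — surface TV over a mesh adjacency (`readEdgeList()`
  reads strictly 0-based two-column text; no 1-based auto-detection). The
  default weight $10^{-5}$ matches the empirical surface-fitting setting.
* `priorTerm()` — mean of $|\theta - \mu|/\sigma$ against externally
  derived mean/SD maps, for stabilising low-SNR fits with cohort priors.
* `customTerm()` — any function returning a finite scalar; supply `grad` to
  use it with the gradient solver (there is no silent finite-difference
  fallback for volume-coupled custom terms, an error names the term
  instead).

## Parallel-imaging reconstruction

The SENSE/CAIPI application treats image reconstruction as the same global
optimisation: `reconGradient()` minimises
$\mathrm{mean}\,|k - E I|_{L1|L2} + \lambda_{TV}\, TV_{2D}(I) + \lambda_{L2}\,\mathrm{mean}\,|I|^2$
over the complex multi-echo image stack $I$ (parameterised by real and
imaginary parts), where $E$ applies coil sensitivities, a **unitary** FFT
and the per-echo undersampling mask. The unitary convention makes the
adjoint of the sampled FFT exactly the masked inverse FFT, so the adjoint
identity holds to machine precision and regularisation weights keep a
stable scale. The direction labelled "forward" here maps image to k-space;
that is a notation choice, the operator contract is what is tested.
`lsqrBaseline()` solves the same Tikhonov least-squares problem by
conjugate gradients on the normal equations and serves as the independent
solver for agreement checks — note its $\lambda$ is defined on the
*unnormalised* objective, so $\lambda_{cg} = \lambda_{L2} \cdot
n_{\mathrm{sampled}} / n_{\mathrm{image}}$ makes the two objectives
identical.

The synthetic phantom (`genPhantomRecon()`) provides a piecewise-constant
complex multi-echo object with mono-exponential magnitude decay and smooth
phase, smooth synthetic coils normalised to $\sum_c |C_c|^2 = 1$ per voxel
(making fully sampled acquisition exactly invertible), and a CAIPI mask
with a kz offset of `zShift` per ky row, rotated by `zTEShift` across
echoes. Geometry defaults were chosen so the undersampling pattern tiles
k-space as a true lattice (the ky extent is a multiple of
$R_z/\gcd(\mathrm{zShift}, R_z)$): at $R_z = 9$, `zShift = 3` the nine
aliasing replicas then spread over three distinct y-shifts, which ring
coils separate well, leaving z-separation to coils whose centres are spread
over the full z extent. Sixteen coils are the default because a unique
least-squares solution of the 9-fold aliased system needs at least nine
coil equations per voxel group. Even so, the 9× problem is genuinely
ill-conditioned — conjugate gradients keep reducing the truth error for
thousands of iterations — which is precisely the regime where the Tikhonov
or TV term earns its keep; the solver-agreement check therefore runs at a
conditioning-restoring $\lambda_{L2} = 0.01$.

## What the synthetic data does and does not emulate

The generators cover every validation experiment at desk scale: multi-echo
mono-exponential volumes at a stated SNR (defined as mean noise-free signal
at the *first echo* inside the mask divided by the noise SD, mirroring the
b = 0 anchoring used in diffusion protocols), a piecewise-constant two-pool
volume for regularisation studies, the CAIPI phantom above, and a
conjugate-Gaussian toy whose posterior is known in closed form
($\bar y$, $\sigma/\sqrt n$). Noise is additive Gaussian by default to
match the samplers' Gaussian likelihood; a Rician magnitude option exists
(`rician = TRUE`) but is off by default and not used by the validation
suite. Every generator is a pure function of its seed and settings.

Deliberately not emulated: physiological/instrumental confounds (motion,
B0/B1 inhomogeneity, drift), Rician bias at very low SNR, realistic coil
noise covariance, partial-volume mixtures, and spatially correlated noise.
Passing the synthetic suite therefore demonstrates the *estimators* are
correct and well-behaved, not that any particular in-vivo protocol will
reach the same accuracy.

Two-pool defaults were chosen for identifiability at the demo's SNR: pool
rates $R_{2a} \in [0.10, 0.15]$, $R_{2b} \in [0.010, 0.020]$ /ms (a fast
myelin-water-like pool against a slow axonal-like pool) sampled by 20
echoes from 1 to 60 ms. With overlapping rate ranges or a short echo train
the voxel-wise problem is degenerate at any realistic SNR — the well-known
pool-swap ambiguity — and no solver setting rescues it; that regime is
exactly what the TV experiment demonstrates regularisation against.

## Problem sizes used by the validation suite

All checks run on one CPU core. The suite uses: $8^3$ volumes with 12
echoes for recovery studies (noiseless: 80&nbsp;000 iterations; SNR 50:
20&nbsp;000 iterations plus two per-voxel NLLS reference fits);
a $12 \times 12 \times 4$ two-pool phantom at SNR 10 (6&nbsp;000 iterations
per fit); 50-voxel conjugate toys at the two canonical 900-sample sampler
settings; a 20-voxel, 2&nbsp;000-iteration bit-identity check; and the
$8 \times 24 \times 18$, 16-coil, 6-echo CAIPI phantom (conjugate
gradients to tolerance, 500 Adam iterations). These sizes keep the whole
suite within a few minutes while leaving every tolerance at its stated
value.

## Numerical details and degenerate inputs

* Values on or outside bounds entering the logit transform are clamped just
  inside (offset $10^{-9}(ub-lb)$) with a warning.
* Non-finite gradients abort the fit naming the offending parameter;
  a non-finite loss aborts returning the last good state with termination
  reason `"aborted"`.
* Out-of-bounds MCMC proposals are rejected, but their likelihoods are
  evaluated at bound-clamped values so vectorised and sequential paths do
  identical arithmetic.
* Single-voxel masks are legal everywhere; spatial TV then contributes 0.
* `l1` losses and TV use subgradient 0 at exact ties.
* Complex residuals use the complex modulus throughout.

## Known limitations

* The finite-difference Jacobian fallback silently assumes voxel
  separability; volume-coupled user models must supply gradients.
* The sampler's noise SD is fixed, not marginalised; uncertainty maps are
  conditional on it.
* No convergence diagnostics beyond acceptance rates and posterior spread
  (no R-hat, no ESS estimate).
* The CG baseline and gradient recon agree on the regularised objective;
  at 9-fold acceleration neither recovers the truth without regularisation,
  by the physics of the problem rather than by implementation choice.
* No minibatching or learning-rate schedules; very large volumes pay the
  full per-iteration cost.
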