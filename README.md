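# qmrfit

Whole-volume solvers for quantitative MRI parameter mapping in R.

Quantitative MRI (qMRI) estimates physical tissue parameters — relaxation
rates, compartment fractions, diffusivities — by fitting a signal model to
multi-measurement data at every voxel. The conventional approach fits each
voxel independently by nonlinear least squares,

    argmin_θ || w (s_meas,r(φ) − s(φ, θ)) ||²   for every voxel r,

which is slow, cannot share information between voxels, and gives no
uncertainty. `qmrfit` instead solves **one** problem over the whole masked
volume,

    argmin_Θ || M W (S_meas(φ) − S(φ, Θ)) ||_{L1|L2} + λ R(Θ),

with `M` the signal mask, `W` an optional weight map and `R` an optional
regulariser (volumetric or surface total variation, prior penalties, custom
terms). Two solvers share one pluggable forward-model interface:

* **`fitGradient()`** — first-order optimisation (Adam / SGD-with-momentum /
  RMSProp) of the global objective with exact gradients and hard box bounds
  via a scaled-logit reparameterisation; three stopping criteria
  (loss threshold, iteration cap, loss-slope convergence).
* **`fitMCMC()`** — fully vectorised Bayesian sampling (Metropolis–Hastings
  with independent chains per voxel, or affine-invariant ensemble stretch
  moves) under a Gaussian likelihood and bound-truncated uniform prior, with
  burn-in/thinning accounting and posterior mean / SD / IQR maps. Each voxel
  consumes a seed-derived random substream in a documented order, so the
  vectorised run is bit-identical to a sequential per-voxel loop.

Built-in models: mono-exponential R2\* relaxometry (`"monoexp_r2s"`), a
two-pool gradient-echo model (`"twopool_gre"`), and a SENSE/CAIPI
parallel-imaging encoding operator (`"sense"`) with a gradient-descent
reconstruction front-end (`reconGradient()`) and a conjugate-gradient
least-squares baseline (`lsqrBaseline()`). A per-voxel bounded NLLS
reference (`nllsOracle()`), synthetic-data generators for every validation
experiment, NIfTI/YAML/edge-list I/O and a command-line interface
(`inst/cli/qmrfit`, subcommands `simulate` / `fit-gradient` / `fit-mcmc` /
`recon`) round out the toolkit. User models are added with
`forwardModel()` + `registerModel()` — a prediction function is enough; an
analytic Jacobian is optional.

## Worked example

Simulate a multi-echo gradient-echo volume (8×8×8, 12 echoes, SNR 50 at the
first echo), fit it with the whole-volume gradient solver, then quantify
per-voxel uncertainty with the sampler:

```r
library(qmrfit)

sim <- genMonoexpVolume(shape = c(8, 8, 8), snr = 50, seed = 1)
fit <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
                   options = fitOptions(initialLearnRate = 0.01, iteration = 10000,
                                        lossFunction = "l2", convergenceValue = 0))
fit
#> FitResult: 10000 iteration(s), terminated by 'max_iter'
#>   final loss 138.63 (data term 138.622)
#> ParameterMaps over shape 8 x 8 x 8
#>   S0 in [0, 5000]: median 538.715 (304 NA)
#>   R2star in [0.0001, 0.2]: median 0.0113055 (304 NA)
```

The final loss is the masked mean squared residual — at SNR 50 the noise SD
is about 17 signal units, so a mean squared residual of ≈139 is the noise
floor, not misfit. The 304 `NA`s are the voxels outside the ellipsoidal
mask. The median estimated R2\* of 0.0113 /ms sits inside the simulated
range (0.01–0.05 /ms); against the known truth the median relative R2\*
error here is 4.8 %, consistent with single-voxel precision at this SNR.

```r
ch <- fitMCMC("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
              options = mcmcOptions("mh", iteration = 4000, thinning = 20,
                                    xStepSize = c(S0 = 15, R2star = 0.002),
                                    noiseSd = sim$noiseSd, seed = 2))
ch
#> ChainStore (mh): 208 voxel(s), 2 parameter(s), 720 retained sample(s)
#>   4 chain(s)/walker(s), mean acceptance 0.208
s <- summarizeChains(ch)
mean(posteriorSd(s)$R2star)
#> [1] 0.00259
```

720 retained samples = 4 chains × floor(4000 · 0.9 / 20). The posterior SD
map is the voxelwise uncertainty: ≈0.0026 /ms here, and indeed the median
deviation of the posterior mean from the simulated truth is 0.0007 /ms —
well within one posterior SD. With the canonical settings (4 × 25 000
iterations, 10 % burn-in, thinning 100 — or 50 walkers × 2 000 for the
ensemble sampler) exactly 900 samples are retained per voxel.

The methods vignette (`vignettes/whole-volume-fitting.Rmd`) documents the
model, the gradient machinery, the samplers' reproducibility contract, all
regularisers and every numerical design choice.

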