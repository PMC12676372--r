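test_that("Gaussian log-likelihood: dropped constants and sigma scaling", {
    y <- matrix(c(1, 2, 3, 4), 2, 2)
    expect_equal(logLikelihoodGaussian(y, y, 1), c(0, 0))
    # residual vector (sigma, sigma) -> -1
    expect_equal(logLikelihoodGaussian(matrix(c(2, 2), 1, 2),
                                       matrix(c(0, 0), 1, 2), 2), -1)
    r <- matrix(rnorm(6), 2, 3)
    expect_equal(logLikelihoodGaussian(r, r * 0, 2),
                 logLikelihoodGaussian(r, r * 0, 1) / 4)
    expect_error(logLikelihoodGaussian(y, y, 0), "positive")
})

test_that("retention schedule reproduces the published chain accounting", {
    expect_identical(retainSchedule(25000, 0.10, 100, nChains = 4)$total, 900L)
    expect_identical(retainSchedule(2000, 0.10, 100, nChains = 50)$total, 900L)
    # burnin 0, thinning 1: every state retained
    s <- retainSchedule(37, 0, 1)
    expect_identical(s$indices, 1:37)
    expect_error(retainSchedule(10, 0.9, 100), "retained")
})

test_that("zero proposal step size freezes the Metropolis-Hastings chain", {
    toy <- genGaussianToy(nObs = 10, thetaTrue = 1, sigma = 1, nVoxels = 3, seed = 50)
    ch <- fitMCMC(toy$model, toy$signal, grid = toy$grid, layout = "list",
                  options = mcmcOptions("mh", iteration = 200, burnin = 0,
                                        thinning = 10, nProposals = 2,
                                        xStepSize = c(theta = 0), noiseSd = 1,
                                        seed = 1))
    expect_true(all(chainSamples(ch) == toy$model@init[["theta"]]))
})

test_that("vectorised MH is bit-identical to the sequential per-voxel reference", {
    toy <- genGaussianToy(nObs = 15, thetaTrue = 2, sigma = 1, nVoxels = 8, seed = 51)
    opt <- mcmcOptions("mh", iteration = 400, burnin = 0.1, thinning = 10,
                       nProposals = 3, xStepSize = c(theta = 0.4), noiseSd = 1,
                       seed = 99)
    ch <- fitMCMC(toy$model, toy$signal, grid = toy$grid, options = opt,
                  layout = "list")
    bundle <- qmrfit:::validateInputs(toy$signal, NULL, NULL, toy$grid, "list")
    Y <- toy$signal
    seqRun <- qmrfit:::.mhSequential(
        toy$model, bundle$grid, Y, 1,
        matrix(toy$model@init[["theta"]], 8, 1, dimnames = list(NULL, "theta")),
        toy$model@lower, toy$model@upper, c(theta = 0.4), 3L, 400L,
        retainSchedule(400, 0.1, 10), qmrfit:::.voxelSeeds(99L, 8))
    expect_identical(chainSamples(ch), seqRun$samples)
    expect_identical(acceptanceRate(ch), seqRun$acceptance)
})

test_that("vectorised ensemble equals the engine run voxel-by-voxel", {
    toy <- genGaussianToy(nObs = 12, thetaTrue = 0, sigma = 1, nVoxels = 5, seed = 52)
    opt <- mcmcOptions("ensemble", iteration = 200, burnin = 0.1, thinning = 10,
                       Nwalkers = 8, noiseSd = 1, seed = 17)
    ch <- fitMCMC(toy$model, toy$signal, grid = toy$grid, options = opt,
                  layout = "list")
    seeds <- qmrfit:::.voxelSeeds(17L, 5)
    sched <- retainSchedule(200, 0.1, 10)
    ref <- array(0, dim(chainSamples(ch)))
    for (v in 1:5) {
        one <- qmrfit:::.ensembleRun(
            toy$model, toy$grid, toy$signal[v, , drop = FALSE], 1,
            matrix(toy$model@init[["theta"]], 1, 1, dimnames = list(NULL, "theta")),
            toy$model@lower, toy$model@upper, 2, 8L, 200L, sched, seeds[v], 0.01)
        ref[v, , ] <- one$samples
    }
    expect_identical(chainSamples(ch), ref)
})

test_that("both samplers reproduce the conjugate-Gaussian posterior", {
    # closed form: posterior mean = ybar, posterior SD = sigma/sqrt(n)
    toy <- genGaussianToy(nObs = 100, thetaTrue = 1, sigma = 1, nVoxels = 10, seed = 53)
    se <- toy$posteriorSd
    expect_equal(se, 0.1)
    mh <- fitMCMC(toy$model, toy$signal, grid = toy$grid, layout = "list",
                  options = mcmcOptions("mh", iteration = 4000, burnin = 0.1,
                                        thinning = 15, nProposals = 4,
                                        xStepSize = c(theta = 0.3), noiseSd = 1,
                                        seed = 3))
    en <- fitMCMC(toy$model, toy$signal, grid = toy$grid, layout = "list",
                  options = mcmcOptions("ensemble", iteration = 1000, burnin = 0.2,
                                        thinning = 10, Nwalkers = 20, noiseSd = 1,
                                        seed = 3))
    for (ch in list(mh, en)) {
        s <- summarizeChains(ch)
        expect_lt(max(abs(posteriorMean(s)$theta - toy$posteriorMean)), 4 * se)
        expect_lt(max(abs(posteriorSd(s)$theta / se - 1)), 0.25)
    }
})

test_that("retained samples always respect the bounds; acceptance in [0,1]", {
    sim <- genMonoexpVolume(shape = c(3, 3, 3), snr = 30, seed = 54)
    opt <- mcmcOptions("mh", iteration = 600, burnin = 0.1, thinning = 10,
                       nProposals = 2, noiseSd = sim$noiseSd, seed = 8)
    ch <- fitMCMC("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
                  options = opt)
    expect_true(validObject(ch))
    mod <- getModel("monoexp_r2s")
    for (p in seq_along(mod@parameters)) {
        x <- chainSamples(ch)[, p, ]
        expect_true(all(x >= mod@lower[[p]] & x <= mod@upper[[p]]))
    }
    expect_true(all(acceptanceRate(ch) >= 0 & acceptanceRate(ch) <= 1))
})

test_that("ensemble stretch acceptance reduces to likelihood ratio at d = 1", {
    # with one parameter the (d-1) log z term vanishes, so on a
    # flat-likelihood target every in-bounds stretch proposal is accepted;
    # bounds are wide and the run short enough that none goes out of bounds
    # on a flat target walkers spread multiplicatively, so the bounds are set
    # far beyond the worst-case 5-iteration spread: no bound rejections
    flat <- forwardModel("flat_ll", "theta", c(theta = -1e6), c(theta = 1e6),
                         init = c(theta = 0),
                         fun = function(theta, grid)
                             matrix(0, length(theta$theta), grid[["n_obs"]]))
    y <- matrix(0, 4, 3)
    ch <- fitMCMC(flat, y, grid = acquisitionGrid(n_obs = 3), layout = "list",
                  options = mcmcOptions("ensemble", iteration = 5, burnin = 0,
                                        thinning = 1, Nwalkers = 10,
                                        noiseSd = 1, seed = 2))
    expect_equal(mean(acceptanceRate(ch)), 1)
})

test_that("posterior summaries: two-point case and degenerate chains", {
    mk <- function(samples) new("ChainStore", samples = samples,
                                parameters = "a", chainId = rep(1L, dim(samples)[3]),
                                algorithm = "mh", lower = c(a = -10), upper = c(a = 10),
                                acceptance = matrix(1, 1, 1), seed = 1L)
    two <- mk(array(c(0, 2), c(1, 1, 2)))
    s <- summarizeChains(two)
    expect_equal(posteriorMean(s)$a, 1)
    expect_equal(posteriorSd(s)$a, sqrt(2))
    same <- mk(array(3, c(1, 1, 5)))
    s2 <- summarizeChains(same)
    expect_equal(posteriorSd(s2)$a, 0)
    expect_equal(posteriorMean(s2)$a, 3)
    expect_error(summarizeChains(mk(array(1, c(1, 1, 1)))), "2 retained")
})

test_that("two-state discretised target reaches its stationary distribution", {
    # sharp two-well likelihood: MH chain frequencies must match the
    # enumerable Boltzmann weights within Monte-Carlo error
    wells <- forwardModel("two_well", "theta", c(theta = -1), c(theta = 1),
                          init = c(theta = 0.3),
                          fun = function(theta, grid) {
                              # piecewise-constant prediction: sign of theta
                              matrix(sign(theta$theta) * 0.5, length(theta$theta),
                                     grid[["n_obs"]])
                          })
    y <- matrix(0.5, 1, 4)     # data prefer the positive state
    # target: ll+ = 0, ll- = -sum((1)^2)/(2 sigma^2) with sigma = 1 -> -2
    ch <- fitMCMC(wells, y, grid = acquisitionGrid(n_obs = 4), layout = "list",
                  options = mcmcOptions("mh", iteration = 20000, burnin = 0.2,
                                        thinning = 4, nProposals = 2,
                                        xStepSize = c(theta = 1.5), noiseSd = 1,
                                        seed = 31))
    th <- chainSamples(ch)[1, 1, ]
    pPlus <- mean(th > 0)
    expect_equal(pPlus, 1 / (1 + exp(-2)), tolerance = 0.05)
})
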