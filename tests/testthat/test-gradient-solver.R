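test_that("data loss: zero residual, constant residual, weight annihilation", {
    a <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
    expect_equal(dataLoss(a, a, norm = "l1"), 0)
    expect_equal(dataLoss(a, a, norm = "l2"), 0)
    cst <- a + 0.7
    expect_equal(dataLoss(cst, a, norm = "l1"), 0.7)
    expect_equal(dataLoss(cst, a, norm = "l2"), 0.49)
    expect_equal(dataLoss(cst, a, weights = array(0, dim(a)), norm = "l2"), 0)
    expect_error(dataLoss(a, a, mask = array(FALSE, c(4, 4, 4))), "no")
    # complex residuals use the modulus
    z <- array(complex(real = 3, imaginary = 4), c(2, 2, 2, 1))
    expect_equal(dataLoss(z, z * 0, norm = "l1"), 5)
})

test_that("optimiser steps follow their recurrences", {
    z <- matrix(c(1, -2, 3, 0), 2, 2)
    g0 <- z * 0
    # zero gradient from zero state: fixed point for all three
    expect_equal(adamStep(z, g0)$z, z)
    expect_equal(sgdmStep(z, g0)$z, z)
    expect_equal(rmspropStep(z, g0)$z, z)
    # first Adam step with constant gradient: magnitude ~ lr in every component
    g <- matrix(c(10, -0.3, 2, -8), 2, 2)
    s1 <- adamStep(z, g, lr = 0.05)
    expect_equal(abs(s1$z - z), matrix(0.05 * abs(g) / (abs(g) + 1e-8), 2, 2),
                 tolerance = 1e-9)
    # determinism: identical calls, identical output
    expect_identical(adamStep(z, g, lr = 0.05), s1)
    # zero-momentum SGDM is plain gradient descent
    expect_equal(sgdmStep(z, g, lr = 0.01, momentum = 0)$z, z - 0.01 * g)
    # RMSProp with constant gradient approaches step magnitude lr
    st <- NULL; zz <- z
    for (i in 1:200) { u <- rmspropStep(zz, g, st, lr = 0.01); st <- u$state }
    expect_equal(abs(u$z - zz), matrix(0.01, 2, 2), tolerance = 0.01 * 0.05)
})

test_that("convergence slope is the OLS slope over the trailing window", {
    h <- 5 - 0.01 * (1:100)
    expect_equal(convergenceSlope(h, 20), -0.01)
    expect_equal(convergenceSlope(rep(2, 50), 20), 0)
    expect_true(is.na(convergenceSlope(h[1:10], 20)))     # not yet evaluable
    expect_error(convergenceSlope(h, 1), "greater than 1")
    # default window is 20
    expect_identical(formals(convergenceSlope)$window, 20L)
})

test_that("stopping criteria fire in order: tol beats max-iter and slope", {
    sim <- genMonoexpVolume(shape = c(4, 4, 4), snr = 50, seed = 40)
    fit <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
                       options = fitOptions(iteration = 50, tol = 1e12))
    expect_identical(terminationReason(fit), "tol")
    expect_identical(fit@iterations, 1L)
    fit2 <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
                        options = fitOptions(iteration = 5, convergenceValue = 0))
    expect_identical(terminationReason(fit2), "max_iter")
    expect_length(lossHistory(fit2), 5)
})

test_that("gradient fit recovers a noiseless mono-exponential volume", {
    sim <- genMonoexpVolume(shape = c(6, 6, 6), snr = 1e9, seed = 41)
    fit <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
                       options = fitOptions(initialLearnRate = 0.01, iteration = 8000,
                                            lossFunction = "l2", convergenceValue = 0))
    m <- sim$mask
    for (p in c("S0", "R2star")) {
        rel <- abs(parameterMaps(fit)[[p]][m] - sim$truth[[p]][m]) / sim$truth[[p]][m]
        expect_lt(max(rel), 5e-3)
    }
    # loss history finite, and decreasing overall on noiseless input
    expect_true(all(is.finite(lossHistory(fit))))
    expect_lt(tail(lossHistory(fit), 1), lossHistory(fit)[1])
    # final maps respect the bounds (validity of the ParameterMaps object)
    expect_true(validObject(parameterMaps(fit)))
})

test_that("memory-optimised and full-volume evaluation give the same fit", {
    sim <- genMonoexpVolume(shape = c(4, 4, 4), snr = 100, seed = 42)
    o1 <- fitOptions(initialLearnRate = 0.02, iteration = 300, convergenceValue = 0,
                     isOptimiseMemory = TRUE)
    o2 <- fitOptions(initialLearnRate = 0.02, iteration = 300, convergenceValue = 0,
                     isOptimiseMemory = FALSE)
    f1 <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid, options = o1)
    f2 <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid, options = o2)
    expect_equal(lossHistory(f1), lossHistory(f2), tolerance = 1e-12)
    expect_equal(parameterMaps(f1)[["R2star"]], parameterMaps(f2)[["R2star"]],
                 tolerance = 1e-10)
})

test_that("uniformly doubling the weights leaves the argmin unchanged", {
    sim <- genMonoexpVolume(shape = c(4, 4, 4), snr = 50, seed = 43)
    o <- fitOptions(initialLearnRate = 0.01, iteration = 3000,
                    lossFunction = "l2", convergenceValue = 0)
    f1 <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
                      options = o)
    f2 <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask,
                      weights = array(2, dim(sim$signalNoisy)),
                      grid = sim$grid, options = o)
    m <- sim$mask
    for (p in c("S0", "R2star"))
        expect_equal(parameterMaps(f1)[[p]][m], parameterMaps(f2)[[p]][m],
                     tolerance = 2e-3)
})

test_that("single-voxel gradient fit agrees with the NLLS oracle optimum", {
    sim <- genMonoexpVolume(shape = c(4, 4, 4), snr = 50, seed = 5)
    m1 <- array(FALSE, c(4, 4, 4)); m1[2, 2, 2] <- TRUE
    fit <- fitGradient("monoexp_r2s", sim$signalNoisy, m1, grid = sim$grid,
                       options = fitOptions(initialLearnRate = 0.002, iteration = 30000,
                                            lossFunction = "l2", convergenceValue = 0))
    orc <- nllsOracle("monoexp_r2s", sim$signalNoisy, m1, grid = sim$grid)
    for (p in c("S0", "R2star")) {
        rel <- abs(parameterMaps(fit)[[p]][2, 2, 2] - orc$maps[[p]][2, 2, 2]) /
            abs(orc$maps[[p]][2, 2, 2])
        expect_lt(rel, 1e-4)
    }
})

test_that("shape-mismatched models fail before iteration 1", {
    bad <- forwardModel("bad_shape", "a", c(a = 0), c(a = 1),
                        fun = function(theta, grid) theta$a)  # drops the echo dim
    sim <- genMonoexpVolume(shape = c(3, 3, 3), snr = 100, seed = 44)
    expect_error(fitGradient(bad, sim$signalNoisy, sim$mask, grid = sim$grid),
                 "elements")
})

test_that("surface fit with graph TV runs in list layout and lowers roughness", {
    set.seed(45)
    nV <- 60
    edges <- cbind(1:(nV - 1), 2:nV)                     # a chain graph
    adj <- graphAdjacency(edges)
    truth <- rep(c(0.02, 0.05), each = nV / 2)           # two flat segments
    t <- seq(2, 24, by = 2)
    sig <- monoexpSignal(rep(1000, nV), truth, t)
    sigN <- sig + array(rnorm(length(sig), sd = 30), dim(sig))
    o <- fitOptions(initialLearnRate = 0.01, iteration = 2000,
                    lossFunction = "l2", convergenceValue = 0)
    f0 <- fitGradient("monoexp_r2s", sigN, grid = acquisitionGrid(echo_times = t),
                      options = o, layout = "list")
    fr <- fitGradient("monoexp_r2s", sigN, grid = acquisitionGrid(echo_times = t),
                      options = o, layout = "list",
                      regularizers = graphTvTerm("R2star", lambda = 5e3, adjacency = adj))
    rough0 <- tvGraph(parameterMaps(f0)[["R2star"]], adj)
    roughR <- tvGraph(parameterMaps(fr)[["R2star"]], adj)
    expect_lt(roughR, rough0)
    rmse0 <- sqrt(mean((parameterMaps(f0)[["R2star"]] - truth)^2))
    rmseR <- sqrt(mean((parameterMaps(fr)[["R2star"]] - truth)^2))
    expect_lt(rmseR, rmse0)
})
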