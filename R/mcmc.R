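#' @include core.R models.R
NULL

#' Options for the stochastic inference sampler
#'
#' @param algorithm `"mh"` (Metropolis-Hastings with independent chains per
#'   voxel) or `"ensemble"` (affine-invariant ensemble / stretch moves).
#' @param iteration chain length; defaults to 25000 for `"mh"` and 2000 for
#'   `"ensemble"`.
#' @param burnin ratio of initial iterations discarded, in `[0, 1)`.
#' @param thinning keep every `thinning`-th post-burn-in state (>= 1).
#' @param xStepSize per-parameter proposal standard deviation for `"mh"`
#'   (named vector or scalar); defaults to 5% of each parameter's bound
#'   range.
#' @param stepSize stretch parameter `a` of the ensemble move; the scale
#'   factor `z` is drawn with density proportional to `1/sqrt(z)` on
#'   `[1/a, a]`.
#' @param Nwalkers walker count for `"ensemble"` (even, >= 4).
#' @param nProposals number of independent MH chains per voxel.
#' @param noiseSd Gaussian likelihood standard deviation (scalar or per-voxel
#'   spatial map; required, > 0). Not sampled: fixing it keeps the
#'   likelihood identical across both algorithms. See
#'   [estimateNoiseSd()] for a residual-based helper.
#' @param walkerJitter ensemble walker initialisation spread as a fraction of
#'   the bound range (uniform jitter around the initial value, clipped inside
#'   the bounds); must be > 0 — identical walkers cannot move.
#' @param seed master seed; every voxel derives an independent substream from
#'   it in a documented order, making the vectorised samplers bit-identical
#'   to a sequential per-voxel reference.
#' @return a validated options list.
#' @export
mcmcOptions <- function(algorithm = c("mh", "ensemble"), iteration = NULL,
                        burnin = 0.1, thinning = 100L, xStepSize = NULL,
                        stepSize = 2, Nwalkers = 50L, nProposals = 4L,
                        noiseSd = NULL, walkerJitter = 0.01, seed = 1L) {
    algorithm <- match.arg(algorithm)
    if (is.null(iteration)) iteration <- if (algorithm == "mh") 25000L else 2000L
    iteration <- as.integer(iteration)
    if (iteration < 1L) stop("iteration must be at least 1")
    if (burnin < 0 || burnin >= 1) stop("burnin must lie in [0, 1)")
    thinning <- as.integer(thinning)
    if (thinning < 1L) stop("thinning must be a positive integer")
    Nwalkers <- as.integer(Nwalkers)
    if (algorithm == "ensemble" && (Nwalkers < 4L || Nwalkers %% 2L != 0L))
        stop("Nwalkers must be even and at least 4")
    if (stepSize <= 1) stop("stepSize (stretch parameter a) must exceed 1")
    if (!is.null(noiseSd) && any(noiseSd <= 0)) stop("noiseSd must be strictly positive")
    if (walkerJitter <= 0) stop("walkerJitter must be positive (identical walkers cannot move)")
    structure(list(algorithm = algorithm, iteration = iteration, burnin = burnin,
                   thinning = thinning, xStepSize = xStepSize, stepSize = stepSize,
                   Nwalkers = Nwalkers, nProposals = as.integer(nProposals),
                   noiseSd = noiseSd, walkerJitter = walkerJitter,
                   seed = as.integer(seed)),
              class = "mcmcOptions")
}

#' Burn-in / thinning retention schedule
#'
#' Per chain, the first `floor(burnin * iteration)` states are discarded and
#' every `thinning`-th of the remainder is kept, starting at offset
#' `thinning`: states `burn + thinning, burn + 2*thinning, ...`. The
#' per-chain count is therefore `floor(iteration * (1 - burnin) / thinning)`.
#'
#' @param iteration chain length.
#' @param burnin discarded initial ratio in `[0, 1)`.
#' @param thinning sampling interval (>= 1).
#' @param nChains independent chains or walkers multiplying the total.
#' @return list with `indices` (retained iteration numbers, per chain),
#'   `perChain` and `total` counts.
#' @examples
#' retainSchedule(25000, 0.1, 100, nChains = 4)$total   # 900
#' retainSchedule(2000, 0.1, 100, nChains = 50)$total   # 900
#' @export
retainSchedule <- function(iteration, burnin = 0.1, thinning = 100L, nChains = 1L) {
    if (burnin < 0 || burnin >= 1) stop("burnin must lie in [0, 1)")
    if (thinning < 1L) stop("thinning must be a positive integer")
    burn <- floor(burnin * iteration)
    if (burn + thinning > iteration)
        stop("no samples retained: decrease burnin/thinning or increase iteration")
    idx <- seq.int(burn + thinning, iteration, by = thinning)
    list(indices = as.integer(idx), perChain = length(idx),
         total = length(idx) * as.integer(nChains))
}

#' Per-voxel Gaussian log-likelihood
#'
#' `-sum_m |r_vm|^2 / (2 sigma_v^2)` per voxel (row), additive constants
#' dropped, with residual `r = measured - predicted`.
#'
#' @param measured,predicted matrices `(n_voxels, n_measurements)`.
#' @param sigma noise SD, scalar or per-voxel vector, strictly positive.
#' @return numeric vector, one value per voxel; 0 at zero residual.
#' @export
logLikelihoodGaussian <- function(measured, predicted, sigma) {
    if (any(sigma <= 0)) stop("sigma must be strictly positive")
    r <- measured - predicted
    if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
    -rowSums(Mod(r)^2) / (2 * sigma^2)
}

# independent, documented per-voxel substream seeds below 2^31
.voxelSeeds <- function(seed, nVoxels) {
    as.integer((as.double(seed) + 1000003 * seq_len(nVoxels)) %% 2147483629)
}

# ---- Metropolis-Hastings ----------------------------------------------------
#
# Random-number consumption order per voxel (from its substream seed):
#   1. proposal normals, array (n_params, n_chains, n_iterations)
#   2. acceptance uniforms, array (n_chains, n_iterations)
# Both the vectorised engine and the sequential per-voxel reference draw in
# exactly this order, which is what makes them bit-identical.

.mhDraws <- function(seedV, np, nchain, niter) {
    set.seed(seedV)
    list(P = array(stats::rnorm(np * nchain * niter), c(np, nchain, niter)),
         U = array(stats::runif(nchain * niter), c(nchain, niter)))
}

.mhVectorised <- function(model, grid, Y, sigma, theta0, lb, ub, xStep,
                          nchain, niter, sched, seeds) {
    nv <- nrow(Y); nm <- ncol(Y); np <- length(lb); pn <- names(lb)
    P <- array(0, c(np, nchain, niter, nv))
    U <- array(0, c(nchain, niter, nv))
    for (v in seq_len(nv)) {
        d <- .mhDraws(seeds[v], np, nchain, niter)
        P[, , , v] <- d$P
        U[, , v] <- d$U
    }
    Yrep <- Y[rep(seq_len(nv), times = nchain), , drop = FALSE]
    sigrep <- rep(rep_len(sigma, nv), times = nchain)
    evalLL <- function(th) {
        tl <- lapply(seq_len(np), function(p) as.vector(th[, , p]))
        names(tl) <- pn
        pred <- model@fun(tl, grid)
        dim(pred) <- c(nv * nchain, nm)
        matrix(logLikelihoodGaussian(Yrep, pred, sigrep), nv, nchain)
    }
    theta <- array(0, c(nv, nchain, np))
    for (p in seq_len(np)) theta[, , p] <- theta0[, p]
    ll <- evalLL(theta)
    Rper <- sched$perChain
    samples <- array(0, c(nv, np, Rper * nchain))
    accCount <- matrix(0, nv, nchain)
    ri <- 0L
    retain <- logical(niter); retain[sched$indices] <- TRUE
    for (t in seq_len(niter)) {
        prop <- theta
        inb <- matrix(TRUE, nv, nchain)
        for (p in seq_len(np)) {
            pP <- matrix(P[p, , t, ], nchain, nv)
            prop[, , p] <- matrix(theta[, , p], nv, nchain) + xStep[p] * t(pP)
            pm <- matrix(prop[, , p], nv, nchain)
            inb <- inb & pm >= lb[p] & pm <= ub[p]
        }
        propEval <- prop
        for (p in seq_len(np))
            propEval[, , p] <- pmin(pmax(prop[, , p], lb[p]), ub[p])
        llp <- evalLL(propEval)
        lu <- log(t(matrix(U[, t, ], nchain, nv)))
        acc <- inb & (lu < (llp - ll))
        for (p in seq_len(np)) {
            cur <- matrix(theta[, , p], nv, nchain)
            new <- matrix(prop[, , p], nv, nchain)
            cur[acc] <- new[acc]
            theta[, , p] <- cur
        }
        ll[acc] <- llp[acc]
        accCount <- accCount + acc
        if (t == 1000L && all(accCount == 0))
            warning(sprintf("no proposal accepted in the first 1000 iterations (acceptance 0 for all %d chains); consider smaller xStepSize (currently %s)",
                            nchain, paste(signif(xStep, 3), collapse = ", ")))
        if (retain[t]) {
            ri <- ri + 1L
            slots <- ri + (seq_len(nchain) - 1L) * Rper
            for (p in seq_len(np)) samples[, p, slots] <- theta[, , p]
        }
    }
    list(samples = samples, acceptance = accCount / niter,
         chainId = rep(seq_len(nchain), each = Rper))
}

# sequential per-voxel reference: same substreams and consumption order,
# but a plain loop over voxels, iterations and chains
.mhSequential <- function(model, grid, Y, sigma, theta0, lb, ub, xStep,
                          nchain, niter, sched, seeds) {
    nv <- nrow(Y); nm <- ncol(Y); np <- length(lb); pn <- names(lb)
    sigma <- rep_len(sigma, nv)
    Rper <- sched$perChain
    samples <- array(0, c(nv, np, Rper * nchain))
    accCount <- matrix(0, nv, nchain)
    retain <- logical(niter); retain[sched$indices] <- TRUE
    for (v in seq_len(nv)) {
        d <- .mhDraws(seeds[v], np, nchain, niter)
        yv <- Y[v, , drop = FALSE]
        llOf <- function(thv) {
            tl <- as.list(thv); names(tl) <- pn
            pred <- model@fun(tl, grid)
            dim(pred) <- c(1L, nm)
            logLikelihoodGaussian(yv, pred, sigma[v])
        }
        th <- matrix(theta0[v, ], nchain, np, byrow = TRUE)
        ll <- numeric(nchain)
        for (cc in seq_len(nchain)) ll[cc] <- llOf(th[cc, ])
        ri <- 0L
        for (t in seq_len(niter)) {
            for (cc in seq_len(nchain)) {
                prop <- th[cc, ] + xStep * d$P[, cc, t]
                inb <- all(prop >= lb & prop <= ub)
                propEval <- pmin(pmax(prop, lb), ub)
                llp <- llOf(propEval)
                if (inb && log(d$U[cc, t]) < (llp - ll[cc])) {
                    th[cc, ] <- prop
                    ll[cc] <- llp
                    accCount[v, cc] <- accCount[v, cc] + 1
                }
            }
            if (retain[t]) {
                ri <- ri + 1L
                for (cc in seq_len(nchain))
                    samples[v, , ri + (cc - 1L) * Rper] <- th[cc, ]
            }
        }
    }
    list(samples = samples, acceptance = accCount / niter,
         chainId = rep(seq_len(nchain), each = Rper))
}

# ---- affine-invariant ensemble ---------------------------------------------
#
# Random-number consumption order per voxel:
#   1. walker-initialisation uniforms, array (n_params, n_walkers)
#   2. per iteration, per half (first then second), three blocks of
#      n_walkers/2 uniforms each: stretch draws, partner draws, acceptance
#      draws — i.e. one array (K/2, 3, 2, n_iterations) filled column-major.

.ensembleDraws <- function(seedV, np, K, niter) {
    Kh <- K %/% 2L
    set.seed(seedV)
    list(jit = array(stats::runif(np * K), c(np, K)),
         rnd = array(stats::runif(Kh * 3L * 2L * niter), c(Kh, 3L, 2L, niter)))
}

.ensembleRun <- function(model, grid, Y, sigma, theta0, lb, ub, a, K,
                         niter, sched, seeds, jitterFrac) {
    nv <- nrow(Y); nm <- ncol(Y); np <- length(lb); pn <- names(lb)
    Kh <- K %/% 2L
    JIT <- array(0, c(np, K, nv))
    RND <- array(0, c(Kh, 3L, 2L, niter, nv))
    for (v in seq_len(nv)) {
        d <- .ensembleDraws(seeds[v], np, K, niter)
        JIT[, , v] <- d$jit
        RND[, , , , v] <- d$rnd
    }
    rng <- ub - lb
    X <- array(0, c(nv, K, np))
    for (p in seq_len(np)) {
        jit <- (t(matrix(JIT[p, , ], K, nv)) - 0.5) * 2 * jitterFrac * rng[p]
        x0 <- theta0[, p] + jit
        X[, , p] <- pmin(pmax(x0, lb[p] + 1e-9 * rng[p]), ub[p] - 1e-9 * rng[p])
    }
    for (p in seq_len(np)) {
        spread <- apply(X[, , p, drop = FALSE], 1, function(x) diff(range(x)))
        if (any(spread == 0))
            stop("all walkers identical for some voxel: the stretch move cannot explore; increase walkerJitter")
    }
    sigv <- rep_len(sigma, nv)
    evalLLHalf <- function(th) {  # th: (nv, Kh, np)
        tl <- lapply(seq_len(np), function(p) as.vector(th[, , p]))
        names(tl) <- pn
        pred <- model@fun(tl, grid)
        dim(pred) <- c(nv * Kh, nm)
        Yrep <- Y[rep(seq_len(nv), times = Kh), , drop = FALSE]
        matrix(logLikelihoodGaussian(Yrep, pred, rep(sigv, times = Kh)), nv, Kh)
    }
    ll <- matrix(0, nv, K)
    ll[, seq_len(Kh)] <- evalLLHalf(X[, seq_len(Kh), , drop = FALSE])
    ll[, Kh + seq_len(Kh)] <- evalLLHalf(X[, Kh + seq_len(Kh), , drop = FALSE])
    Rper <- sched$perChain
    samples <- array(0, c(nv, np, Rper * K))
    accCount <- matrix(0, nv, K)
    retain <- logical(niter); retain[sched$indices] <- TRUE
    ri <- 0L
    halves <- list(seq_len(Kh), Kh + seq_len(Kh))
    vIdx <- rep(seq_len(nv), times = Kh)
    for (t in seq_len(niter)) {
        for (h in 1:2) {
            mov <- halves[[h]]; oth <- halves[[3L - h]]
            uz <- t(matrix(RND[, 1L, h, t, ], Kh, nv))
            uj <- t(matrix(RND[, 2L, h, t, ], Kh, nv))
            ua <- t(matrix(RND[, 3L, h, t, ], Kh, nv))
            z <- ((a - 1) * uz + 1)^2 / a
            j <- pmin(floor(uj * Kh) + 1L, Kh)
            prop <- array(0, c(nv, Kh, np))
            inb <- matrix(TRUE, nv, Kh)
            Xoth <- X[, oth, , drop = FALSE]
            for (p in seq_len(np)) {
                Xj <- matrix(Xoth[cbind(vIdx, as.vector(j), p)], nv, Kh)
                pr <- Xj + z * (matrix(X[, mov, p], nv, Kh) - Xj)
                prop[, , p] <- pr
                inb <- inb & pr >= lb[p] & pr <= ub[p]
            }
            propEval <- prop
            for (p in seq_len(np))
                propEval[, , p] <- pmin(pmax(prop[, , p], lb[p]), ub[p])
            llp <- evalLLHalf(propEval)
            logacc <- (np - 1) * log(z) + llp - matrix(ll[, mov], nv, Kh)
            acc <- inb & (log(ua) < logacc)
            for (p in seq_len(np)) {
                cur <- matrix(X[, mov, p], nv, Kh)
                new <- matrix(prop[, , p], nv, Kh)
                cur[acc] <- new[acc]
                X[, mov, p] <- cur
            }
            llm <- matrix(ll[, mov], nv, Kh); llm[acc] <- llp[acc]; ll[, mov] <- llm
            accCount[, mov] <- accCount[, mov] + acc
        }
        if (retain[t]) {
            ri <- ri + 1L
            slots <- ri + (seq_len(K) - 1L) * Rper
            for (p in seq_len(np)) samples[, p, slots] <- X[, , p]
        }
    }
    list(samples = samples, acceptance = accCount / niter,
         chainId = rep(seq_len(K), each = Rper))
}

#' Sample model parameters with a vectorised MCMC sampler
#'
#' Draws from the posterior of the model parameters per masked voxel under a
#' Gaussian likelihood with fixed noise SD and a bound-truncated uniform
#' prior (any proposal with a parameter outside its box bounds is rejected).
#' Two algorithms are available: Metropolis-Hastings with `nProposals`
#' independent chains per voxel and a symmetric normal proposal of SD
#' `xStepSize` per parameter, and the affine-invariant ensemble sampler with
#' `Nwalkers` walkers updated half-by-half through stretch moves with
#' acceptance factor `z^(d-1) * likelihood ratio`. All voxels and chains
#' advance in lockstep, vectorised; each voxel consumes an independent,
#' seed-derived random substream in a documented order, so the output is
#' bit-identical to a sequential per-voxel reference run.
#'
#' Burn-in and thinning follow [retainSchedule()]; with the settings
#' 4 chains x 25000 iterations (or 50 walkers x 2000 iterations), 10%
#' burn-in and thinning 100, exactly 900 samples are retained per voxel.
#'
#' @inheritParams fitGradient
#' @param options an [mcmcOptions()] list; `noiseSd` is required.
#' @return a [ChainStore-class]; summarise with [summarizeChains()].
#' @examples
#' toy <- genGaussianToy(nObs = 20, thetaTrue = 1, sigma = 1, nVoxels = 2, seed = 1)
#' ch <- fitMCMC(toy$model, toy$signal, grid = toy$grid,
#'               options = mcmcOptions("mh", iteration = 500, thinning = 5,
#'                                     noiseSd = 1, seed = 7), layout = "list")
#' summarizeChains(ch)
#' @export
fitMCMC <- function(model, signal, mask = NULL, grid = NULL, init = NULL,
                    bounds = NULL, options, layout = c("volume", "list")) {
    layout <- match.arg(layout)
    model <- .resolveModel(model)
    stopifnot(inherits(options, "mcmcOptions"))
    if (is.null(options$noiseSd)) stop("options$noiseSd is required (Gaussian likelihood SD)")
    bundle <- validateInputs(signal, mask, NULL, grid, layout)
    pn <- model@parameters; np <- length(pn)
    lb <- if (!is.null(bounds)) bounds$lower[pn] else model@lower
    ub <- if (!is.null(bounds)) bounds$upper[pn] else model@upper
    nv <- bundle$nVoxels; nm <- prod(bundle$measDim)
    Y <- gatherVoxels(bundle$signal, bundle$mask); dim(Y) <- c(nv, nm)
    sigma <- options$noiseSd
    if (length(sigma) > 1L) sigma <- gatherVoxels(array(sigma, bundle$spatialDim), bundle$mask)
    theta0 <- matrix(0, nv, np, dimnames = list(NULL, pn))
    for (p in pn) {
        v <- if (!is.null(init) && !is.null(init[[p]])) init[[p]] else model@init[[p]]
        theta0[, p] <- if (length(v) == 1L) rep(v, nv)
                       else gatherVoxels(array(v, bundle$spatialDim), bundle$mask)
        theta0[, p] <- pmin(pmax(theta0[, p], lb[[p]] + 1e-9 * (ub[[p]] - lb[[p]])),
                            ub[[p]] - 1e-9 * (ub[[p]] - lb[[p]]))
    }
    seeds <- .voxelSeeds(options$seed, nv)
    if (options$algorithm == "mh") {
        xStep <- options$xStepSize
        if (is.null(xStep)) xStep <- 0.05 * (ub - lb)
        xStep <- rep_len(xStep, np); names(xStep) <- pn
        if (!is.null(names(options$xStepSize)) && all(pn %in% names(options$xStepSize)))
            xStep <- options$xStepSize[pn]
        sched <- retainSchedule(options$iteration, options$burnin, options$thinning,
                                options$nProposals)
        run <- .mhVectorised(model, bundle$grid, Y, sigma, theta0, lb, ub, xStep,
                             options$nProposals, options$iteration,
                             retainSchedule(options$iteration, options$burnin, options$thinning),
                             seeds)
        nChains <- options$nProposals
    } else {
        if (options$Nwalkers < 2L * np)
            warning(sprintf("Nwalkers (%d) below twice the parameter count (%d): degenerate ensemble geometry",
                            options$Nwalkers, np))
        sched <- retainSchedule(options$iteration, options$burnin, options$thinning,
                                options$Nwalkers)
        run <- .ensembleRun(model, bundle$grid, Y, sigma, theta0, lb, ub,
                            options$stepSize, options$Nwalkers, options$iteration,
                            retainSchedule(options$iteration, options$burnin, options$thinning),
                            seeds, options$walkerJitter)
        nChains <- options$Nwalkers
    }
    new("ChainStore", samples = run$samples, parameters = pn,
        chainId = as.integer(run$chainId), algorithm = options$algorithm,
        lower = lb, upper = ub, acceptance = run$acceptance,
        seed = options$seed)
}

#' Summarise retained posterior samples
#'
#' Per-voxel, per-parameter sample mean, unbiased (n-1) standard deviation
#' and interquartile range of the retained draws — the posterior point
#' estimate and uncertainty maps.
#'
#' @param chains a [ChainStore-class] with at least 2 retained samples per
#'   voxel.
#' @return a [PosteriorSummary-class].
#' @export
summarizeChains <- function(chains) {
    stopifnot(methods::is(chains, "ChainStore"))
    s <- chains@samples
    d <- dim(s)
    if (d[3] < 2L) stop("at least 2 retained samples per voxel are required")
    pn <- chains@parameters
    mu <- list(); sd <- list(); iqr <- list()
    for (p in seq_along(pn)) {
        x <- matrix(s[, p, ], d[1], d[3])
        m <- rowMeans(x)
        v <- rowSums((x - m)^2) / (d[3] - 1L)
        mu[[pn[p]]] <- m
        sd[[pn[p]]] <- sqrt(v)
        iqr[[pn[p]]] <- apply(x, 1L, function(r) diff(stats::quantile(r, c(0.25, 0.75), names = FALSE)))
    }
    new("PosteriorSummary", mean = mu, sd = sd, iqr = iqr, parameters = pn)
}

#' Estimate the likelihood noise SD from a quick least-squares pre-fit
#'
#' Optional helper for choosing `noiseSd`: runs the per-voxel bounded NLLS
#' reference and returns the SD of its residuals, pooled over all masked
#' voxels and measurements.
#'
#' @inheritParams fitGradient
#' @return scalar residual SD.
#' @export
estimateNoiseSd <- function(model, signal, mask = NULL, grid, init = NULL,
                            bounds = NULL, layout = c("volume", "list")) {
    layout <- match.arg(layout)
    model <- .resolveModel(model)
    fit <- nllsOracle(model, signal, mask, grid, init, bounds, layout)
    bundle <- validateInputs(signal, mask, NULL, grid, layout)
    nv <- bundle$nVoxels; nm <- prod(bundle$measDim)
    Y <- gatherVoxels(bundle$signal, bundle$mask); dim(Y) <- c(nv, nm)
    tl <- lapply(model@parameters, function(p) gatherVoxels(array(fit$maps[[p]], bundle$spatialDim), bundle$mask))
    names(tl) <- model@parameters
    pred <- model@fun(tl, bundle$grid); dim(pred) <- c(nv, nm)
    stats::sd(as.vector(Y - pred))
}
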