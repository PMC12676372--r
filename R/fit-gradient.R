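#' @include core.R models.R regularizers.R
NULL

#' Options for the whole-volume gradient solver
#'
#' @param optimizer `"adam"`, `"sgdm"` or `"rmsprop"`.
#' @param initialLearnRate step size of the parameter update (in the
#'   unconstrained space; > 0).
#' @param iteration maximum number of iterations (>= 1).
#' @param tol stop when the loss falls below this threshold (0 disables).
#' @param convergenceValue stop when the absolute slope of the loss over the
#'   last `convergenceWindow` iterations falls below this value.
#' @param convergenceWindow window length for the loss-slope criterion
#'   (> 1; default 20, robust to small loss fluctuations).
#' @param lossFunction `"l1"` or `"l2"` data loss.
#' @param isOptimiseMemory when `TRUE` (default), parameters are gathered to
#'   the masked voxels before the forward evaluation, restricting computation
#'   (and memory) to the mask; they are scattered back to the volume each
#'   iteration whenever spatial regularisation needs the native shape.
#' @param beta1,beta2,epsilon Adam constants.
#' @param momentum SGDM momentum constant.
#' @param decay RMSProp squared-gradient decay constant.
#' @return a validated options list.
#' @export
fitOptions <- function(optimizer = c("adam", "sgdm", "rmsprop"),
                       initialLearnRate = 0.001, iteration = 4000L, tol = 0,
                       convergenceValue = 1e-8, convergenceWindow = 20L,
                       lossFunction = c("l1", "l2"), isOptimiseMemory = TRUE,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       momentum = 0.9, decay = 0.9) {
    optimizer <- match.arg(optimizer)
    lossFunction <- match.arg(lossFunction)
    if (iteration < 1L) stop("iteration must be at least 1")
    if (convergenceWindow <= 1L) stop("convergenceWindow must be greater than 1")
    if (initialLearnRate <= 0) stop("initialLearnRate must be positive")
    structure(list(optimizer = optimizer, initialLearnRate = initialLearnRate,
                   iteration = as.integer(iteration), tol = tol,
                   convergenceValue = convergenceValue,
                   convergenceWindow = as.integer(convergenceWindow),
                   lossFunction = lossFunction, isOptimiseMemory = isOptimiseMemory,
                   beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                   momentum = momentum, decay = decay),
              class = "fitOptions")
}

#' Masked data-fidelity loss
#'
#' Aggregates all voxels within the mask into one scalar: the mean over
#' masked signal elements of `|W * r|` (`"l1"`) or `(W * r)^2` (`"l2"`),
#' with residual `r = measured - predicted`; complex residuals use the
#' complex modulus. The mean (not sum) normalisation makes `tol` and the
#' regularisation weights insensitive to mask size.
#'
#' @param measured,predicted arrays of one shape (real or complex).
#' @param mask logical array over the leading spatial dims, or `NULL`.
#' @param weights nonnegative array broadcastable to the signal, or `NULL`.
#' @param norm `"l1"` or `"l2"`.
#' @return nonnegative scalar.
#' @export
dataLoss <- function(measured, predicted, mask = NULL, weights = NULL,
                     norm = c("l1", "l2")) {
    norm <- match.arg(norm)
    d <- .dimOf(measured)
    if (!identical(as.integer(.dimOf(predicted)), as.integer(d)))
        stop("measured and predicted shapes differ")
    keep <- .maskElements(mask, d)
    if (!any(keep)) stop("mask selects no elements")
    w <- if (is.null(weights)) 1 else .expandLike(weights, d)
    r <- (measured - predicted)[keep]
    wr <- if (is.null(weights)) r else w[keep] * r
    if (norm == "l1") mean(Mod(wr)) else mean(Mod(wr)^2)
}

# expand mask over spatial dims to element selection over the full shape
.maskElements <- function(mask, d) {
    if (is.null(mask)) return(rep(TRUE, prod(d)))
    dm <- .dimOf(mask)
    ns <- length(dm)
    if (!identical(as.integer(d[seq_len(ns)]), as.integer(dm)))
        stop("mask shape does not match the signal's leading dimensions")
    rep(as.vector(mask), times = max(1L, prod(d[-seq_len(ns)])))
}

.expandLike <- function(x, d) {
    if (length(x) == 1L) return(array(as.vector(x), d))
    dx <- .dimOf(x)
    if (identical(as.integer(dx), as.integer(d))) return(x)
    if (prod(dx) < prod(d) && prod(d) %% prod(dx) == 0L)
        return(array(rep(as.vector(x), times = prod(d) / prod(dx)), d))
    stop("weights are not broadcastable to the signal shape")
}

#' Single optimiser update steps
#'
#' One update of the unconstrained parameters given a gradient, for the three
#' supported first-order optimisers. `adamStep()` applies the bias-corrected
#' Adam recurrence `m <- b1 m + (1-b1) g`, `v <- b2 v + (1-b2) g^2`,
#' `z <- z - lr * mhat / (sqrt(vhat) + eps)`. `sgdmStep()` uses classical
#' momentum `v <- momentum v + g`, `z <- z - lr v` (plain gradient descent at
#' `momentum = 0`). `rmspropStep()` uses `v <- decay v + (1-decay) g^2`,
#' `z <- z - lr g / (sqrt(v) + eps)`. Pass `state = NULL` on the first call.
#'
#' @param z current unconstrained parameter array.
#' @param grad gradient array shaped like `z` (must be finite).
#' @param state accumulator list from the previous call, or `NULL`.
#' @param lr learning rate.
#' @param beta1,beta2,epsilon,momentum,decay optimiser constants.
#' @return list with updated `z` and `state`.
#' @export
adamStep <- function(z, grad, state = NULL, lr = 0.001, beta1 = 0.9,
                     beta2 = 0.999, epsilon = 1e-8) {
    if (is.null(state)) state <- list(m = z * 0, v = z * 0, t = 0L)
    t <- state$t + 1L
    m <- beta1 * state$m + (1 - beta1) * grad
    v <- beta2 * state$v + (1 - beta2) * grad^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(z = z - lr * mhat / (sqrt(vhat) + epsilon),
         state = list(m = m, v = v, t = t))
}

#' @rdname adamStep
#' @export
sgdmStep <- function(z, grad, state = NULL, lr = 0.001, momentum = 0.9) {
    if (is.null(state)) state <- list(v = z * 0)
    v <- momentum * state$v + grad
    list(z = z - lr * v, state = list(v = v))
}

#' @rdname adamStep
#' @export
rmspropStep <- function(z, grad, state = NULL, lr = 0.001, decay = 0.9,
                        epsilon = 1e-8) {
    if (is.null(state)) state <- list(v = z * 0)
    v <- decay * state$v + (1 - decay) * grad^2
    list(z = z - lr * grad / (sqrt(v) + epsilon),
         state = list(v = v))
}

.optimStep <- function(opts) {
    switch(opts$optimizer,
           adam = function(z, g, st) adamStep(z, g, st, opts$initialLearnRate,
                                              opts$beta1, opts$beta2, opts$epsilon),
           sgdm = function(z, g, st) sgdmStep(z, g, st, opts$initialLearnRate,
                                              opts$momentum),
           rmsprop = function(z, g, st) rmspropStep(z, g, st, opts$initialLearnRate,
                                                    opts$decay, opts$epsilon))
}

#' Slope of the loss over a trailing window
#'
#' Ordinary-least-squares slope of loss versus iteration index over the last
#' `window` entries, used as the convergence criterion: optimisation stops
#' when `|slope| < convergenceValue`. Returns `NA` (not yet evaluable,
#' treated as not converged) while the history is shorter than the window.
#'
#' @param lossHistory numeric vector of per-iteration loss values.
#' @param window window length (> 1; default 20).
#' @return slope in loss units per iteration, or `NA_real_`.
#' @export
convergenceSlope <- function(lossHistory, window = 20L) {
    if (window <= 1L) stop("window must be greater than 1")
    n <- length(lossHistory)
    if (n < window) return(NA_real_)
    y <- lossHistory[(n - window + 1L):n]
    x <- seq_len(window)
    xc <- x - mean(x)
    sum(xc * (y - mean(y))) / sum(xc^2)
}

# dL/dpredicted for the masked-mean losses (real signals), as a full array
.dataLossGradPred <- function(residual, keep, w, norm, n) {
    # residual = predicted - measured (note sign), already weighted outside
    g <- array(0, .dimOf(residual))
    if (norm == "l1") g[keep] <- (w * sign(residual))[keep] / n
    else g[keep] <- (2 * w^2 * residual)[keep] / n
    g
}

#' Fit a forward model to a whole volume by gradient descent
#'
#' Minimises one global objective over every masked voxel simultaneously:
#' the masked mean `"l1"`/`"l2"` misfit between measured and predicted
#' signals plus any weighted regularisation terms, with box bounds enforced
#' through the scaled-logit transform (gradients are taken in the
#' unconstrained space). Each iteration evaluates the forward model for all
#' voxels at once, backpropagates exact gradients (analytic model Jacobian
#' when available, vectorised central differences otherwise; analytic
#' gradients for the data loss and built-in regularisers), takes one
#' optimiser step, and then checks the stopping criteria in the order
#' loss-below-`tol`, maximum iterations, loss-slope convergence.
#'
#' @param model a [ForwardModel-class] or registered model name.
#' @param signal measured data; in `"volume"` layout the first 3 dims are
#'   spatial, in `"list"` layout the first dim indexes samples.
#' @param mask logical spatial array (`NULL`: all voxels).
#' @param weights optional nonnegative weights broadcastable to the signal.
#' @param grid an [AcquisitionGrid-class] or named list.
#' @param init named list/vector of initial values (scalar or per-voxel),
#'   strictly inside the bounds; defaults to the model's initialisation
#'   (bound midpoints unless the model states otherwise).
#' @param bounds optional named list with `lower`/`upper` vectors overriding
#'   the model's default bounds.
#' @param options a [fitOptions()] list.
#' @param regularizers a [composeRegularizers()] object, a single term, or a
#'   list of terms; evaluated on the parameter maps in their native shape
#'   (scattered back to the volume when `isOptimiseMemory` gathers).
#' @param layout `"volume"` or `"list"`.
#' @return a [FitResult-class]; final maps are `NA` outside the mask.
#' @examples
#' sim <- genMonoexpVolume(shape = c(6, 6, 6), snr = 1e9, seed = 1)
#' fit <- fitGradient("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid,
#'                    options = fitOptions(initialLearnRate = 0.05, iteration = 600))
#' terminationReason(fit)
#' @export
fitGradient <- function(model, signal, mask = NULL, weights = NULL, grid,
                        init = NULL, bounds = NULL, options = fitOptions(),
                        regularizers = NULL, layout = c("volume", "list")) {
    layout <- match.arg(layout)
    model <- .resolveModel(model)
    bundle <- validateInputs(signal, mask, weights, grid, layout)
    opts <- options
    pn <- model@parameters
    np <- length(pn)
    lb <- if (!is.null(bounds)) bounds$lower[pn] else model@lower
    ub <- if (!is.null(bounds)) bounds$upper[pn] else model@upper
    if (any(!is.finite(lb)) || any(!is.finite(ub)) || any(lb >= ub))
        stop("bounds must be finite with lower < upper for every parameter")

    mask <- bundle$mask
    nv <- bundle$nVoxels
    measDim <- bundle$measDim
    nm <- prod(measDim)
    Y <- gatherVoxels(bundle$signal, mask); dim(Y) <- c(nv, nm)
    Wfull <- gatherVoxels(bundle$weights, mask); dim(Wfull) <- c(nv, nm)

    reg <- if (is.null(regularizers)) NULL
           else if (inherits(regularizers, "regularizerSet")) regularizers
           else composeRegularizers(regularizers)
    if (!is.null(reg) && length(reg$terms) == 0L) reg <- NULL

    # initial values -> per-voxel matrix, strictly inside bounds
    theta0 <- matrix(0, nv, np, dimnames = list(NULL, pn))
    for (p in pn) {
        v <- if (!is.null(init) && !is.null(init[[p]])) init[[p]] else model@init[[p]]
        theta0[, p] <- if (length(v) == 1L) rep(v, nv) else gatherVoxels(array(v, bundle$spatialDim), mask)
    }
    z <- matrix(0, nv, np, dimnames = list(NULL, pn))
    for (p in pn) z[, p] <- toUnconstrained(theta0[, p], lb[[p]], ub[[p]])

    evalModel <- function(thetaList) {
        if (opts$isOptimiseMemory) {
            pred <- model@fun(thetaList, bundle$grid)
        } else {
            vols <- lapply(thetaList, scatterVoxels, mask = mask, fill = 0)
            pred <- model@fun(vols, bundle$grid)
            pred <- gatherVoxels(pred, mask)
        }
        pred
    }
    thetaList0 <- lapply(pn, function(p) fromUnconstrained(z[, p], lb[[p]], ub[[p]]))
    names(thetaList0) <- pn
    pred0 <- evalModel(thetaList0)
    if (length(pred0) != nv * nm)
        stop(sprintf("model '%s' returned %d elements for %d masked voxels x %d measurements",
                     model@name, length(pred0), nv, as.integer(nm)))

    jacOf <- function(thetaList, pred) {
        if (!is.null(model@jacobian)) {
            J <- if (opts$isOptimiseMemory) model@jacobian(thetaList, bundle$grid)
                 else lapply(model@jacobian(lapply(thetaList, scatterVoxels, mask = mask, fill = 0),
                                            bundle$grid),
                             gatherVoxels, mask = mask)
            lapply(J, function(j) { dim(j) <- c(nv, nm); j })
        } else {
            # central differences per parameter map: exact direction for
            # voxel-separable models, two forward evaluations per parameter
            J <- vector("list", np); names(J) <- pn
            for (p in pn) {
                h <- 1e-6 * (ub[[p]] - lb[[p]])
                tp <- thetaList; tp[[p]] <- pmin(thetaList[[p]] + h, ub[[p]])
                tm <- thetaList; tm[[p]] <- pmax(thetaList[[p]] - h, lb[[p]])
                hp <- tp[[p]] - tm[[p]]
                jp <- (evalModel(tp) - evalModel(tm))
                dim(jp) <- c(nv, nm)
                J[[p]] <- jp / hp
            }
            J
        }
    }

    step <- .optimStep(opts)
    state <- NULL
    loss <- numeric(opts$iteration)
    termination <- "max_iter"
    it <- 0L
    lastGood <- z

    repeat {
        it <- it + 1L
        thetaList <- lapply(pn, function(p) fromUnconstrained(z[, p], lb[[p]], ub[[p]]))
        names(thetaList) <- pn
        pred <- evalModel(thetaList); dim(pred) <- c(nv, nm)
        r <- pred - Y
        Ld <- if (opts$lossFunction == "l1") mean(abs(Wfull * r)) else mean((Wfull * r)^2)

        gpred <- .dataLossGradPred(r, rep(TRUE, length(r)), Wfull, opts$lossFunction, length(r))
        J <- jacOf(thetaList, pred)
        gtheta <- matrix(0, nv, np, dimnames = list(NULL, pn))
        for (p in pn) gtheta[, p] <- rowSums(gpred * J[[p]])

        Lr <- 0
        if (!is.null(reg)) {
            if (layout == "volume") {
                maps <- lapply(thetaList, scatterVoxels, mask = mask, fill = 0)
                Lr <- reg$value(maps, mask)
                gr <- reg$grad(maps, mask)
                for (p in names(gr)) gtheta[, p] <- gtheta[, p] + gatherVoxels(gr[[p]], mask)
            } else {
                maps <- lapply(thetaList, function(x) scatterVoxels(x, mask, fill = 0))
                Lr <- reg$value(maps, mask)
                gr <- reg$grad(maps, mask)
                for (p in names(gr)) gtheta[, p] <- gtheta[, p] + gatherVoxels(array(gr[[p]], .dimOf(mask)), mask)
            }
        }

        gz <- gtheta
        for (p in pn) gz[, p] <- gtheta[, p] * .boundTransformDeriv(z[, p], lb[[p]], ub[[p]])
        if (any(!is.finite(gz))) {
            bad <- pn[which(colSums(!is.finite(gz)) > 0)][1]
            stop(sprintf("non-finite gradient for parameter '%s' at iteration %d", bad, it))
        }

        L <- Ld + Lr
        loss[it] <- L
        if (!is.finite(L)) {
            warning(sprintf("non-finite loss at iteration %d; returning last good state", it))
            z <- lastGood
            termination <- "aborted"
            it <- it - 1L
            break
        }
        lastGood <- z
        upd <- step(z, gz, state)
        z <- upd$z; state <- upd$state

        if (L < opts$tol) { termination <- "tol"; break }
        if (it >= opts$iteration) { termination <- "max_iter"; break }
        sl <- convergenceSlope(loss[seq_len(it)], opts$convergenceWindow)
        if (!is.na(sl) && abs(sl) < opts$convergenceValue) { termination <- "converged"; break }
    }

    thetaFinal <- lapply(pn, function(p) fromUnconstrained(z[, p], lb[[p]], ub[[p]]))
    names(thetaFinal) <- pn
    maps <- if (layout == "volume")
        lapply(thetaFinal, scatterVoxels, mask = mask, fill = NA_real_)
    else lapply(thetaFinal, function(x) as.vector(scatterVoxels(x, mask, fill = NA_real_)))
    predF <- evalModel(thetaFinal); dim(predF) <- c(nv, nm)
    rF <- predF - Y
    LdF <- if (opts$lossFunction == "l1") mean(abs(Wfull * rF)) else mean((Wfull * rF)^2)
    new("FitResult",
        maps = parameterMapsList(maps, lb, ub),
        lossHistory = loss[seq_len(max(it, 1L))],
        dataLoss = LdF,
        termination = termination,
        iterations = as.integer(max(it, 1L)))
}
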