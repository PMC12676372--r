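#' @include AllClasses.R core.R
NULL

.modelRegistry <- new.env(parent = emptyenv())

#' Construct a forward signal model
#'
#' Wraps a deterministic prediction function into the contract both solvers
#' consume. The function receives `theta` (named list of parameter arrays of
#' any common shape) and an [AcquisitionGrid-class], and must return a signal
#' array whose leading dimension(s) equal the parameter shape and whose
#' trailing dimension(s) are the measurement dimensions — exactly the shape of
#' the measured data it will be compared against.
#'
#' @param name model name used in the registry and error messages.
#' @param parameters character vector of parameter names.
#' @param lower,upper named finite default bounds per parameter.
#' @param init named default initial values; defaults to the bound midpoints.
#' @param fun the prediction `function(theta, grid)`.
#' @param jacobian optional `function(theta, grid)` returning a named list of
#'   `d signal / d parameter` arrays shaped like the prediction. When absent,
#'   the gradient solver uses central differences per parameter (two forward
#'   evaluations each), which is exact in the voxel-separable limit.
#' @return a [ForwardModel-class].
#' @export
forwardModel <- function(name, parameters, lower, upper, init = NULL,
                         fun, jacobian = NULL) {
    if (is.null(init)) init <- (lower[parameters] + upper[parameters]) / 2
    new("ForwardModel", name = name, parameters = parameters,
        lower = lower[parameters], upper = upper[parameters],
        init = init[parameters], fun = fun, jacobian = jacobian)
}

#' Model registry
#'
#' Registered models are retrievable by name from both solvers and the
#' command-line interface. The built-ins `"monoexp_r2s"`, `"twopool_gre"` and
#' `"sense"` are registered when the package loads.
#'
#' @param model a [ForwardModel-class].
#' @param name model name.
#' @param overwrite replace an existing entry instead of erroring.
#' @return `registerModel()` returns the model invisibly; `getModel()` the
#'   registered [ForwardModel-class]; `listModels()` the registered names.
#' @examples
#' getModel("monoexp_r2s")
#' listModels()
#' @export
registerModel <- function(model, overwrite = FALSE) {
    stopifnot(methods::is(model, "ForwardModel"))
    if (!overwrite && !is.null(.modelRegistry[[model@name]]))
        stop(sprintf("a model named '%s' is already registered", model@name))
    assign(model@name, model, envir = .modelRegistry)
    invisible(model)
}

#' @rdname registerModel
#' @export
getModel <- function(name) {
    m <- .modelRegistry[[name]]
    if (is.null(m))
        stop(sprintf("no model named '%s' is registered (available: %s)",
                     name, paste(listModels(), collapse = ", ")))
    m
}

#' @rdname registerModel
#' @export
listModels <- function() sort(ls(.modelRegistry))

.resolveModel <- function(model) {
    if (is.character(model)) getModel(model) else {
        stopifnot(methods::is(model, "ForwardModel")); model
    }
}

#' Mono-exponential R2* decay signal
#'
#' The single-compartment gradient-echo relaxometry model
#' `S(t) = S0 * exp(-t * R2star)`, broadcast over all voxels and echoes.
#'
#' @param S0 equilibrium signal (scalar or array over voxels).
#' @param R2star effective transverse relaxation rate in 1/ms (same shape as
#'   `S0`).
#' @param t echo times in ms (nonnegative vector).
#' @return array of shape `(dim(S0), length(t))`; a vector when `S0` is
#'   scalar.
#' @examples
#' monoexpSignal(2, 0.05, 20)   # 2 * exp(-1)
#' @export
monoexpSignal <- function(S0, R2star, t) {
    if (any(t < 0)) stop("echo times t must be nonnegative")
    d <- .dimOf(S0)
    s <- as.vector(S0) * exp(-as.vector(R2star) %o% t)
    if (length(S0) == 1L) as.vector(s) else array(s, c(d, length(t)))
}

#' Two-pool gradient-echo signal
#'
#' A two-compartment relaxometry demo model:
#' `S(t) = S0 * (f * exp(-t * R2a) + (1 - f) * exp(-t * R2b))`,
#' with `f` the signal fraction of the fast-relaxing pool. Deliberately
#' ill-conditioned at low SNR, which is what spatial regularisation is for.
#'
#' @param S0 equilibrium signal.
#' @param f fast-pool signal fraction in `[0, 1]`.
#' @param R2a,R2b pool relaxation rates (1/ms), nonnegative.
#' @param t echo times in ms.
#' @return array of shape `(dim(S0), length(t))`.
#' @export
twopoolSignal <- function(S0, f, R2a, R2b, t) {
    if (any(t < 0)) stop("echo times t must be nonnegative")
    if (any(f < 0 | f > 1)) stop("pool fraction f must lie in [0, 1]")
    if (any(R2a < 0) || any(R2b < 0)) stop("relaxation rates must be nonnegative")
    d <- .dimOf(S0)
    ea <- exp(-as.vector(R2a) %o% t)
    eb <- exp(-as.vector(R2b) %o% t)
    s <- as.vector(S0) * (as.vector(f) * ea + (1 - as.vector(f)) * eb)
    if (length(S0) == 1L) as.vector(s) else array(s, c(d, length(t)))
}

.monoexpModel <- function() {
    forwardModel(
        name = "monoexp_r2s",
        parameters = c("S0", "R2star"),
        lower = c(S0 = 0, R2star = 1e-4),
        upper = c(S0 = 5000, R2star = 0.2),
        fun = function(theta, grid) monoexpSignal(theta$S0, theta$R2star, grid[["echo_times"]]),
        jacobian = function(theta, grid) {
            t <- grid[["echo_times"]]
            d <- .dimOf(theta$S0)
            dec <- exp(-as.vector(theta$R2star) %o% t)
            s <- as.vector(theta$S0) * dec
            tm <- matrix(t, nrow = length(theta$S0), ncol = length(t), byrow = TRUE)
            list(S0 = array(dec, c(d, length(t))),
                 R2star = array(-tm * s, c(d, length(t))))
        })
}

.twopoolModel <- function() {
    forwardModel(
        name = "twopool_gre",
        parameters = c("S0", "f", "R2a", "R2b"),
        lower = c(S0 = 0, f = 0, R2a = 0.04, R2b = 1e-4),
        upper = c(S0 = 5000, f = 1, R2a = 0.3, R2b = 0.04),
        init = c(S0 = 1000, f = 0.25, R2a = 0.1, R2b = 0.02),
        fun = function(theta, grid)
            twopoolSignal(theta$S0, theta$f, theta$R2a, theta$R2b, grid[["echo_times"]]),
        jacobian = function(theta, grid) {
            t <- grid[["echo_times"]]
            d <- .dimOf(theta$S0)
            nv <- length(theta$S0); nt <- length(t)
            S0 <- as.vector(theta$S0); f <- as.vector(theta$f)
            ea <- exp(-as.vector(theta$R2a) %o% t)
            eb <- exp(-as.vector(theta$R2b) %o% t)
            tm <- matrix(t, nrow = nv, ncol = nt, byrow = TRUE)
            sh <- c(d, nt)
            list(S0   = array(f * ea + (1 - f) * eb, sh),
                 f    = array(S0 * (ea - eb), sh),
                 R2a  = array(-S0 * f * tm * ea, sh),
                 R2b  = array(-S0 * (1 - f) * tm * eb, sh))
        })
}
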