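#' @include models.R sense.R
NULL

#' @keywords internal
"_PACKAGE"

#' @importFrom methods new is show validObject
#' @importFrom stats fft rnorm runif plogis qlogis
NULL

.onLoad <- function(libname, pkgname) {
    for (m in list(.monoexpModel(), .twopoolModel(), .senseModel()))
        if (is.null(.modelRegistry[[m@name]])) registerModel(m)
    invisible()
}
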