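#' @include AllClasses.R
NULL

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving data and orientation metadata.
#' Complex volumes (k-space, coil maps, reconstructed images) are stored as
#' a paired real/imaginary file set `<prefix>_real.nii.gz`,
#' `<prefix>_imag.nii.gz`.
#'
#' @param path file path (`.nii` / `.nii.gz`).
#' @param x numeric/logical array to write.
#' @param prefix path prefix for the complex pair.
#' @return `readVolume()`: a plain numeric array; `readComplexVolume()`: a
#'   complex array; the writers return the written path(s) invisibly.
#' @export
readVolume <- function(path) {
    img <- RNifti::readNifti(path)
    a <- array(as.numeric(img), dim(img))
    a
}

#' @rdname readVolume
#' @export
writeVolume <- function(x, path) {
    if (is.logical(x)) x <- array(as.numeric(x), .dimOf(x))
    RNifti::writeNifti(RNifti::asNifti(x), path)
    invisible(path)
}

#' @rdname readVolume
#' @export
writeComplexVolume <- function(x, prefix) {
    pr <- paste0(prefix, "_real.nii.gz")
    pi <- paste0(prefix, "_imag.nii.gz")
    writeVolume(array(Re(x), .dimOf(x)), pr)
    writeVolume(array(Im(x), .dimOf(x)), pi)
    invisible(c(pr, pi))
}

#' @rdname readVolume
#' @export
readComplexVolume <- function(prefix) {
    re <- readVolume(paste0(prefix, "_real.nii.gz"))
    im <- readVolume(paste0(prefix, "_imag.nii.gz"))
    array(complex(real = re, imaginary = im), .dimOf(re))
}

#' Read a vertex adjacency from an edge-list file
#'
#' Two whitespace-separated integer columns, strictly 0-based vertex
#' indices (no auto-detection of 1-based files — a documented convention).
#' Symmetric duplicates are merged; self-edges are rejected.
#'
#' @param path text file path.
#' @param nVertices vertex count; defaults to the largest index + 1.
#' @return a [GraphAdjacency-class].
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path, nVertices = NULL) {
    e <- utils::read.table(path, header = FALSE, colClasses = "integer")
    if (ncol(e) != 2L)
        stop(sprintf("edge list '%s': expected 2 integer columns, found %d", path, ncol(e)))
    if (any(e < 0L))
        stop(sprintf("edge list '%s': negative index (indices are 0-based)", path))
    graphAdjacency(as.matrix(e) + 1L,
                   nVertices = if (is.null(nVertices)) NULL else as.integer(nVertices))
}

#' @rdname readEdgeList
#' @param adjacency a [GraphAdjacency-class] to write (0-based on disk).
#' @export
writeEdgeList <- function(adjacency, path) {
    utils::write.table(adjacency@edges - 1L, path, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read an acquisition grid or solver options from YAML
#'
#' `readAcquisitionConfig()` expects a mapping of named numeric sequences
#' (e.g. `echo_times: [2, 4, 6]`) and returns an [AcquisitionGrid-class].
#' `readFitConfig()` / `readMcmcConfig()` validate the keys against the
#' corresponding options constructor and error on any unknown key, naming
#' it.
#'
#' @param path YAML file path.
#' @return an [AcquisitionGrid-class], [fitOptions()] or [mcmcOptions()]
#'   object respectively.
#' @export
readAcquisitionConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.list(cfg) || is.null(names(cfg)) || any(!nzchar(names(cfg))))
        stop(sprintf("config '%s': expected a mapping of named numeric arrays", path))
    for (nm in names(cfg)) {
        v <- suppressWarnings(as.numeric(unlist(cfg[[nm]])))
        if (anyNA(v)) stop(sprintf("config '%s': entry '%s' is not numeric", path, nm))
        cfg[[nm]] <- v
    }
    do.call(acquisitionGrid, cfg)
}

#' @rdname readAcquisitionConfig
#' @export
readFitConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    known <- names(formals(fitOptions))
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop(sprintf("config '%s': unknown key(s): %s", path, paste(bad, collapse = ", ")))
    do.call(fitOptions, cfg)
}

#' @rdname readAcquisitionConfig
#' @export
readMcmcConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    known <- names(formals(mcmcOptions))
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop(sprintf("config '%s': unknown key(s): %s", path, paste(bad, collapse = ", ")))
    do.call(mcmcOptions, cfg)
}
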