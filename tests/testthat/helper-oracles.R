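# brute-force nested-loop anisotropic TV (independent oracle for tvSpatial)
bruteForceTv <- function(map, mask = NULL, ndims = 3L) {
    d <- dim(map)
    if (is.null(mask)) mask <- array(TRUE, d)
    tot <- 0; n <- 0L
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
        if (ndims >= 1 && x < d[1] && mask[x, y, z] && mask[x + 1, y, z]) {
            tot <- tot + abs(map[x + 1, y, z] - map[x, y, z]); n <- n + 1L
        }
        if (ndims >= 2 && y < d[2] && mask[x, y, z] && mask[x, y + 1, z]) {
            tot <- tot + abs(map[x, y + 1, z] - map[x, y, z]); n <- n + 1L
        }
        if (ndims >= 3 && z < d[3] && mask[x, y, z] && mask[x, y, z + 1]) {
            tot <- tot + abs(map[x, y, z + 1] - map[x, y, z]); n <- n + 1L
        }
    }
    if (n == 0L) 0 else tot / n
}

# random complex array helper
rcomplex <- function(n, d = NULL) {
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    if (!is.null(d)) dim(x) <- d
    x
}
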