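#' @useDynLib esoMorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a CTVolume
#'
#' @param voxels 3D array of HU values, axis order (slice, row, column).
#' @param spacing numeric(3) voxel size in mm (z, y, x).
#' @param origin numeric(3) physical coordinate of voxel (1,1,1) in mm.
#' @return A validated [CTVolume-class].
#' @examples
#' vol <- CTVolume(array(0, c(4, 8, 8)), spacing = c(5, 0.8, 0.8))
#' spacing(vol)
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a BinaryMask
#'
#' @inheritParams CTVolume
#' @param voxels 3D array with values in {0, 1}.
#' @return A validated [BinaryMask-class].
#' @export
BinaryMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(voxels) <- "integer"
    new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

.sameGrid <- function(a, b) {
    identical(dim(a@voxels), dim(b@voxels)) &&
        isTRUE(all.equal(a@spacing, b@spacing, tolerance = 1e-6)) &&
        isTRUE(all.equal(a@origin, b@origin, tolerance = 1e-6))
}

.stopIfGridMismatch <- function(a, b) {
    if (!.sameGrid(a, b))
        stop("grid mismatch: mask and volume must share shape, spacing and origin",
             call. = FALSE)
    invisible(TRUE)
}

#' Euclidean distance transform on a physical grid
#'
#' Exact Euclidean distance (in mm) from each voxel/pixel to the nearest
#' `TRUE` element of `feature`, honouring anisotropic spacing. Accepts a 2D
#' matrix or a 3D array. Elements with no feature anywhere get `Inf`.
#'
#' @param feature logical (or 0/1) matrix or 3D array marking the target set.
#' @param spacing numeric of length `length(dim(feature))`, mm per axis.
#' @return Numeric array of the same shape with distances in mm.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' distanceTransform(m, c(1, 1))[3, 5]  # 2 mm
#' @export
distanceTransform <- function(feature, spacing = rep(1, length(dim(feature)))) {
    d <- dim(feature)
    if (is.null(d) || !length(d) %in% 2:3)
        stop("feature must be a matrix or 3D array")
    if (length(spacing) != length(d))
        stop("spacing must have one entry per axis")
    if (length(d) == 2L) {
        dim3 <- c(d, 1L); sp3 <- c(spacing, 1)
    } else {
        dim3 <- d; sp3 <- spacing
    }
    out <- .edt_cpp(as.logical(feature), as.integer(dim3), as.numeric(sp3))
    dim(out) <- d
    out
}

# Trilinear interpolation of a 3D array at continuous voxel coordinates
# (1-indexed, n x 3 in (z,y,x) order). Coordinates outside the grid get
# `fill`. Used for HU resampling and plane sampling.
.interpTrilinear <- function(arr, coords, fill = 0) {
    d <- dim(arr)
    z <- coords[, 1]; y <- coords[, 2]; x <- coords[, 3]
    inside <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    out <- rep(fill, nrow(coords))
    if (!any(inside)) return(out)
    z <- z[inside]; y <- y[inside]; x <- x[inside]
    z0 <- pmin(floor(z), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
    x0 <- pmin(floor(x), d[3] - 1L)
    fz <- z - z0; fy <- y - y0; fx <- x - x0
    idx <- function(zi, yi, xi) ((xi - 1) * d[2] + (yi - 1)) * d[1] + zi
    v000 <- arr[idx(z0, y0, x0)];         v100 <- arr[idx(z0 + 1, y0, x0)]
    v010 <- arr[idx(z0, y0 + 1, x0)];     v110 <- arr[idx(z0 + 1, y0 + 1, x0)]
    v001 <- arr[idx(z0, y0, x0 + 1)];     v101 <- arr[idx(z0 + 1, y0, x0 + 1)]
    v011 <- arr[idx(z0, y0 + 1, x0 + 1)]; v111 <- arr[idx(z0 + 1, y0 + 1, x0 + 1)]
    out[inside] <-
        (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v001) +
                    fy * ((1 - fx) * v010 + fx * v011)) +
        fz * ((1 - fy) * ((1 - fx) * v100 + fx * v101) +
              fy * ((1 - fx) * v110 + fx * v111))
    out
}

# Nearest-neighbour sampling at continuous voxel coordinates (same contract).
.interpNearest <- function(arr, coords, fill = 0) {
    d <- dim(arr)
    zi <- round(coords[, 1]); yi <- round(coords[, 2]); xi <- round(coords[, 3])
    inside <- zi >= 1 & zi <= d[1] & yi >= 1 & yi <= d[2] & xi >= 1 & xi <= d[3]
    out <- rep(fill, nrow(coords))
    if (any(inside))
        out[inside] <- arr[((xi[inside] - 1) * d[2] + (yi[inside] - 1)) * d[1] +
                           zi[inside]]
    out
}

# Run code with a private RNG stream: seeds, runs, then restores the global
# RNG state so library calls stay reproducible for the caller.
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Round half-up to `digits` decimals, the convention of printed report tables
# (round() alone rounds half-to-even).
.roundHalfUp <- function(x, digits = 3) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}
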