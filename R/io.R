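#' Read a CT volume from NIfTI
#'
#' Reads a 3D NIfTI image into a [CTVolume-class], converting the on-disk
#' (x, y, z) axis order to the internal (slice, row, column) = (z, y, x)
#' convention and taking spacing and origin from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [CTVolume-class].
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path) {
    arr <- .readNiftiArray(path)
    CTVolume(arr$voxels, spacing = arr$spacing, origin = arr$origin)
}

#' Read a binary mask from NIfTI
#'
#' @inheritParams readVolume
#' @return A [BinaryMask-class]; errors with "mask not binary" if the file
#'   contains values other than 0 and 1.
#' @export
readMask <- function(path) {
    arr <- .readNiftiArray(path)
    if (!all(arr$voxels %in% c(0, 1))) stop("mask not binary", call. = FALSE)
    BinaryMask(arr$voxels, spacing = arr$spacing, origin = arr$origin)
}

.readNiftiArray <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) {
        # degenerate singleton 4th dimension written by some tools
        dim(a) <- dim(a)[1:3]
    }
    if (length(dim(a)) != 3L) stop("not a 3D volume", call. = FALSE)
    pd <- RNifti::pixdim(img)[seq_len(3)]
    xf <- try(RNifti::xform(img), silent = TRUE)
    orig <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
    # disk (x, y, z) -> internal (z, y, x)
    list(voxels = aperm(a, c(3, 2, 1)), spacing = rev(pd), origin = rev(orig))
}

.writeNiftiArray <- function(voxels, spacing, origin, path, datatype) {
    a <- aperm(voxels, c(3, 2, 1))  # internal (z,y,x) -> disk (x,y,z)
    img <- RNifti::asNifti(a)
    sp <- rev(spacing)
    RNifti::pixdim(img) <- sp
    m <- diag(c(sp, 1))
    m[1:3, 4] <- rev(origin)
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Write a CT volume or mask to NIfTI
#'
#' CT volumes are stored as 32-bit float (value-preserving for HU); masks as
#' 8-bit unsigned integers (bit-exact label round trip).
#'
#' @param vol a [CTVolume-class].
#' @param mask a [BinaryMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "CTVolume"))
    if (!dir.exists(dirname(path)))
        stop("unwritable path: ", dirname(path), call. = FALSE)
    .writeNiftiArray(vol@voxels, vol@spacing, vol@origin, path, "float")
}

#' @rdname writeVolume
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "BinaryMask"))
    if (!dir.exists(dirname(path)))
        stop("unwritable path: ", dirname(path), call. = FALSE)
    .writeNiftiArray(mask@voxels, mask@spacing, mask@origin, path, "uint8")
}

.resampleGrid <- function(x, targetMm, interp) {
    if (!is.numeric(targetMm) || length(targetMm) != 1L || targetMm <= 0)
        stop("targetMm must be a positive scalar", call. = FALSE)
    d <- dim(x@voxels)
    if (any(d < 2L)) stop("degenerate input grid", call. = FALSE)
    extent <- (d - 1) * x@spacing
    nNew <- pmax(2L, as.integer(round(extent / targetMm)) + 1L)
    # new voxel centres in old (continuous, 1-indexed) voxel coordinates
    ax <- lapply(1:3, function(i) (seq_len(nNew[i]) - 1) * targetMm / x@spacing[i] + 1)
    coords <- as.matrix(expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]],
                                    KEEP.OUT.ATTRS = FALSE))
    vals <- interp(x@voxels, coords)
    array(vals, dim = nNew)
}

#' @rdname resampleIsotropic
setMethod("resampleIsotropic", "CTVolume", function(x, targetMm) {
    v <- .resampleGrid(x, targetMm, function(a, co) .interpTrilinear(a, co, fill = min(a)))
    CTVolume(v, spacing = rep(targetMm, 3), origin = x@origin)
})

#' @rdname resampleIsotropic
setMethod("resampleIsotropic", "BinaryMask", function(x, targetMm) {
    v <- .resampleGrid(x, targetMm, function(a, co) .interpNearest(a, co, fill = 0L))
    BinaryMask(v, spacing = rep(targetMm, 3), origin = x@origin)
})
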