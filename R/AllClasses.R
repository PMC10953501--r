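#' @import methods
NULL

#' ScanGrid: common geometry of voxel grids
#'
#' Virtual parent of [CTVolume-class] and [BinaryMask-class]. Voxels are
#' stored in a 3D array with axis order (slice, row, column) = (z, y, x);
#' `spacing` and `origin` follow the same order and are in millimetres.
#' Voxel centres are 0-indexed in physical space: the centre of voxel
#' (i, j, k) (1-indexed in R) lies at `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @slot voxels 3D array of voxel values.
#' @slot spacing numeric(3), per-axis voxel size in mm (z, y, x).
#' @slot origin numeric(3), physical coordinate of voxel (1,1,1) in mm.
#' @name ScanGrid-class
#' @exportClass ScanGrid
setClass("ScanGrid", representation("VIRTUAL",
    voxels = "array", spacing = "numeric", origin = "numeric"))

.validScanGrid <- function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 3L) msg <- c(msg, "voxels must be a 3D array")
    else if (any(d < 2L)) msg <- c(msg, "grid must have >= 2 voxels per axis")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values")
    if (length(msg)) msg else TRUE
}

#' CTVolume: a CT grid in Hounsfield units
#'
#' A 3D scalar grid of Hounsfield units with physical spacing and origin.
#' See [ScanGrid-class] for the geometry convention.
#'
#' @seealso [CTVolume()], [readVolume()], [resampleIsotropic()]
#' @name CTVolume-class
#' @exportClass CTVolume
setClass("CTVolume", contains = "ScanGrid")

setValidity("CTVolume", function(object) {
    msg <- .validScanGrid(object)
    msg <- if (isTRUE(msg)) character() else msg
    if (any(!is.finite(object@voxels)))
        msg <- c(msg, "HU values must be finite")
    if (length(msg)) msg else TRUE
})

#' BinaryMask: a voxel label grid
#'
#' A 3D grid of {0,1} labels sharing the geometry contract of
#' [CTVolume-class]. Used for esophagus segmentations and derived wall masks.
#'
#' @seealso [BinaryMask()], [readMask()], [removeLumenAir()]
#' @name BinaryMask-class
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "ScanGrid")

setValidity("BinaryMask", function(object) {
    msg <- .validScanGrid(object)
    msg <- if (isTRUE(msg)) character() else msg
    v <- object@voxels
    if (!all(v == 0 | v == 1)) msg <- c(msg, "mask not binary")
    if (length(msg)) msg else TRUE
})

#' WallMask: an esophageal wall mask with its provenance
#'
#' A [BinaryMask-class] produced by [removeLumenAir()], recording the HU
#' threshold that separated intraluminal air from the wall.
#'
#' @slot huThreshold numeric(1), the air-removal threshold in HU.
#' @name WallMask-class
#' @exportClass WallMask
setClass("WallMask", contains = "BinaryMask",
         representation(huThreshold = "numeric"))

#' Centerline: the medial curve of a tubular organ
#'
#' Ordered 3D points along the organ axis, superior to inferior, in mm
#' (columns z, y, x), with cumulative arc length and unit tangents.
#'
#' @slot points n x 3 matrix of mm coordinates (z, y, x).
#' @slot cumArcMm cumulative arc length from the superior end, starting at 0.
#' @slot tangents n x 3 matrix of unit tangent vectors.
#' @seealso [extractCenterline()], [resampleCenterline()], [straighten()]
#' @name Centerline-class
#' @exportClass Centerline
setClass("Centerline", representation(
    points = "matrix", cumArcMm = "numeric", tangents = "matrix"))

setValidity("Centerline", function(object) {
    msg <- character()
    n <- nrow(object@points)
    if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
    if (n < 2L) msg <- c(msg, "centerline needs >= 2 points")
    if (length(object@cumArcMm) != n)
        msg <- c(msg, "cumArcMm length must match points")
    else {
        if (object@cumArcMm[1] != 0) msg <- c(msg, "cumArcMm must start at 0")
        if (n >= 2L && any(diff(object@cumArcMm) <= 0))
            msg <- c(msg, "cumArcMm must be strictly increasing")
    }
    if (!all(dim(object@tangents) == dim(object@points)))
        msg <- c(msg, "tangents must match points in shape")
    else {
        nrm <- sqrt(rowSums(object@tangents^2))
        if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "tangents must be unit-norm")
    }
    if (length(msg)) msg else TRUE
})

#' StraightenedStack: cross-sections orthogonal to the centerline
#'
#' The result of curved planar reformation: square planes sampled
#' perpendicular to the centerline at a fixed arc step, so the tube appears
#' straight. Planes are stored in a (npix, npix, nplanes) array.
#'
#' @slot planes 3D array, one square plane per sampled arc position.
#' @slot arcMm arc position of each plane.
#' @slot pixelMm in-plane pixel size in mm.
#' @slot stepMm arc step between planes in mm.
#' @slot kind "mask" (nearest-neighbour sampled) or "hu" (linear).
#' @slot truncated logical per plane: foreground touched the plane border.
#' @seealso [straighten()], [thicknessProfile()]
#' @name StraightenedStack-class
#' @exportClass StraightenedStack
setClass("StraightenedStack", representation(
    planes = "array", arcMm = "numeric", pixelMm = "numeric",
    stepMm = "numeric", kind = "character", truncated = "logical"))

setValidity("StraightenedStack", function(object) {
    msg <- character()
    d <- dim(object@planes)
    if (length(d) != 3L) msg <- c(msg, "planes must be a 3D array")
    else if (d[1] != d[2]) msg <- c(msg, "planes must be square")
    else if (length(object@arcMm) != d[3] || length(object@truncated) != d[3])
        msg <- c(msg, "arcMm/truncated must have one entry per plane")
    if (!object@kind %in% c("mask", "hu")) msg <- c(msg, "kind must be mask or hu")
    if (object@pixelMm <= 0 || object@stepMm <= 0)
        msg <- c(msg, "pixelMm and stepMm must be positive")
    if (length(msg)) msg else TRUE
})

#' SegmentTreeModel: decision tree over per-segment morphometry features
#'
#' A CART-style decision tree mapping per-segment feature vectors to a
#' cancer-present call. The tree is held as a flat node table (heap-numbered
#' nodes, axis-aligned numeric splits, leaf class probabilities) which is
#' what prediction traverses, so that a model serialized to JSON and read
#' back predicts identically.
#'
#' @slot nodes data.frame of nodes: node id, split variable, threshold,
#'   direction of the left branch, leaf flag, probability of cancer, n.
#' @slot schema character vector of feature column names used for splitting.
#' @slot config list echo of the training configuration.
#' @slot seed integer training seed.
#' @seealso [fitSegmentTree()], [predictSegments()], [writeTreeModel()]
#' @name SegmentTreeModel-class
#' @exportClass SegmentTreeModel
setClass("SegmentTreeModel", representation(
    nodes = "data.frame", schema = "character", config = "list",
    seed = "integer"))

setValidity("SegmentTreeModel", function(object) {
    msg <- character()
    need <- c("node", "var", "threshold", "left_if_lt", "leaf", "prob_pos", "n")
    if (!all(need %in% names(object@nodes)))
        msg <- c(msg, "nodes table missing required columns")
    else {
        nd <- object@nodes
        if (!1 %in% nd$node) msg <- c(msg, "root node (1) missing")
        int <- nd$node[!nd$leaf]
        if (length(int) &&
            !all(c(2 * int, 2 * int + 1) %in% nd$node))
            msg <- c(msg, "every internal node needs both children")
        pp <- nd$prob_pos[nd$leaf]
        if (any(pp < 0 | pp > 1)) msg <- c(msg, "leaf probabilities outside [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ScanGrid", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("%s: %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
                class(object), d[1], d[2], d[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
    if (is(object, "BinaryMask"))
        cat(sprintf("  foreground voxels: %d\n", sum(object@voxels == 1)))
    else
        cat(sprintf("  HU range: [%.1f, %.1f]\n",
                    min(object@voxels), max(object@voxels)))
    invisible(object)
})

#' @export
setMethod("show", "Centerline", function(object) {
    cat(sprintf("Centerline: %d points, arc length %.1f mm\n",
                nrow(object@points), max(object@cumArcMm)))
    invisible(object)
})

#' @export
setMethod("show", "StraightenedStack", function(object) {
    d <- dim(object@planes)
    cat(sprintf(
        "StraightenedStack (%s): %d planes of %d x %d px (%.2g mm), step %.2g mm\n",
        object@kind, d[3], d[1], d[2], object@pixelMm, object@stepMm))
    if (any(object@truncated))
        cat(sprintf("  %d truncated plane(s)\n", sum(object@truncated)))
    invisible(object)
})

#' @export
setMethod("show", "SegmentTreeModel", function(object) {
    nd <- object@nodes
    cat(sprintf("SegmentTreeModel: %d nodes (%d leaves), features: %s\n",
                nrow(nd), sum(nd$leaf),
                paste(unique(nd$var[!nd$leaf]), collapse = ", ")))
    invisible(object)
})
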