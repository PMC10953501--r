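#' Accessors for voxel grids and centerlines
#'
#' `voxels()`, `spacing()` and `origin()` return the voxel array, per-axis
#' voxel size (mm) and the physical coordinate (mm) of the first voxel of a
#' [CTVolume-class] or [BinaryMask-class]. `clPoints()`, `arcLength()` and
#' `clTangents()` access [Centerline-class] geometry; `arcLength()` on a
#' centerline returns the total arc length in mm.
#'
#' @param x the object.
#' @return See description; accessors never copy-modify the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("clPoints", function(x) standardGeneric("clPoints"))
#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))
#' @rdname accessors
#' @export
setGeneric("clTangents", function(x) standardGeneric("clTangents"))
#' @rdname accessors
#' @export
setGeneric("cumArc", function(x) standardGeneric("cumArc"))

#' @rdname accessors
setMethod("voxels", "ScanGrid", function(x) x@voxels)
#' @rdname accessors
setMethod("spacing", "ScanGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "ScanGrid", function(x) x@origin)
#' @rdname accessors
setMethod("clPoints", "Centerline", function(x) x@points)
#' @rdname accessors
setMethod("arcLength", "Centerline", function(x) max(x@cumArcMm))
#' @rdname accessors
setMethod("cumArc", "Centerline", function(x) x@cumArcMm)
#' @rdname accessors
setMethod("clTangents", "Centerline", function(x) x@tangents)

#' Resample a grid to isotropic spacing
#'
#' @param x a [CTVolume-class] or [BinaryMask-class].
#' @param targetMm positive scalar, the isotropic voxel size in mm.
#' @return An object of the same class on an isotropic grid. CT volumes are
#'   interpolated linearly; masks with nearest neighbour so labels stay crisp.
#' @details The output grid covers the same physical extent within one voxel
#'   per axis; foreground volume of convex masks is conserved within a few
#'   percent for objects at least ~10 voxels across.
#' @export
setGeneric("resampleIsotropic", function(x, targetMm)
    standardGeneric("resampleIsotropic"))
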