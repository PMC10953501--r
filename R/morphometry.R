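#' Delineate the esophageal wall by removing intraluminal air
#'
#' The segmentation mask covers the whole organ including the air-filled
#' lumen; thresholding the CT inside the mask removes the air portion and
#' leaves the soft-tissue wall. A voxel is kept iff it is in the mask and its
#' HU value is at or above `huThreshold`.
#'
#' @param mask a [BinaryMask-class] esophagus segmentation.
#' @param ct the paired [CTVolume-class] on the same grid.
#' @param huThreshold air threshold in HU; the default -500 sits midway
#'   between air (~ -1000 HU) and any soft tissue.
#' @return A [WallMask-class] recording the threshold applied. Idempotent:
#'   re-applying the same threshold to the result is a no-op.
#' @export
removeLumenAir <- function(mask, ct, huThreshold = -500) {
    stopifnot(is(mask, "BinaryMask"), is(ct, "CTVolume"),
              is.finite(huThreshold))
    .stopIfGridMismatch(mask, ct)
    v <- array(0L, dim(mask@voxels))
    v[mask@voxels == 1L & ct@voxels >= huThreshold] <- 1L
    if (sum(v) == 0L) stop("empty wall: mask contains no voxels above threshold",
                           call. = FALSE)
    new("WallMask", voxels = v, spacing = mask@spacing, origin = mask@origin,
        huThreshold = huThreshold)
}

#' Measure one transversal cut-plane of the wall
#'
#' Diameters are area-equivalent: the wall with its lumen hole(s) filled has
#' area \eqn{A_f}, giving an outer diameter \eqn{2\sqrt{A_f/\pi}}; the
#' enclosed lumen area gives the lumen diameter the same way, and the wall
#' thickness is half the diameter difference. A collapsed lumen (no enclosed
#' hole) yields lumen diameter 0, so thickness equals the outer radius — the
#' normal presentation of a collapsed esophagus. A Euclidean
#' distance-transform medial thickness (twice the mean ridge distance) is
#' returned as a cross-check field.
#'
#' @param plane 2D 0/1 matrix, a wall cross-section.
#' @param pixelMm square pixel size in mm.
#' @return One-row data.frame: `outer_diameter_mm`, `lumen_diameter_mm`,
#'   `wall_thickness_mm`, `area_mm2`, `thickness_edt_mm`.
#' @examples
#' px <- 0.25
#' g <- expand.grid(y = 1:80, x = 1:80)
#' r <- sqrt((g$y - 40.5)^2 + (g$x - 40.5)^2) * px
#' ring <- matrix(as.integer(r <= 6 & r > 4), 80, 80)
#' measureCrossSection(ring, px)$wall_thickness_mm  # ~2 mm
#' @export
measureCrossSection <- function(plane, pixelMm) {
    if (!is.matrix(plane) || sum(plane) == 0) stop("empty plane", call. = FALSE)
    stopifnot(pixelMm > 0)
    px2 <- pixelMm^2
    filled <- EBImage::fillHull(plane > 0)
    aWall <- sum(plane > 0) * px2
    aFilled <- sum(filled) * px2
    aLumen <- aFilled - aWall
    outer <- 2 * sqrt(aFilled / pi)
    lumen <- 2 * sqrt(max(aLumen, 0) / pi)
    thick <- (outer - lumen) / 2

    # medial EDT thickness: distance of each wall pixel to the background,
    # ridge pixels = within half a pixel of the maximum
    edt <- distanceTransform(plane == 0, c(pixelMm, pixelMm))
    inside <- plane > 0
    m <- max(edt[inside])
    thickEdt <- if (is.finite(m)) {           # all-foreground plane has no EDT
        ridge <- inside & edt >= m - pixelMm / 2
        # half-pixel correction: EDT measures to background pixel centres,
        # the continuous boundary sits about half a pixel closer
        max(2 * mean(edt[ridge]) - pixelMm / 2, pixelMm)
    } else NA_real_

    data.frame(outer_diameter_mm = outer, lumen_diameter_mm = lumen,
               wall_thickness_mm = thick, area_mm2 = aWall,
               thickness_edt_mm = thickEdt)
}

#' Measure diameter and wall thickness along the straightened esophagus
#'
#' Applies [measureCrossSection()] to every plane of a straightened wall
#' stack, producing the per-cut-plane profile whose per-segment variances
#' feed the classifier. Planes with no wall pixels are skipped and reported
#' as gaps.
#'
#' @param stack a [StraightenedStack-class] of the wall mask (kind "mask").
#' @return data.frame with one row per non-empty plane: `arc_mm` plus the
#'   [measureCrossSection()] fields and a `truncated` flag.
#' @seealso [straighten()], [computeSegmentFeatures()]
#' @export
thicknessProfile <- function(stack) {
    stopifnot(is(stack, "StraightenedStack"))
    if (stack@kind != "mask")
        stop("thicknessProfile expects a mask stack", call. = FALSE)
    np <- dim(stack@planes)[3]
    if (np == 0) stop("empty stack", call. = FALSE)
    rows <- vector("list", np)
    nGap <- 0L
    for (k in seq_len(np)) {
        pl <- stack@planes[, , k]
        if (sum(pl) == 0) { nGap <- nGap + 1L; next }
        cs <- measureCrossSection(pl, stack@pixelMm)
        cs$arc_mm <- stack@arcMm[k]
        cs$truncated <- stack@truncated[k]
        rows[[k]] <- cs
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("empty stack: no plane contains wall", call. = FALSE)
    if (nGap > 0)
        message(nGap, " empty plane(s) skipped in thickness profile")
    out[, c("arc_mm", "outer_diameter_mm", "lumen_diameter_mm",
            "wall_thickness_mm", "area_mm2", "thickness_edt_mm", "truncated")]
}

#' Export a thickness profile as CSV
#'
#' @param profile data.frame from [thicknessProfile()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeProfile <- function(profile, path) {
    utils::write.csv(profile, path, row.names = FALSE)
    invisible(path)
}
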