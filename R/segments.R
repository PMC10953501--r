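#' Divide the straightened esophagus into upper, middle, lower segments
#'
#' Clinical division from the superior starting point: the upper segment is
#' the first 5 cm, the middle the next 10 cm, and the lower the remaining
#' length. Intervals are half-open `[a, b)` with the final interval closed,
#' and are clipped when the organ is shorter than a boundary.
#'
#' @param L total centerline arc length in mm.
#' @param upperMm,middleMm segment lengths in mm (defaults 50 and 100).
#' @return data.frame with one row per segment: `segment`, `start_mm`,
#'   `end_mm`, `length_mm`; attribute `total_mm`. Empty segments have zero
#'   length.
#' @examples
#' divideSegments(250)  # 50 / 100 / 100 mm
#' divideSegments(120)  # 50 / 70 / 0 mm
#' @export
divideSegments <- function(L, upperMm = 50, middleMm = 100) {
    if (!is.numeric(L) || length(L) != 1L || L <= 0)
        stop("total length must be positive", call. = FALSE)
    b1 <- min(upperMm, L)
    b2 <- min(upperMm + middleMm, L)
    out <- data.frame(
        segment = c("upper", "middle", "lower"),
        start_mm = c(0, b1, b2),
        end_mm = c(b1, b2, L),
        stringsAsFactors = FALSE)
    out$length_mm <- out$end_mm - out$start_mm
    attr(out, "total_mm") <- L
    out
}

# Segment index (1=upper, 2=middle, 3=lower) of each arc position under the
# half-open rule; the final interval is closed at L.
.assignSegment <- function(arcMm, bounds) {
    L <- attr(bounds, "total_mm")
    idx <- findInterval(arcMm, c(bounds$start_mm, L),
                        rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), 3L)
    # an arc landing exactly on L may fall into a clipped zero-length
    # segment; push it back to the last segment with positive extent
    for (k in 3:2) if (bounds$length_mm[k] == 0) idx[idx == k] <- k - 1L
    idx
}

#' Per-segment morphometric feature vectors
#'
#' Assigns each cut-plane of a thickness profile to its segment and computes
#' per segment: plane count, mean and sample variance (ddof = 1) of the
#' outer diameter and of the wall thickness, and the maximum wall thickness.
#' Measurement variance over the cut-planes of a segment is the primary
#' cancer signature (a focal lesion perturbs thickness over part of the
#' segment); means and maxima cover uniform generalized thickening, which
#' has low variance but a shifted level. Segments with fewer than two planes
#' are flagged missing.
#'
#' @param profile data.frame from [thicknessProfile()], ordered by `arc_mm`.
#' @param bounds data.frame from [divideSegments()].
#' @return data.frame with one row per segment: `segment`, `n_planes`,
#'   `mean_outer_mm`, `var_outer_mm2`, `mean_thickness_mm`,
#'   `var_thickness_mm2`, `max_thickness_mm`, `missing`.
#' @export
computeSegmentFeatures <- function(profile, bounds) {
    if (is.null(profile) || nrow(profile) == 0)
        stop("empty profile", call. = FALSE)
    seg <- .assignSegment(profile$arc_mm, bounds)
    out <- lapply(1:3, function(k) {
        p <- profile[seg == k, , drop = FALSE]
        n <- nrow(p)
        if (n < 2) {
            data.frame(segment = bounds$segment[k], n_planes = n,
                       mean_outer_mm = NA_real_, var_outer_mm2 = NA_real_,
                       mean_thickness_mm = NA_real_,
                       var_thickness_mm2 = NA_real_,
                       max_thickness_mm = NA_real_, missing = TRUE,
                       stringsAsFactors = FALSE)
        } else {
            data.frame(segment = bounds$segment[k], n_planes = n,
                       mean_outer_mm = mean(p$outer_diameter_mm),
                       var_outer_mm2 = stats::var(p$outer_diameter_mm),
                       mean_thickness_mm = mean(p$wall_thickness_mm),
                       var_thickness_mm2 = stats::var(p$wall_thickness_mm),
                       max_thickness_mm = max(p$wall_thickness_mm),
                       missing = FALSE, stringsAsFactors = FALSE)
        }
    })
    do.call(rbind, out)
}
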