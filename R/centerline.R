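# Voxel adjacency graph (26-connectivity) over foreground voxels of an
# isotropic grid. Returns the igraph plus per-edge physical length and the
# voxel coordinates (arrayInd rows) of each vertex.
.voxelGraph <- function(fgIdx, dm, spacingMm) {
    pos <- integer(prod(dm))
    pos[fgIdx] <- seq_along(fgIdx)
    co <- arrayInd(fgIdx, dm)
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[order(offs[, 1], offs[, 2], offs[, 3]), , drop = FALSE]
    offs <- offs[(offs[, 1] > 0) |
                 (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
                 drop = FALSE]
    from <- integer(0); to <- integer(0); len <- numeric(0)
    for (r in seq_len(nrow(offs))) {
        o <- offs[r, ]
        nz <- co[, 1] + o[1]; ny <- co[, 2] + o[2]; nx <- co[, 3] + o[3]
        ok <- nz >= 1 & nz <= dm[1] & ny >= 1 & ny <= dm[2] &
              nx >= 1 & nx <= dm[3]
        if (!any(ok)) next
        nidx <- ((nx[ok] - 1) * dm[2] + (ny[ok] - 1)) * dm[1] + nz[ok]
        p <- pos[nidx]
        hit <- p > 0L
        if (!any(hit)) next
        from <- c(from, which(ok)[hit])
        to <- c(to, p[hit])
        len <- c(len, rep(sqrt(sum((o * spacingMm)^2)), sum(hit)))
    }
    g <- igraph::make_graph(rbind(from, to), n = length(fgIdx),
                            directed = FALSE)
    list(graph = g, length = len, coords = co)
}

#' Extract the esophageal centerline from a segmentation mask
#'
#' The mask is resampled to an isotropic grid (5 mm CT slices are far too
#' coarse for 3D medial analysis), reduced to its largest connected
#' component, and its interior Euclidean distance transform is computed. The
#' centerline is the geodesic between the two ends of the tube — found by a
#' double graph-distance sweep — along edges penalized by inverse squared
#' interior depth, which pulls the path onto the medial axis of the tube.
#' The path is smoothed with a moving-average window and ordered
#' superior to inferior (ascending slice coordinate).
#'
#' @param mask a [BinaryMask-class].
#' @param isoMm isotropic resampling step in mm (default 1).
#' @param smoothWindow moving-average window in points (default 5).
#' @return A [Centerline-class] with points in mm, cumulative arc length and
#'   unit tangents.
#' @export
extractCenterline <- function(mask, isoMm = 1, smoothWindow = 5) {
    stopifnot(is(mask, "BinaryMask"))
    if (sum(mask@voxels) == 0) stop("empty mask", call. = FALSE)
    nzSlices <- sum(apply(mask@voxels, 1, function(s) any(s == 1)))
    if (nzSlices < 3) stop("mask too small: need foreground in >= 3 slices",
                           call. = FALSE)
    iso <- resampleIsotropic(mask, isoMm)
    dm <- dim(iso@voxels)
    fgIdx <- which(iso@voxels == 1L)

    vg <- .voxelGraph(fgIdx, dm, rep(isoMm, 3))
    comp <- igraph::components(vg$graph)
    keepComp <- which.max(comp$csize)
    keep <- comp$membership == keepComp
    if (sum(keep) < length(fgIdx)) {
        fgIdx <- fgIdx[keep]
        vg <- .voxelGraph(fgIdx, dm, rep(isoMm, 3))
    }
    g <- vg$graph

    depth <- distanceTransform(iso@voxels == 0L, rep(isoMm, 3))[fgIdx]
    # double sweep with plain geodesic length to find the tube ends
    d1 <- igraph::distances(g, v = 1, weights = vg$length)[1, ]
    a <- which.max(d1)
    d2 <- igraph::distances(g, v = a, weights = vg$length)[1, ]
    b <- which.max(d2)
    ecount <- igraph::ecount(g)
    ends <- igraph::ends(g, seq_len(ecount), names = FALSE)
    wCen <- vg$length / ((depth[ends[, 1]] + depth[ends[, 2]]) / 2 + 0.5)^2
    sp <- igraph::shortest_paths(g, from = a, to = b, weights = wCen)
    path <- as.integer(sp$vpath[[1]])
    if (length(path) < 3) stop("skeleton path too short", call. = FALSE)

    # the geodesic endpoints sit on the mask surface (e.g. a rim corner of a
    # tube end face); trim the shallow end excursions, then extend the
    # trimmed path along its end tangents to the mask boundary so the
    # centerline spans the organ's full medial extent
    dpath <- depth[path]
    med <- stats::median(dpath)
    i0 <- 1L
    while (i0 < length(path) && dpath[i0] < 0.9 * med) i0 <- i0 + 1L
    i1 <- length(path)
    while (i1 > i0 && dpath[i1] < 0.9 * med) i1 <- i1 - 1L
    path <- path[i0:i1]
    if (length(path) < 3) stop("skeleton path too short", call. = FALSE)

    pts <- sweep((vg$coords[path, , drop = FALSE] - 1) * isoMm, 2,
                 iso@origin, `+`)
    if (pts[1, 1] > pts[nrow(pts), 1]) pts <- pts[rev(seq_len(nrow(pts))), ]
    pts <- .movingAverage(pts, smoothWindow)
    pts <- .extendToBoundary(pts, iso, isoMm)
    .makeCenterline(pts)
}

# March from each end of the path along the local end tangent until leaving
# the mask, appending the last inside point; keeps the centerline spanning
# flat tube ends that the depth trim pulled away from.
.extendToBoundary <- function(pts, iso, isoMm) {
    n <- nrow(pts)
    extend <- function(p0, u) {
        u <- u / sqrt(sum(u^2))
        added <- NULL
        for (s in seq(isoMm, 60, by = isoMm)) {
            q <- p0 + s * u
            vox <- matrix((q - iso@origin) / isoMm + 1, 1)
            if (.interpNearest(iso@voxels, vox, fill = 0) != 1) break
            added <- rbind(added, q)
        }
        added
    }
    # end tangents from a ~10 mm span of the smoothed path
    k <- min(max(3L, ceiling(10 / isoMm)), n - 1L)
    headPts <- extend(pts[1, ], pts[1, ] - pts[1 + k, ])
    tailPts <- extend(pts[n, ], pts[n, ] - pts[n - k, ])
    if (!is.null(headPts)) headPts <- headPts[rev(seq_len(nrow(headPts))), , drop = FALSE]
    rbind(headPts, pts, tailPts)
}

# Column-wise moving average with shrinking windows at the ends.
.movingAverage <- function(pts, w) {
    if (w <= 1) return(pts)
    h <- floor(w / 2)
    n <- nrow(pts)
    out <- pts
    cs <- rbind(0, apply(pts, 2, cumsum))
    for (i in seq_len(n)) {
        lo <- max(1, i - h); hi <- min(n, i + h)
        out[i, ] <- (cs[hi + 1, ] - cs[lo, ]) / (hi - lo + 1)
    }
    out
}

.makeCenterline <- function(pts, arc = NULL) {
    seg <- sqrt(rowSums(diff(pts)^2))
    keep <- c(TRUE, seg > 1e-9)
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
    if (n < 2) stop("degenerate centerline", call. = FALSE)
    if (is.null(arc)) {
        seg <- sqrt(rowSums(diff(pts)^2))
        arc <- c(0, cumsum(seg))
    } else arc <- arc[keep]
    tg <- matrix(0, n, 3)
    tg[1, ] <- pts[2, ] - pts[1, ]
    tg[n, ] <- pts[n, ] - pts[n - 1, ]
    if (n > 2) tg[2:(n - 1), ] <- pts[3:n, , drop = FALSE] -
            pts[1:(n - 2), , drop = FALSE]
    tg <- tg / sqrt(rowSums(tg^2))
    colnames(pts) <- colnames(tg) <- c("z", "y", "x")
    new("Centerline", points = unname(pts), cumArcMm = as.numeric(arc),
        tangents = unname(tg))
}

# Linear interpolation of centerline points at arbitrary arc positions.
.clInterp <- function(cl, s) {
    cbind(stats::approx(cl@cumArcMm, cl@points[, 1], xout = s)$y,
          stats::approx(cl@cumArcMm, cl@points[, 2], xout = s)$y,
          stats::approx(cl@cumArcMm, cl@points[, 3], xout = s)$y)
}

#' Resample a centerline at equal arc steps
#'
#' Points are placed at arc positions 0, step, 2*step, ...; both endpoints
#' are preserved (the final interval may be shorter than `stepMm` when the
#' total length is not a multiple of the step). Resampling twice at the same
#' step is idempotent.
#'
#' @param cl a [Centerline-class].
#' @param stepMm positive arc step in mm; must not exceed the total length.
#' @return A [Centerline-class].
#' @export
resampleCenterline <- function(cl, stepMm) {
    stopifnot(is(cl, "Centerline"), stepMm > 0)
    L <- arcLength(cl)
    if (stepMm > L) stop("step larger than total length", call. = FALSE)
    s <- seq(0, L, by = stepMm)
    if (L - s[length(s)] > 1e-9) s <- c(s, L)
    .makeCenterline(.clInterp(cl, s), arc = s)
}

# Rotation-minimizing (parallel-transport) frames along the centerline:
# project the previous normal off each new tangent instead of using Frenet
# frames, which spin freely at low curvature.
.transportFrames <- function(tangents) {
    n <- nrow(tangents)
    nrm <- matrix(0, n, 3); bin <- matrix(0, n, 3)
    t1 <- tangents[1, ]
    e <- diag(3)[, which.min(abs(t1))]
    v <- e - sum(e * t1) * t1
    nrm[1, ] <- v / sqrt(sum(v^2))
    bin[1, ] <- .cross3(t1, nrm[1, ])
    for (k in seq_len(n)[-1]) {
        tk <- tangents[k, ]
        v <- nrm[k - 1, ] - sum(nrm[k - 1, ] * tk) * tk
        if (sqrt(sum(v^2)) < 1e-9) v <- bin[k - 1, ] - sum(bin[k - 1, ] * tk) * tk
        nrm[k, ] <- v / sqrt(sum(v^2))
        bin[k, ] <- .cross3(tk, nrm[k, ])
    }
    list(normal = nrm, binormal = bin)
}

.cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

#' Straighten a volume or mask along the centerline
#'
#' Curved planar reformation: square planes are sampled on orthonormal
#' frames perpendicular to the centerline tangent at fixed arc steps, so the
#' esophagus appears straight and the 5 cm / 10 cm / remainder segment
#' division becomes a simple split of the plane index. Frames are propagated
#' by parallel transport to prevent in-plane spin. Masks are sampled
#' nearest-neighbour, CT volumes linearly.
#'
#' @param x a [CTVolume-class] or [BinaryMask-class].
#' @param cl the [Centerline-class] of the organ, in the same physical space.
#' @param planeHalfWidthMm half-width of each square plane in mm.
#' @param planePixelMm in-plane pixel size in mm.
#' @param stepMm arc step between planes in mm (default 2.5, half the
#'   routine slice thickness).
#' @return A [StraightenedStack-class] with `floor(L / stepMm) + 1` planes.
#'   Mask planes whose foreground touches the plane border are flagged
#'   truncated and a warning is raised.
#' @export
straighten <- function(x, cl, planeHalfWidthMm = 20, planePixelMm = 1,
                       stepMm = 2.5) {
    stopifnot(is(x, "ScanGrid"), is(cl, "Centerline"),
              planeHalfWidthMm > 0, planePixelMm > 0, stepMm > 0)
    if (nrow(cl@points) < 2) stop("empty centerline", call. = FALSE)
    isMask <- is(x, "BinaryMask")
    L <- arcLength(cl)
    arcs <- seq(0, L, by = stepMm)
    pts <- .clInterp(cl, arcs)
    n <- length(arcs)
    if (n == 1L) {
        tg <- cl@tangents[1, , drop = FALSE]
    } else {
        tg <- matrix(0, n, 3)
        tg[1, ] <- pts[2, ] - pts[1, ]
        tg[n, ] <- pts[n, ] - pts[n - 1, ]
        if (n > 2) tg[2:(n - 1), ] <- pts[3:n, , drop = FALSE] -
                pts[1:(n - 2), , drop = FALSE]
        tg <- tg / sqrt(rowSums(tg^2))
    }
    fr <- .transportFrames(tg)

    u <- seq(-planeHalfWidthMm, planeHalfWidthMm, by = planePixelMm)
    npix <- length(u)
    uv <- expand.grid(u = u, v = u)
    planes <- array(if (isMask) 0L else -1000, c(npix, npix, length(arcs)))
    trunc <- logical(length(arcs))
    fill <- if (isMask) 0 else -1000
    for (k in seq_along(arcs)) {
        world <- matrix(pts[k, ], nrow(uv), 3, byrow = TRUE) +
            outer(uv$u, fr$normal[k, ]) + outer(uv$v, fr$binormal[k, ])
        vox <- sweep(world, 2, x@origin, `-`)
        vox <- sweep(vox, 2, x@spacing, `/`) + 1
        vals <- if (isMask) .interpNearest(x@voxels, vox, fill = fill)
                else .interpTrilinear(x@voxels, vox, fill = fill)
        pl <- matrix(vals, npix, npix)
        if (isMask) {
            border <- c(pl[1, ], pl[npix, ], pl[, 1], pl[, npix])
            trunc[k] <- any(border > 0)
        }
        planes[, , k] <- pl
    }
    if (any(trunc))
        warning(sum(trunc),
                " plane(s) truncated: wall reaches the plane border",
                call. = FALSE)
    new("StraightenedStack", planes = planes, arcMm = arcs,
        pixelMm = planePixelMm, stepMm = stepMm,
        kind = if (isMask) "mask" else "hu", truncated = trunc)
}

#' Export a centerline as CSV
#'
#' @param cl a [Centerline-class].
#' @param path output CSV path; columns x, y, z, arc_mm.
#' @return The path, invisibly.
#' @export
writeCenterline <- function(cl, path) {
    df <- data.frame(x = cl@points[, 3], y = cl@points[, 2],
                     z = cl@points[, 1], arc_mm = cl@cumArcMm)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
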