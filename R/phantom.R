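#' Specify a synthetic esophageal lesion
#'
#' The three morphologies esophageal carcinomas present with on CT are
#' supported: a focal area of mural thickening, a flat/polypoid intraluminal
#' lesion, and generalized mural thickening.
#'
#' @param kind one of `"focal_thickening"`, `"polypoid"`,
#'   `"generalized_thickening"`.
#' @param center_arc_mm lesion centre position along the centerline (mm from
#'   the superior end).
#' @param extent_mm longitudinal extent of the lesion (mm).
#' @param delta_thickness_mm added wall thickness (focal/generalized) or
#'   nodule radius (polypoid), in mm.
#' @return A `LesionSpec` list.
#' @export
lesionSpec <- function(kind = c("focal_thickening", "polypoid",
                                "generalized_thickening"),
                       center_arc_mm, extent_mm, delta_thickness_mm) {
    kind <- match.arg(kind)
    stopifnot(extent_mm > 0, delta_thickness_mm > 0, center_arc_mm >= 0)
    structure(list(kind = kind, center_arc_mm = center_arc_mm,
                   extent_mm = extent_mm,
                   delta_thickness_mm = delta_thickness_mm),
              class = "LesionSpec")
}

#' Specify a synthetic esophagus phantom
#'
#' Defines a curved air-filled tube of soft-tissue wall embedded in a
#' mediastinal-fat background, on a CT-like anisotropic grid (5 mm slices by
#' default, matching routine chest CT). The tube axis follows a smooth
#' sinusoidal lateral deflection so centerline extraction is tested on a
#' genuinely curved organ.
#'
#' @param length_mm tube arc length in mm (default 250, a typical adult
#'   esophagus).
#' @param curvature list with `amplitude_mm` and `period_mm` of the lateral
#'   sinusoidal deflection of the tube axis.
#' @param lumen_radius_mm radius of the air-filled lumen (mm).
#' @param wall_thickness_mm baseline wall thickness (mm).
#' @param lesions list of [lesionSpec()] objects.
#' @param grid_shape integer(3) voxel counts (slice, row, column). The
#'   default is a reduced grid so tests run quickly; the clinical 512 x 512
#'   in-plane matrix is available by passing it here.
#' @param spacing numeric(3) voxel size in mm (z, y, x); default
#'   `c(5, 0.8, 0.8)` (5 mm slice thickness).
#' @param noise_sd_hu standard deviation of additive Gaussian HU noise.
#' @param seed integer RNG seed, making phantoms voxel-reproducible.
#' @return A `PhantomSpec` list.
#' @export
phantomSpec <- function(length_mm = 250,
                        curvature = list(amplitude_mm = 15, period_mm = 200),
                        lumen_radius_mm = 4, wall_thickness_mm = 3,
                        lesions = list(),
                        grid_shape = c(64L, 96L, 96L),
                        spacing = c(5, 0.8, 0.8),
                        noise_sd_hu = 10, seed = 1L) {
    stopifnot(length_mm > 0, lumen_radius_mm > 0, wall_thickness_mm > 0,
              all(spacing > 0), all(grid_shape >= 2))
    for (l in lesions) {
        if (!inherits(l, "LesionSpec")) stop("lesions must be LesionSpec objects")
        if (l$center_arc_mm > length_mm)
            stop("lesion outside tube length", call. = FALSE)
    }
    structure(list(length_mm = length_mm, curvature = curvature,
                   lumen_radius_mm = lumen_radius_mm,
                   wall_thickness_mm = wall_thickness_mm, lesions = lesions,
                   grid_shape = as.integer(grid_shape),
                   spacing = as.numeric(spacing),
                   noise_sd_hu = noise_sd_hu, seed = as.integer(seed)),
              class = "PhantomSpec")
}

# Wall thickness (mm) at arc position s, from baseline plus lesion deltas.
# Focal lesions have a flat core over the central 60% of their extent with a
# cosine taper to zero at the ends; generalized thickening is flat over its
# whole extent.
.phantomThicknessAt <- function(spec, s) {
    th <- rep(spec$wall_thickness_mm, length(s))
    for (l in spec$lesions) {
        if (l$kind == "polypoid") next
        half <- l$extent_mm / 2
        u <- abs(s - l$center_arc_mm) / half   # 0 at centre, 1 at edge
        add <- numeric(length(s))
        if (l$kind == "generalized_thickening") {
            add[u <= 1] <- l$delta_thickness_mm
        } else {
            core <- 0.6
            add[u <= core] <- l$delta_thickness_mm
            tap <- u > core & u <= 1
            add[tap] <- l$delta_thickness_mm *
                0.5 * (1 + cos(pi * (u[tap] - core) / (1 - core)))
        }
        th <- th + add
    }
    th
}

# Tube axis sampled at fine arc steps: matrix of (z, y, x) mm plus arc.
.phantomAxis <- function(spec, ds = 0.5) {
    d <- spec$grid_shape; sp <- spec$spacing
    zmax <- (d[1] - 1) * sp[1]
    y0 <- (d[2] - 1) * sp[2] / 2
    x0 <- (d[3] - 1) * sp[3] / 2
    A <- spec$curvature$amplitude_mm
    P <- spec$curvature$period_mm
    zstart <- min(8, zmax * 0.03)
    dz <- 0.25
    z <- seq(zstart, zmax, by = dz)
    y <- y0 + A * sin(2 * pi * (z - zstart) / P)
    seg <- sqrt(diff(z)^2 + diff(y)^2)
    arc <- c(0, cumsum(seg))
    if (max(arc) < spec$length_mm)
        stop("grid too small for tube of length ", spec$length_mm, " mm",
             call. = FALSE)
    keep <- arc <= spec$length_mm + 1e-9
    z <- z[keep]; y <- y[keep]; arc <- arc[keep]
    # resample to equal arc steps
    sOut <- seq(0, max(arc), by = ds)
    cbind(arc = sOut,
          z = stats::approx(arc, z, xout = sOut)$y,
          y = stats::approx(arc, y, xout = sOut)$y,
          x = rep(x0, length(sOut)))
}

#' Generate a synthetic esophagus phantom
#'
#' Voxelizes the tube described by a [phantomSpec()]: the mask is the union
#' of wall and lumen voxels; the CT assigns approximately -1000 HU to the
#' lumen (air), 40 HU to the wall (soft tissue) and -80 HU to the background
#' (mediastinal fat), plus Gaussian noise. Ground truth records the analytic
#' centerline, the per-segment cancer labels under the 5 cm / 10 cm /
#' remainder division rule, and the patient-level label (any segment
#' positive).
#'
#' @param spec a [phantomSpec()].
#' @return A list with elements `ct` ([CTVolume-class]), `mask`
#'   ([BinaryMask-class]) and `truth` (list: `centerline` matrix of mm points
#'   with arc, `segment_labels` named logical for upper/middle/lower,
#'   `patient_label`, `lesions`).
#' @examples
#' ph <- generatePhantom(phantomSpec(length_mm = 120,
#'                                   grid_shape = c(32, 48, 48)))
#' ph$truth$patient_label
#' @export
generatePhantom <- function(spec) {
    stopifnot(inherits(spec, "PhantomSpec"))
    axis <- .phantomAxis(spec)
    thick <- .phantomThicknessAt(spec, axis[, "arc"])
    rmax <- spec$lumen_radius_mm + max(thick) + 2
    d <- spec$grid_shape; sp <- spec$spacing

    ys <- (seq_len(d[2]) - 1) * sp[2]
    xs <- (seq_len(d[3]) - 1) * sp[3]
    yg <- matrix(ys, d[2], d[3])
    xg <- matrix(xs, d[2], d[3], byrow = TRUE)

    lumen <- array(FALSE, d); wall <- array(FALSE, d)
    for (i in seq_len(d[1])) {
        zi <- (i - 1) * sp[1]
        cand <- which(abs(axis[, "z"] - zi) <= rmax)
        if (!length(cand)) next
        d2min <- matrix(Inf, d[2], d[3]); amin <- matrix(1L, d[2], d[3])
        for (ci in cand) {
            d2 <- (zi - axis[ci, "z"])^2 + (yg - axis[ci, "y"])^2 +
                  (xg - axis[ci, "x"])^2
            upd <- d2 < d2min
            d2min[upd] <- d2[upd]; amin[upd] <- ci
        }
        r <- sqrt(d2min)
        lum <- r <= spec$lumen_radius_mm
        wal <- !lum & r <= spec$lumen_radius_mm + thick[amin]
        # flat tube ends: drop voxels projecting beyond the first/last axis
        # sample along the end tangents (no spherical end caps)
        nAx <- nrow(axis)
        t1 <- axis[2, c("z", "y", "x")] - axis[1, c("z", "y", "x")]
        tn <- axis[nAx, c("z", "y", "x")] - axis[nAx - 1, c("z", "y", "x")]
        pr1 <- (zi - axis[1, "z"]) * t1[1] + (yg - axis[1, "y"]) * t1[2] +
               (xg - axis[1, "x"]) * t1[3]
        prn <- (zi - axis[nAx, "z"]) * tn[1] + (yg - axis[nAx, "y"]) * tn[2] +
               (xg - axis[nAx, "x"]) * tn[3]
        beyond <- (amin == 1L & pr1 < 0) | (amin == nAx & prn > 0)
        lum <- lum & !beyond
        wal <- wal & !beyond
        lumen[i, , ] <- lum
        wall[i, , ] <- wal
    }

    # polypoid lesions: hemispherical nodule seated on the inner wall,
    # protruding into the lumen along the +x normal (always perpendicular to
    # the planar tube axis)
    for (l in spec$lesions) {
        if (l$kind != "polypoid") next
        ai <- which.min(abs(axis[, "arc"] - l$center_arc_mm))
        ctr <- c(axis[ai, "z"], axis[ai, "y"],
                 axis[ai, "x"] + spec$lumen_radius_mm)
        rr <- l$delta_thickness_mm
        zi <- which(abs((seq_len(d[1]) - 1) * sp[1] - ctr[1]) <= rr)
        for (i in zi) {
            dz2 <- ((i - 1) * sp[1] - ctr[1])^2
            d2 <- dz2 + (yg - ctr[2])^2 + (xg - ctr[3])^2
            inb <- d2 <= rr^2
            wall[i, , ] <- wall[i, , ] | inb
            lumen[i, , ] <- lumen[i, , ] & !inb
        }
    }

    ct <- array(-80, d)
    ct[lumen] <- -1000
    ct[wall] <- 40
    if (spec$noise_sd_hu > 0)
        ct <- ct + .withSeed(spec$seed,
                             array(stats::rnorm(prod(d), 0, spec$noise_sd_hu), d))

    maskArr <- array(0L, d); maskArr[lumen | wall] <- 1L

    segs <- c(upper = FALSE, middle = FALSE, lower = FALSE)
    for (l in spec$lesions) {
        s <- l$center_arc_mm
        seg <- if (s < 50) "upper" else if (s < 150) "middle" else "lower"
        segs[seg] <- TRUE
    }
    truth <- list(
        centerline = axis[seq(1, nrow(axis), by = 2), c("arc", "z", "y", "x")],
        segment_labels = segs,
        patient_label = any(segs),
        lesions = spec$lesions)

    list(ct = CTVolume(ct, spacing = sp),
         mask = BinaryMask(maskArr, spacing = sp),
         truth = truth)
}

# Deterministic per-case seeds and lesion parameter draws for a cohort.
.cohortDraws <- function(n_pos, n_neg, effect, seed, L) {
    n <- n_pos + n_neg
    kinds <- c("focal_thickening", "polypoid", "generalized_thickening")
    .withSeed(seed, {
        caseSeeds <- sample.int(2^31 - 2, n)
        lapply(seq_len(n), function(i) {
            if (i > n_pos) return(list(seed = caseSeeds[i], lesions = list()))
            kind <- if (identical(effect$kind, "mixed")) sample(kinds, 1)
                    else effect$kind
            list(seed = caseSeeds[i], lesions = list(lesionSpec(
                kind = kind,
                center_arc_mm = stats::runif(1, 25, L - 25),
                extent_mm = stats::runif(1, effect$extent_range[1],
                                         effect$extent_range[2]),
                delta_thickness_mm = stats::runif(1, effect$delta_range[1],
                                                  effect$delta_range[2]))))
        })
    })
}

#' Generate a cohort of phantoms with and without lesions
#'
#' Draws lesion parameters case by case from the effect configuration and
#' generates `n_pos` lesioned and `n_neg` clean phantoms, each with a
#' deterministic per-case seed derived from the master seed. Lesion added
#' thickness defaults to Uniform(2, 6) mm; longitudinal extent to
#' Uniform(20, 50) mm, in the range of reported esophageal-cancer lengths.
#'
#' @param n_pos,n_neg numbers of lesioned and lesion-free cases.
#' @param effect list: `kind` (lesion morphology, or `"mixed"` to sample one
#'   of the three per case), `delta_range`, `extent_range` (mm).
#' @param seed master seed.
#' @param spec_base a [phantomSpec()] providing geometry defaults for every
#'   case (its `lesions` and `seed` are overridden).
#' @param dir optional directory; when given, each case's CT and mask are
#'   written as NIfTI and a `manifest.csv` is written alongside.
#' @return A list with `manifest` (data.frame: case_id, per-segment truth,
#'   patient label, lesion parameters, file paths when written) and `cases`
#'   (list of in-memory phantoms, `NULL` for each case when `dir` is given).
#' @export
generateCohort <- function(n_pos, n_neg,
                           effect = list(kind = "focal_thickening",
                                         delta_range = c(2, 6),
                                         extent_range = c(20, 50)),
                           seed = 1L, spec_base = phantomSpec(), dir = NULL) {
    if (n_pos < 0 || n_neg < 0) stop("negative counts", call. = FALSE)
    n <- n_pos + n_neg
    draws <- .cohortDraws(n_pos, n_neg, effect, seed, spec_base$length_mm)
    cases <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        sp <- spec_base
        sp$lesions <- draws[[i]]$lesions
        sp$seed <- draws[[i]]$seed
        ph <- generatePhantom(sp)
        id <- sprintf("case%03d", i)
        les <- if (length(sp$lesions)) sp$lesions[[1]] else NULL
        ctPath <- maskPath <- NA_character_
        if (!is.null(dir)) {
            if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
            ctPath <- file.path(dir, paste0(id, "_ct.nii.gz"))
            maskPath <- file.path(dir, paste0(id, "_mask.nii.gz"))
            writeVolume(ph$ct, ctPath)
            writeMask(ph$mask, maskPath)
            cases[i] <- list(NULL)
        } else cases[[i]] <- ph
        rows[[i]] <- data.frame(
            case_id = id,
            patient_label = ph$truth$patient_label,
            upper = ph$truth$segment_labels[["upper"]],
            middle = ph$truth$segment_labels[["middle"]],
            lower = ph$truth$segment_labels[["lower"]],
            lesion_kind = if (is.null(les)) NA_character_ else les$kind,
            lesion_center_arc_mm = if (is.null(les)) NA_real_ else les$center_arc_mm,
            lesion_extent_mm = if (is.null(les)) NA_real_ else les$extent_mm,
            lesion_delta_mm = if (is.null(les)) NA_real_ else les$delta_thickness_mm,
            seed = sp$seed,
            ct_path = ctPath, mask_path = maskPath,
            stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    if (!is.null(dir))
        utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                         row.names = FALSE)
    list(manifest = manifest, cases = cases)
}
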