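# Geometry fixtures built in code. Heavy shared objects are cached for the
# test run.

.fixtures <- new.env(parent = emptyenv())

fixCached <- function(name, expr) {
    if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
    get(name, envir = .fixtures)
}

# straight cylinder along z with flat ends, 1 mm grid
makeStraightTube <- function(lengthMm = 200, radiusMm = 7,
                             pad = 5, inPlane = 24) {
    d <- c(lengthMm + 2 * pad, inPlane, inPlane)
    ctr <- (inPlane + 1) / 2
    g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
    r <- sqrt((g$y - ctr)^2 + (g$x - ctr)^2)
    v <- array(as.integer(r <= radiusMm & g$z > pad & g$z <= pad + lengthMm), d)
    BinaryMask(v, spacing = c(1, 1, 1))
}

# quarter torus in the z=const plane: major radius R, tube radius r
makeQuarterTorus <- function(R = 40, r = 5) {
    d <- c(2 * r + 10, R + r + 15, R + r + 15)
    g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
    zz <- g$z - (d[1] + 1) / 2
    yy <- g$y - 5.5
    xx <- g$x - 5.5
    ang <- atan2(yy, xx)
    rad <- sqrt(yy^2 + xx^2)
    v <- array(as.integer(sqrt((rad - R)^2 + zz^2) <= r &
                          ang >= 0 & ang <= pi / 2 & yy >= 0 & xx >= 0), d)
    BinaryMask(v, spacing = c(1, 1, 1))
}

# analytic 2D annulus plane (1 = wall), pixel size px
makeAnnulusPlane <- function(router, rinner, px) {
    n <- ceiling(2 * router / px) + 9
    ctr <- (n + 1) / 2
    g <- expand.grid(i = 1:n, j = 1:n)
    r <- sqrt((g$i - ctr)^2 + (g$j - ctr)^2) * px
    matrix(as.integer(r <= router & r > rinner), n, n)
}

makeDiskPlane <- function(radius, px) makeAnnulusPlane(radius, -1, px)

# axis-aligned cube mask
makeCubeMask <- function(dim3 = c(20, 20, 20), from = c(5, 5, 5),
                         sizeVox = 10, spacing = c(1, 1, 1)) {
    v <- array(0L, dim3)
    v[from[1]:(from[1] + sizeVox - 1), from[2]:(from[2] + sizeVox - 1),
      from[3]:(from[3] + sizeVox - 1)] <- 1L
    BinaryMask(v, spacing = spacing)
}

# reduced phantom geometry for fast end-to-end tests
testPhantomSpec <- function(...) {
    phantomSpec(length_mm = 180, grid_shape = c(44L, 72L, 48L),
                curvature = list(amplitude_mm = 10, period_mm = 150), ...)
}

fixCleanPhantom <- function() fixCached("cleanPhantom",
    generatePhantom(testPhantomSpec(seed = 101L)))

fixLesionPhantom <- function() fixCached("lesionPhantom",
    generatePhantom(testPhantomSpec(
        lesions = list(lesionSpec("focal_thickening", center_arc_mm = 80,
                                  extent_mm = 30, delta_thickness_mm = 4)),
        seed = 102L)))

fixTestConfig <- function() {
    cfg <- defaultPipelineConfig()
    cfg$plane_half_width_mm <- 16
    cfg
}

# small cohort + its per-segment feature table, shared by classifier and
# pipeline tests
fixSmallCohort <- function() fixCached("smallCohort",
    generateCohort(6, 6,
                   effect = list(kind = "focal_thickening",
                                 delta_range = c(3, 6),
                                 extent_range = c(20, 45)),
                   seed = 7L, spec_base = testPhantomSpec()))

fixSmallFeatures <- function() fixCached("smallFeatures",
    esoMorph:::.cohortFeatureTable(fixSmallCohort(), fixTestConfig()))
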