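test_that("lesion placement drives segment and patient ground truth", {
    # no lesions: everything negative
    clean <- fixCleanPhantom()
    expect_false(any(clean$truth$segment_labels))
    expect_false(clean$truth$patient_label)

    # a lesion centred at 80 mm falls in the middle segment [50, 150)
    les <- fixLesionPhantom()
    expect_identical(unname(les$truth$segment_labels),
                     c(FALSE, TRUE, FALSE))
    expect_true(les$truth$patient_label)

    # patient label is the OR over segments for a mixed set of lesions
    for (arc in c(30, 100, 160)) {
        ph <- generatePhantom(phantomSpec(
            length_mm = 200, grid_shape = c(48L, 72L, 48L), noise_sd_hu = 0,
            lesions = list(lesionSpec("focal_thickening", arc, 20, 3))))
        expect_identical(ph$truth$patient_label,
                         any(ph$truth$segment_labels))
        seg <- c("upper", "middle", "lower")[findInterval(arc, c(0, 50, 150))]
        expect_true(ph$truth$segment_labels[[seg]])
    }

    expect_error(phantomSpec(length_mm = 100, lesions = list(
        lesionSpec("focal_thickening", 150, 20, 3))), "outside tube length")
})

test_that("phantom generation is seed-deterministic", {
    sp <- testPhantomSpec(seed = 33L)
    a <- generatePhantom(sp)
    b <- generatePhantom(sp)
    expect_identical(voxels(a$ct), voxels(b$ct))
    expect_identical(voxels(a$mask), voxels(b$mask))

    d1 <- generateCohort(3, 3, seed = 5L, spec_base = testPhantomSpec())
    d2 <- generateCohort(3, 3, seed = 5L, spec_base = testPhantomSpec())
    expect_identical(d1$manifest, d2$manifest)
})

test_that("tissue HU classes are separable before noise", {
    ph <- generatePhantom(testPhantomSpec(noise_sd_hu = 0, seed = 1L))
    ct <- voxels(ph$ct); mask <- voxels(ph$mask)
    lumen <- mask == 1L & ct < -500
    wall <- mask == 1L & ct >= -500
    expect_gt(sum(lumen), 0)
    expect_true(all(ct[lumen] < -500))
    expect_true(all(ct[wall] > -200))
})

test_that("voxelized ring thickness matches the analytic baseline", {
    # straight phantom, no noise: a native mid-tube transverse slice is an
    # annulus of outer radius lumen + wall
    sp <- phantomSpec(length_mm = 150, grid_shape = c(40L, 64L, 64L),
                      curvature = list(amplitude_mm = 0, period_mm = 150),
                      noise_sd_hu = 0,
                      spacing = c(5, 0.8, 0.8))
    ph <- generatePhantom(sp)
    wall <- voxels(ph$mask) == 1L & voxels(ph$ct) > -200
    mid <- round(dim(wall)[1] / 2)
    cs <- measureCrossSection(wall[mid, , ] * 1L, 0.8)
    expect_lt(abs(cs$wall_thickness_mm - sp$wall_thickness_mm), 0.8)
    expect_lt(abs(cs$outer_diameter_mm -
                  2 * (sp$lumen_radius_mm + sp$wall_thickness_mm)), 0.8)
})

test_that("cohort composition and lesion-size distribution are as configured", {
    coh <- fixSmallCohort()
    man <- coh$manifest
    expect_identical(nrow(man), 12L)
    expect_identical(sum(man$patient_label), 6L)
    expect_true(all(is.na(man$lesion_delta_mm[!man$patient_label])))

    neg <- generateCohort(0, 5, seed = 2L, spec_base = testPhantomSpec())
    expect_false(any(neg$manifest$patient_label))
    expect_error(generateCohort(-1, 3), "negative counts")

    # Monte-Carlo check of the Uniform(2, 6) mm thickness-delta draw
    draws <- esoMorph:::.cohortDraws(
        1000, 0, effect = list(kind = "focal_thickening",
                               delta_range = c(2, 6),
                               extent_range = c(20, 50)),
        seed = 99L, L = 250)
    deltas <- vapply(draws, function(d) d$lesions[[1]]$delta_thickness_mm,
                     numeric(1))
    se <- sqrt((6 - 2)^2 / 12 / 1000)
    expect_lt(abs(mean(deltas) - 4), 3 * se)
    expect_true(all(deltas >= 2 & deltas <= 6))
})
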