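# synthetic per-segment feature table with a controllable signal column
mkFeatures <- function(n, sep = TRUE, seed = 1) {
    set.seed(seed)
    seg <- rep(c("upper", "middle", "lower"), length.out = n)
    v <- runif(n, 0, 4)
    lab <- rep(c(FALSE, TRUE), length.out = n)
    if (sep) v <- v + ifelse(lab, 6, 0)  # perfectly separated at ~5
    data.frame(case_id = sprintf("p%02d", seq_len(n)), segment = seg,
               n_planes = 20L, mean_outer_mm = rnorm(n, 14, 0.2),
               var_outer_mm2 = runif(n, 0, 1), mean_thickness_mm = 3,
               var_thickness_mm2 = v, max_thickness_mm = 3 + sqrt(v),
               missing = FALSE, label = lab, stringsAsFactors = FALSE)
}

test_that("a perfectly separable feature yields a depth-1 pure tree", {
    ft <- mkFeatures(40)
    m <- fitSegmentTree(ft, treeConfig(max_depth = 3, min_leaf = 5))
    pred <- predictSegments(m, ft)
    expect_identical(pred$pred_label, ft$label)         # training accuracy 1
    expect_identical(sum(!m@nodes$leaf), 1L)            # single split
    split <- m@nodes[!m@nodes$leaf, ]
    expect_identical(split$var, "var_thickness_mm2")
    # pure leaves predict with probability 1
    expect_true(all(pred$prob_pos %in% c(0, 1)))
})

test_that("degenerate training inputs are rejected", {
    ft <- mkFeatures(20)
    ft$label <- TRUE
    expect_error(fitSegmentTree(ft), "single class")
    expect_error(fitSegmentTree(ft[0, ]), "empty feature table")
    ft2 <- mkFeatures(20)
    ft2$var_thickness_mm2[3] <- NA
    expect_error(fitSegmentTree(ft2), "missing values")
})

test_that("node impurity matches the closed form", {
    expect_equal(giniImpurity(c(0, 0, 1, 1)), 0.5)
    expect_equal(giniImpurity(rep(1, 7)), 0)
    expect_equal(giniImpurity(c(0, 1, 1, 1)), 1 - 0.25^2 - 0.75^2)
})

test_that("prediction is deterministic and propagates missing segments", {
    ft <- mkFeatures(30)
    m <- fitSegmentTree(ft)
    p1 <- predictSegments(m, ft)
    p2 <- predictSegments(m, ft)
    expect_identical(p1$prob_pos, p2$prob_pos)

    # two cases with identical features get identical predictions
    ft2 <- ft[c(1, 1), ]; ft2$case_id <- c("a", "b")
    p <- predictSegments(m, ft2)
    expect_identical(p$prob_pos[1], p$prob_pos[2])

    # a missing middle segment stays missing, never negative
    ft3 <- ft[1:3, ]
    ft3$missing[2] <- TRUE
    ft3[2, c("mean_outer_mm", "var_outer_mm2", "mean_thickness_mm",
             "var_thickness_mm2", "max_thickness_mm")] <- NA
    p <- predictSegments(m, ft3)
    expect_true(is.na(p$pred_label[2]))
    expect_false(any(is.na(p$pred_label[c(1, 3)])))

    expect_error(predictSegments(m, ft[, !names(ft) %in% "var_outer_mm2"]),
                 "schema mismatch")
})

test_that("patient aggregation is the any-positive rule and is monotone", {
    mk <- function(labels, probs = as.numeric(labels)) {
        data.frame(segment = c("upper", "middle", "lower"),
                   prob_pos = probs, pred_label = labels)
    }
    expect_false(aggregatePatient(mk(c(FALSE, FALSE, FALSE)))$patient_label)
    expect_true(aggregatePatient(mk(c(FALSE, TRUE, FALSE)))$patient_label)
    expect_warning(
        agg <- aggregatePatient(mk(c(FALSE, NA, NA), c(0.2, NA, NA))),
        "missing")
    expect_false(agg$patient_label)
    expect_error(aggregatePatient(mk(c(NA, NA, NA), rep(NA_real_, 3))),
                 "all segments missing")

    # monotone: flipping any segment negative->positive never flips the
    # patient positive->negative
    for (base in list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE))) {
        before <- aggregatePatient(mk(base))$patient_label
        for (i in 1:3) {
            up <- base; up[i] <- TRUE
            after <- aggregatePatient(mk(up))$patient_label
            expect_true(after >= before)
        }
    }
})

test_that("threshold learning adapts to monotone feature transforms", {
    ft <- mkFeatures(40)
    m0 <- fitSegmentTree(ft)
    acc0 <- mean(predictSegments(m0, ft)$pred_label == ft$label)
    ft2 <- ft
    ft2$var_thickness_mm2 <- exp(ft2$var_thickness_mm2 / 3)  # strictly monotone
    m1 <- fitSegmentTree(ft2)
    acc1 <- mean(predictSegments(m1, ft2)$pred_label == ft2$label)
    expect_equal(acc1, acc0)
})

test_that("cross-validation partitions patients and is seed-stable", {
    ft <- mkFeatures(60, seed = 4)
    ft$patient_label <- ft$label  # one segment per synthetic patient here
    cv <- crossValidate(ft, k = 5, seed = 11L)
    # every patient appears in exactly one test fold
    expect_identical(sort(unique(cv$patients$case_id)), sort(ft$case_id))
    expect_identical(nrow(cv$patients), length(unique(ft$case_id)))
    expect_identical(sort(unique(cv$patients$fold)), 1:5)

    cv2 <- crossValidate(ft, k = 5, seed = 11L)
    expect_identical(cv$folds, cv2$folds)
    expect_identical(cv$pooled, cv2$pooled)

    expect_error(crossValidate(ft[1:9, ], k = 5, seed = 1L), "exceeds")
})

test_that("JSON serialization round-trips to an identical tree", {
    ft <- mkFeatures(40, seed = 2)
    m <- fitSegmentTree(ft)
    path <- withr::local_tempfile(fileext = ".json")
    writeTreeModel(m, path)
    m2 <- readTreeModel(path)
    expect_equal(m2@nodes, m@nodes, tolerance = 1e-12)
    expect_identical(m2@schema, m@schema)
    p1 <- predictSegments(m, ft)
    p2 <- predictSegments(m2, ft)
    expect_identical(p1$prob_pos, p2$prob_pos)
    expect_identical(p1$pred_label, p2$pred_label)

    # refuse foreign JSON
    bad <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(a = 1), bad)
    expect_error(readTreeModel(bad), "not a serialized tree model")
})
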