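test_that("confusion counts partition the cases", {
    cc <- confusionCounts(c(rep(TRUE, 6), rep(FALSE, 4)),
                          c(rep(TRUE, 6), rep(FALSE, 4)))
    expect_identical(cc[c("TP", "TN", "FP", "FN")],
                     list(TP = 6L, TN = 4L, FP = 0L, FN = 0L))

    allPos <- confusionCounts(rep(TRUE, 200), rep(c(TRUE, FALSE), each = 100))
    expect_identical(allPos$TP, 100L)
    expect_identical(allPos$FP, 100L)

    expect_error(confusionCounts(logical(0), logical(0)), "empty input")
    expect_error(confusionCounts(c(TRUE), c(TRUE, FALSE)), "length mismatch")
    expect_error(confusionCounts(c(0, 2), c(0, 1)), "non-binary")
})

test_that("diagnostic metrics reproduce printed reader-study rows", {
    # model row: sens 0.900 / spec 0.880 on a 100/100 split
    m <- diagnosticMetrics(list(TP = 90, FN = 10, TN = 88, FP = 12))
    expect_equal(round(m$sensitivity, 3), 0.900)
    expect_equal(round(m$specificity, 3), 0.880)
    expect_equal(round(m$f1, 3), 0.891)
    expect_equal(round(m$auc, 3), 0.890)

    # second reader: sens 0.780 / spec 0.870
    m2 <- diagnosticMetrics(list(TP = 78, FN = 22, TN = 87, FP = 13))
    expect_equal(round(m2$f1, 3), 0.817)

    # chance performance
    m3 <- diagnosticMetrics(list(TP = 25, FN = 25, TN = 25, FP = 25))
    expect_equal(m3$sensitivity, 0.5)
    expect_equal(m3$specificity, 0.5)
    expect_equal(m3$f1, 0.5)
    expect_equal(m3$auc, 0.5)

    # zero denominators surface as NA, not silent zeros
    m4 <- diagnosticMetrics(list(TP = 0, FN = 0, TN = 5, FP = 5))
    expect_true(is.na(m4$sensitivity))
    expect_true(is.na(m4$auc))
})

test_that("metric identities hold for arbitrary counts", {
    set.seed(8)
    for (i in 1:50) {
        cc <- list(TP = rpois(1, 30) + 1, TN = rpois(1, 30) + 1,
                   FP = rpois(1, 10), FN = rpois(1, 10))
        m <- diagnosticMetrics(cc)
        expect_equal(m$fnr, 1 - m$sensitivity)
        expect_equal(m$fpr, 1 - m$specificity)
        expect_identical(m$recall, m$sensitivity)
        expect_equal(m$auc, (m$sensitivity + m$specificity) / 2)
        expect_gte(m$f1, 0); expect_lte(m$f1, 1)
        expect_equal(m$accuracy,
                     (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN))
    }
})

test_that("rank AUC equals the exhaustive pair-count oracle", {
    expect_equal(aucFromScores(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
    expect_error(aucFromScores(1:4, rep(1, 4)), "both classes")

    set.seed(21)
    for (i in 1:60) {
        n <- sample(4:50, 1)
        lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
        sc <- sample(seq_len(8), n, replace = TRUE)   # heavy ties
        pos <- sc[lab]; neg <- sc[!lab]
        oracle <- (sum(outer(pos, neg, ">")) +
                   0.5 * sum(outer(pos, neg, "=="))) /
                  (length(pos) * length(neg))
        expect_identical(aucFromScores(sc, lab), oracle)
    }

    # Monte-Carlo null: random scores give AUC ~ 0.5
    set.seed(5)
    auc <- aucFromScores(rnorm(4000), rep(c(TRUE, FALSE), each = 2000))
    expect_lt(abs(auc - 0.5), 0.03)
})

test_that("DeLong test agrees with an independent implementation", {
    set.seed(14)
    lab <- rep(c(1, 0), each = 80)
    a <- rnorm(160) + lab
    b <- rnorm(160) + 0.6 * lab
    dt <- delongTest(a, b, lab)
    rt <- pROC::roc.test(pROC::roc(lab, a, quiet = TRUE),
                         pROC::roc(lab, b, quiet = TRUE), method = "delong")
    expect_equal(dt$z, unname(rt$statistic), tolerance = 1e-9)
    expect_equal(dt$p, rt$p.value, tolerance = 1e-9)
    expect_equal(dt$auc_a, as.numeric(rt$estimate[1]), tolerance = 1e-12)
})

test_that("DeLong test is symmetric and degenerates sanely", {
    set.seed(3)
    lab <- rep(c(TRUE, FALSE), each = 40)
    a <- rnorm(80) + lab; b <- rnorm(80)
    d1 <- delongTest(a, b, lab)
    d2 <- delongTest(b, a, lab)
    expect_equal(d1$z, -d2$z)
    expect_equal(d1$p, d2$p)

    di <- delongTest(a, a, lab)
    expect_identical(di$z, 0)
    expect_identical(di$p, 1)

    expect_error(delongTest(a, b[-1], lab), "unpaired")
})

test_that("DeLong agrees with a paired-bootstrap AUC-difference test", {
    set.seed(77)
    lab <- rep(c(TRUE, FALSE), each = 100)
    a <- rnorm(200) + 0.9 * lab
    b <- rnorm(200) + 0.55 * lab
    dt <- delongTest(a, b, lab)
    # bootstrap null distribution of the AUC difference (percentile CI test)
    B <- 800
    diffs <- replicate(B, {
        i <- sample(200, replace = TRUE)
        while (length(unique(lab[i])) < 2) i <- sample(200, replace = TRUE)
        aucFromScores(a[i], lab[i]) - aucFromScores(b[i], lab[i])
    })
    pBoot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    se <- sqrt(max(pBoot, 1 / B) * (1 - min(pBoot, 1 - 1 / B)) / B)
    expect_lt(abs(dt$p - pBoot), max(0.08, 4 * se))
})

test_that("ICC(2,1) matches a hand-computed ANOVA table and recovers rho", {
    # worked 6 x 2 example against aov mean squares
    r6 <- matrix(c(9, 2, 5, 8, 6, 7, 8, 4, 7, 7, 5, 8), 6, 2)
    df <- data.frame(y = as.vector(r6), case = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
    ms <- summary(stats::aov(y ~ case + rater, df))[[1]][, "Mean Sq"]
    n <- 6; k <- 2
    oracle <- (ms[1] - ms[3]) /
        (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
    a <- iccAgreement(r6)
    expect_equal(a$icc, unname(oracle), tolerance = 1e-4)
    expect_lte(a$ci["low"], a$icc)
    expect_gte(a$ci["high"], a$icc)
    expect_match(a$model, "ICC\\(2,1\\)")

    # identical non-constant raters: perfect agreement
    x <- c(3, 1, 4, 1, 5, 9)
    expect_equal(iccAgreement(cbind(x, x))$icc, 1)

    # generative recovery at n = 500, rho = 0.7
    set.seed(6)
    case <- rnorm(500, 0, sqrt(0.7))
    r <- cbind(case + rnorm(500, 0, sqrt(0.3)),
               case + rnorm(500, 0, sqrt(0.3)))
    a <- iccAgreement(r)
    se <- (a$ci["high"] - a$ci["low"]) / (2 * 1.96)
    expect_lt(abs(a$icc - 0.7), 3 * se)

    expect_error(iccAgreement(matrix(1, 10, 2)), "constant")
    expect_error(iccAgreement(matrix(1:4, 2, 2)), ">= 2 raters and >= 5")
})

test_that("Dice behaves on identical, disjoint and half-overlapping masks", {
    a <- makeCubeMask()
    expect_equal(diceCoefficient(a, a), 1)

    b <- makeCubeMask(from = c(5, 5, 15), sizeVox = 5)
    expect_equal(diceCoefficient(a, b), 0)

    # |A| = |B| = 1000, overlap 500
    h <- makeCubeMask(from = c(5, 5, 10), sizeVox = 10)
    expect_equal(diceCoefficient(a, h), 0.5)

    expect_message(
        expect_equal(diceCoefficient(BinaryMask(array(0L, c(4, 4, 4))),
                                     BinaryMask(array(0L, c(4, 4, 4)))), 1),
        "both masks empty")
    expect_error(diceCoefficient(a, BinaryMask(array(0L, c(4, 4, 4)))),
                 "grid mismatch")
})

test_that("Hausdorff distance is metric-like on offset cubes", {
    a <- makeCubeMask(dim3 = c(24, 24, 24))
    expect_equal(hausdorffDistance(a, a), 0)

    # 10 mm cubes offset by 2 mm along one axis
    b <- makeCubeMask(dim3 = c(24, 24, 24), from = c(5, 5, 7))
    h <- hausdorffDistance(a, b)
    expect_lt(abs(h - 2), 1)
    expect_identical(hausdorffDistance(b, a), h)  # symmetry

    # physical spacing is honoured
    a5 <- makeCubeMask(dim3 = c(24, 24, 24), spacing = c(1, 1, 2))
    b5 <- makeCubeMask(dim3 = c(24, 24, 24), from = c(5, 5, 7),
                       spacing = c(1, 1, 2))
    expect_lt(abs(hausdorffDistance(a5, b5) - 4), 2)

    expect_error(hausdorffDistance(a, BinaryMask(array(0L, c(24, 24, 24)))),
                 "empty mask")
})

test_that("reader-study report rows and averages follow the table convention", {
    cc <- function(sens, spec) countsFromRates(sens, spec, 100, 100)
    tab <- readerStudyReport(list(
        reader1 = cc(0.92, 0.90), reader2 = cc(0.96, 0.95),
        reader3 = cc(0.96, 0.97)))
    avg <- tab[tab$Reader == "Average", ]
    expect_equal(avg$Sensitivity, 0.947)
    expect_equal(avg$Specificity, 0.940)

    # independent-session FNR average 13.7%
    tabI <- readerStudyReport(list(
        reader1 = cc(0.86, 0.85), reader2 = cc(0.78, 0.87),
        reader3 = cc(0.95, 0.91)))
    expect_equal(tabI[tabI$Reader == "Average", "FNR"], 0.137)
    expect_equal(tabI[tabI$Reader == "Average", "FPR"], 0.123)

    # single reader: average equals the reader
    one <- readerStudyReport(list(solo = cc(0.9, 0.88)))
    expect_equal(one[one$Reader == "Average", -1],
                 one[one$Reader == "solo", -1], ignore_attr = TRUE)

    expect_error(readerStudyReport(list()), "empty input")
})
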