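#' Confusion counts from paired label vectors
#'
#' @param predicted,truth equal-length binary vectors (logical, 0/1, or
#'   "pos"/"neg").
#' @return list of class `ConfusionCounts`: `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusionCounts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusionCounts <- function(predicted, truth) {
    if (length(predicted) == 0) stop("empty input", call. = FALSE)
    if (length(predicted) != length(truth))
        stop("length mismatch", call. = FALSE)
    toBin <- function(x) {
        if (is.logical(x)) return(x)
        if (is.numeric(x)) {
            if (!all(x %in% c(0, 1))) stop("non-binary input", call. = FALSE)
            return(x == 1)
        }
        if (!all(x %in% c("pos", "neg"))) stop("non-binary input", call. = FALSE)
        x == "pos"
    }
    p <- toBin(predicted); t <- toBin(truth)
    if (anyNA(p) || anyNA(t)) stop("non-binary input", call. = FALSE)
    structure(list(TP = sum(p & t), TN = sum(!p & !t),
                   FP = sum(p & !t), FN = sum(!p & t)),
              class = "ConfusionCounts")
}

#' Build confusion counts from printed rates
#'
#' Reconstructs TP/TN/FP/FN from a reported sensitivity and specificity on a
#' known positive/negative split, e.g. the 100/100 case mix of a validation
#' reader study.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param nPos,nNeg class sizes.
#' @return A `ConfusionCounts` object (counts rounded to integers).
#' @export
countsFromRates <- function(sensitivity, specificity, nPos, nNeg) {
    stopifnot(sensitivity >= 0, sensitivity <= 1,
              specificity >= 0, specificity <= 1, nPos > 0, nNeg > 0)
    TP <- round(sensitivity * nPos); TN <- round(specificity * nNeg)
    structure(list(TP = TP, TN = TN, FP = nNeg - TN, FN = nPos - TP),
              class = "ConfusionCounts")
}

#' Diagnostic metrics from confusion counts
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, recall (= sensitivity), precision TP/(TP+FP),
#' FNR = 1 - sensitivity, FPR = 1 - specificity, F1 =
#' 2*recall*precision/(recall+precision), and the single-operating-point AUC
#' (sensitivity + specificity)/2 — the ROC area of a binary (non-scored)
#' classifier. Zero-denominator fields are returned as `NA`, never silent
#' zeros.
#'
#' @param c a `ConfusionCounts` object or list with TP/TN/FP/FN.
#' @return list of class `DiagnosticMetrics` with the nine fields.
#' @examples
#' diagnosticMetrics(confusionCounts(c(1,1,0,0), c(1,0,1,0)))
#' @export
diagnosticMetrics <- function(c) {
    TP <- c$TP; TN <- c$TN; FP <- c$FP; FN <- c$FN
    stopifnot(all(c(TP, TN, FP, FN) >= 0))
    total <- TP + TN + FP + FN
    if (total == 0) stop("no cases", call. = FALSE)
    sdiv <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- sdiv(TP, TP + FN)
    spec <- sdiv(TN, TN + FP)
    prec <- sdiv(TP, TP + FP)
    f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
        2 * sens * prec / (sens + prec) else NA_real_
    structure(list(
        sensitivity = sens, specificity = spec,
        accuracy = (TP + TN) / total, recall = sens, precision = prec,
        fnr = if (is.na(sens)) NA_real_ else 1 - sens,
        fpr = if (is.na(spec)) NA_real_ else 1 - spec,
        f1 = f1,
        auc = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2),
        class = "DiagnosticMetrics")
}

#' ROC AUC from continuous scores
#'
#' Rank-based (Mann–Whitney) AUC, identical to the trapezoidal ROC area;
#' ties contribute half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
aucFromScores <- function(scores, labels) {
    lab <- if (is.logical(labels)) labels else labels == 1 | labels == "pos"
    n1 <- sum(lab); n0 <- sum(!lab)
    if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
    r <- rank(scores)
    (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values of DeLong: V10[i] = P(score_i > neg) per positive case,
# V01[j] = P(pos > score_j) per negative case, with ties counting half.
.delongPlacements <- function(scores, lab) {
    pos <- scores[lab]; neg <- scores[!lab]
    m <- length(pos); n <- length(neg)
    v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                  numeric(1))
    v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated ROC AUCs
#'
#' Paired comparison of the AUCs of two raters/models scored on the same
#' cases, using placement-value covariance and a two-sided normal
#' approximation. Binary ratings are accepted (each rater then has a
#' single-operating-point ROC); with coarse ratings the variance estimate is
#' rank-deficient and the test is conservative.
#'
#' @param ratingsA,ratingsB numeric ratings of the same cases by two raters.
#' @param labels binary truth labels.
#' @return list: `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delongTest <- function(ratingsA, ratingsB, labels) {
    if (length(ratingsA) != length(ratingsB) ||
        length(ratingsA) != length(labels))
        stop("unpaired lengths", call. = FALSE)
    lab <- if (is.logical(labels)) labels else labels == 1 | labels == "pos"
    if (!any(lab) || all(lab)) stop("both classes required", call. = FALSE)
    pa <- .delongPlacements(ratingsA, lab)
    pb <- .delongPlacements(ratingsB, lab)
    m <- sum(lab); n <- sum(!lab)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
    d <- pa$auc - pb$auc
    z <- if (v <= .Machine$double.eps) 0 else d / sqrt(v)
    list(auc_a = pa$auc, auc_b = pb$auc, z = z,
         p = 2 * stats::pnorm(-abs(z)))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' two-way ANOVA decomposition (cases x raters, no replication), with the
#' F-distribution confidence interval of McGraw & Wong.
#'
#' @param ratings numeric matrix, cases in rows, raters in columns, no
#'   missing cells.
#' @param conf confidence level (default 0.95).
#' @return list of class `AgreementResult`: `icc`, `ci` (low, high),
#'   `model` ("ICC(2,1) absolute agreement"), mean squares.
#' @export
iccAgreement <- function(ratings, conf = 0.95) {
    ratings <- as.matrix(ratings)
    n <- nrow(ratings); k <- ncol(ratings)
    if (k < 2 || n < 5) stop("need >= 2 raters and >= 5 cases", call. = FALSE)
    if (anyNA(ratings)) stop("missing cells not supported", call. = FALSE)
    if (stats::var(as.vector(ratings)) == 0)
        stop("constant ratings: variance decomposition undefined",
             call. = FALSE)
    grand <- mean(ratings)
    rowM <- rowMeans(ratings); colM <- colMeans(ratings)
    ssr <- k * sum((rowM - grand)^2)
    ssc <- n * sum((colM - grand)^2)
    sst <- sum((ratings - grand)^2)
    sse <- sst - ssr - ssc
    msr <- ssr / (n - 1)
    msc <- ssc / (k - 1)
    mse <- sse / ((n - 1) * (k - 1))
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

    alpha <- 1 - conf
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fL <- stats::qf(1 - alpha / 2, n - 1, v)
    fU <- stats::qf(1 - alpha / 2, v, n - 1)
    low <- n * (msr - fL * mse) /
        (fL * (k * msc + (k * n - k - n) * mse) + n * msr)
    high <- n * (fU * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fU * msr)
    structure(list(icc = icc, ci = c(low = low, high = high),
                   model = "ICC(2,1) absolute agreement",
                   ms = c(msr = msr, msc = msc, mse = mse)),
              class = "AgreementResult")
}

#' Dice overlap between two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty (logged
#' via a message).
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
    .stopIfGridMismatch(a, b)
    na <- sum(a@voxels); nb <- sum(b@voxels)
    if (na + nb == 0) {
        message("both masks empty: Dice defined as 1")
        return(1)
    }
    2 * sum(a@voxels == 1L & b@voxels == 1L) / (na + nb)
}

# Boundary voxels: foreground with at least one 6-neighbour background (or
# the array edge).
.boundaryCoords <- function(mask) {
    v <- mask@voxels == 1L
    d <- dim(v)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
    inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    v & !inner
}

#' Symmetric Hausdorff distance between two masks, in mm
#'
#' Maximum distance from the boundary voxels of either mask to the nearest
#' boundary voxel of the other, on the physical (mm) grid; computed exactly
#' via the Euclidean distance transform of each boundary set.
#'
#' @param a,b nonempty [BinaryMask-class] objects on the same grid.
#' @return Hausdorff distance in mm (0 iff identical boundaries).
#' @export
hausdorffDistance <- function(a, b) {
    .stopIfGridMismatch(a, b)
    if (sum(a@voxels) == 0 || sum(b@voxels) == 0)
        stop("empty mask", call. = FALSE)
    ba <- .boundaryCoords(a); bb <- .boundaryCoords(b)
    dToB <- distanceTransform(bb, a@spacing)
    dToA <- distanceTransform(ba, a@spacing)
    max(max(dToB[ba]), max(dToA[bb]))
}

#' Reader-study report table
#'
#' One row per reader or model with the full metric set, followed by an
#' average row computed as the arithmetic mean of the per-reader metric
#' values. Reported values are rounded half-up to 3 decimals, the convention
#' of printed diagnostic tables; the unrounded table is attached as
#' attribute `"raw"`.
#'
#' @param entries named list of `ConfusionCounts` objects (e.g. one per
#'   reader plus the model).
#' @param averageOver optional character vector of entry names to average;
#'   defaults to all entries.
#' @return data.frame with columns Reader, Sensitivity, Specificity,
#'   Accuracy, F1, AUC, FNR, FPR.
#' @export
readerStudyReport <- function(entries, averageOver = names(entries)) {
    if (length(entries) == 0) stop("empty input", call. = FALSE)
    if (is.null(names(entries)) || any(names(entries) == ""))
        stop("entries must be named", call. = FALSE)
    rows <- lapply(names(entries), function(nm) {
        m <- diagnosticMetrics(entries[[nm]])
        data.frame(Reader = nm, Sensitivity = m$sensitivity,
                   Specificity = m$specificity, Accuracy = m$accuracy,
                   F1 = m$f1, AUC = m$auc, FNR = m$fnr, FPR = m$fpr,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    avg <- tab[tab$Reader %in% averageOver, -1, drop = FALSE]
    tab <- rbind(tab, cbind(Reader = "Average", as.data.frame(t(colMeans(avg)))))
    raw <- tab
    tab[, -1] <- .roundHalfUp(as.matrix(tab[, -1]), 3)
    attr(tab, "raw") <- raw
    tab
}

#' Render a report table as fixed-width text
#'
#' @param tab data.frame from [readerStudyReport()].
#' @return character vector of lines, invisibly; also printed.
#' @export
formatReport <- function(tab) {
    txt <- utils::capture.output(print(format(tab, nsmall = 3), row.names = FALSE))
    cat(txt, sep = "\n")
    invisible(txt)
}
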