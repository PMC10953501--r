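# Feature columns used for splitting, in schema order. `segment_idx` encodes
# upper/middle/lower as 1/2/3 (anatomically ordered).
.treeSchema <- c("segment_idx", "n_planes", "mean_outer_mm", "var_outer_mm2",
                 "mean_thickness_mm", "var_thickness_mm2", "max_thickness_mm")

.segmentIdx <- function(segment) {
    idx <- match(segment, c("upper", "middle", "lower"))
    if (anyNA(idx)) stop("unknown segment name", call. = FALSE)
    idx
}

#' Gini impurity of a label vector
#'
#' @param labels binary labels (logical, 0/1 or two-level factor).
#' @return `1 - sum(p^2)` over the class proportions.
#' @examples giniImpurity(c(0, 0, 1, 1))  # 0.5
#' @export
giniImpurity <- function(labels) {
    p <- table(labels) / length(labels)
    1 - sum(p^2)
}

#' Default decision-tree training configuration
#'
#' Hyperparameters for the per-segment cancer tree: Gini criterion, maximum
#' depth 3, minimum leaf size 5, balanced class weights. The feature space
#' is small (7 columns) and a shallow tree keeps the classifier readable.
#'
#' @param max_depth,min_leaf,threshold tree depth cap, minimum cases per
#'   leaf, and the probability operating point for a positive call.
#' @param balanced logical: weight classes inversely to their frequency.
#' @param seed integer training seed.
#' @return A named list.
#' @export
treeConfig <- function(max_depth = 3, min_leaf = 5, threshold = 0.5,
                       balanced = TRUE, seed = 1L) {
    stopifnot(max_depth >= 1, min_leaf >= 1, threshold > 0, threshold < 1)
    list(max_depth = max_depth, min_leaf = min_leaf, threshold = threshold,
         balanced = balanced, criterion = "gini", seed = as.integer(seed))
}

# Flatten an rpart fit to the node table the package predicts from.
.rpartToNodes <- function(fit) {
    fr <- fit$frame
    ids <- as.integer(rownames(fr))
    leaf <- fr$var == "<leaf>"
    probPos <- fr$yval2[, 5]          # weighted P(class 2 = "pos") per node
    thr <- rep(NA_real_, nrow(fr))
    leftLt <- rep(NA, nrow(fr))
    if (!all(leaf)) {
        # rows of fit$splits per internal node: 1 primary + ncompete + nsurrogate
        ix <- 1L
        for (r in which(!leaf)) {
            thr[r] <- fit$splits[ix, "index"]
            leftLt[r] <- fit$splits[ix, "ncat"] == -1
            ix <- ix + 1L + fr$ncompete[r] + fr$nsurrogate[r]
        }
    }
    data.frame(node = ids,
               var = ifelse(leaf, NA_character_, as.character(fr$var)),
               threshold = thr, left_if_lt = leftLt, leaf = leaf,
               prob_pos = probPos, n = fr$n, stringsAsFactors = FALSE)
}

#' Fit the per-segment decision tree
#'
#' Trains a CART-style tree (Gini splits, depth- and leaf-size-limited,
#' balanced class weights) on per-segment morphometry features. One pooled
#' tree is fitted across segments, with the segment index available as an
#' ordered feature. Rows flagged `missing` are dropped before fitting.
#'
#' @param features data.frame with columns `segment`, `label` (logical or
#'   "pos"/"neg"), the [computeSegmentFeatures()] columns and optionally
#'   `missing`.
#' @param config list from [treeConfig()].
#' @return A [SegmentTreeModel-class].
#' @seealso [predictSegments()], [writeTreeModel()]
#' @export
fitSegmentTree <- function(features, config = treeConfig()) {
    if (is.null(features) || nrow(features) == 0)
        stop("empty feature table", call. = FALSE)
    df <- features
    if ("missing" %in% names(df)) df <- df[!df$missing, , drop = FALSE]
    df$segment_idx <- .segmentIdx(df$segment)
    lab <- df$label
    if (!is.logical(lab)) lab <- lab %in% c("pos", "1", "TRUE", TRUE)
    if (length(unique(lab)) < 2) stop("single class", call. = FALSE)
    miss <- !stats::complete.cases(df[, .treeSchema])
    if (any(miss)) stop("missing values in used features", call. = FALSE)
    y <- factor(ifelse(lab, "pos", "neg"), levels = c("neg", "pos"))
    w <- rep(1, nrow(df))
    if (isTRUE(config$balanced)) {
        tab <- table(y)
        w <- as.numeric(length(y) / (2 * tab[y]))
    }
    dat <- df[, .treeSchema]
    dat$.y <- y
    fit <- .withSeed(config$seed,
        rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                     control = rpart::rpart.control(
                         maxdepth = config$max_depth,
                         minbucket = config$min_leaf,
                         minsplit = 2 * config$min_leaf,
                         cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0)))
    new("SegmentTreeModel", nodes = .rpartToNodes(fit), schema = .treeSchema,
        config = config, seed = as.integer(config$seed))
}

# Traverse the node table; returns P(pos) per row, NA when routing hits a
# missing feature value.
.treePredictProb <- function(model, X) {
    nd <- model@nodes
    byId <- split(seq_len(nrow(nd)), nd$node)
    vapply(seq_len(nrow(X)), function(i) {
        id <- 1L
        repeat {
            r <- nd[byId[[as.character(id)]], ]
            if (r$leaf) return(r$prob_pos)
            v <- X[i, r$var]
            if (is.na(v)) return(NA_real_)
            goLeft <- if (r$left_if_lt) v < r$threshold else v >= r$threshold
            id <- if (goLeft) 2L * id else 2L * id + 1L
        }
    }, numeric(1))
}

#' Predict cancer presence per segment
#'
#' Applies the tree to each feature row. A segment flagged missing (fewer
#' than two measured cut-planes) propagates as missing, never as a negative
#' call.
#'
#' @param model a [SegmentTreeModel-class].
#' @param features data.frame as in [fitSegmentTree()] (labels not needed).
#' @param threshold probability operating point; defaults to the trained
#'   config's (0.5 unless overridden).
#' @return `features` with columns `prob_pos`, `pred_label` (logical, NA for
#'   missing segments) appended.
#' @export
predictSegments <- function(model, features, threshold = NULL) {
    stopifnot(is(model, "SegmentTreeModel"))
    if (is.null(threshold)) threshold <- model@config$threshold
    df <- features
    df$segment_idx <- .segmentIdx(df$segment)
    if (!all(model@schema %in% names(df)))
        stop("schema mismatch: feature columns do not match training schema",
             call. = FALSE)
    X <- df[, model@schema, drop = FALSE]
    miss <- if ("missing" %in% names(df)) df$missing else rep(FALSE, nrow(df))
    prob <- rep(NA_real_, nrow(df))
    if (any(!miss)) prob[!miss] <- .treePredictProb(model, X[!miss, , drop = FALSE])
    out <- features
    out$prob_pos <- prob
    out$pred_label <- ifelse(is.na(prob), NA, prob >= threshold)
    out
}

#' Aggregate segment calls into a patient diagnosis
#'
#' Any-positive rule: the patient is called positive iff at least one
#' non-missing segment is positive; the patient probability is the maximum
#' segment probability. Missing segments are excluded; a negative call made
#' with segments missing carries a warning.
#'
#' @param segPred data.frame from [predictSegments()] for one patient.
#' @return list: `patient_label`, `patient_prob`, `n_missing`, `segments`.
#' @export
aggregatePatient <- function(segPred) {
    ok <- !is.na(segPred$pred_label)
    if (!any(ok)) stop("all segments missing", call. = FALSE)
    label <- any(segPred$pred_label[ok])
    if (!label && any(!ok))
        warning("negative patient call with missing segment(s)", call. = FALSE)
    list(patient_label = label,
         patient_prob = max(segPred$prob_pos[ok]),
         n_missing = sum(!ok),
         segments = segPred)
}

#' Cross-validate the segment classifier at patient level
#'
#' Folds are stratified by the patient label and split at patient level, so
#' all segments of a patient share a fold. For each fold a tree is trained
#' on the remaining patients and applied to the held-out ones; held-out
#' patient calls are pooled into one confusion matrix.
#'
#' @param features per-segment feature table with `case_id`, `segment`,
#'   `label` (per-segment truth), `patient_label` and the
#'   [computeSegmentFeatures()] columns.
#' @param k number of folds (default 5).
#' @param config [treeConfig()] list.
#' @param seed fold-assignment seed.
#' @return list: `pooled` ([confusionCounts()]), `pooledMetrics`
#'   ([diagnosticMetrics()]), `perFold` data.frame, `patients` data.frame of
#'   held-out patient predictions, `segments` data.frame of held-out
#'   segment predictions with fold ids.
#' @export
crossValidate <- function(features, k = 5, config = treeConfig(), seed = 1L) {
    stopifnot(k >= 2)
    pat <- unique(features[, c("case_id", "patient_label")])
    if (any(table(pat$patient_label) < k))
        stop("k exceeds the number of patients in a class", call. = FALSE)
    folds <- .withSeed(seed, {
        f <- integer(nrow(pat))
        for (lab in unique(pat$patient_label)) {
            idx <- which(pat$patient_label == lab)
            f[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        f
    })
    foldOf <- stats::setNames(folds, pat$case_id)

    patRows <- list(); segRows <- list(); perFold <- list()
    for (fold in seq_len(k)) {
        testIds <- pat$case_id[folds == fold]
        train <- features[!features$case_id %in% testIds, , drop = FALSE]
        test <- features[features$case_id %in% testIds, , drop = FALSE]
        model <- fitSegmentTree(train, config)
        pred <- predictSegments(model, test)
        pred$fold <- fold
        segRows[[fold]] <- pred
        byCase <- split(pred, pred$case_id)
        pr <- do.call(rbind, lapply(names(byCase), function(id) {
            agg <- suppressWarnings(aggregatePatient(byCase[[id]]))
            data.frame(case_id = id, fold = fold,
                       truth = byCase[[id]]$patient_label[1],
                       pred = agg$patient_label, prob = agg$patient_prob,
                       stringsAsFactors = FALSE)
        }))
        patRows[[fold]] <- pr
        cc <- confusionCounts(pr$pred, pr$truth)
        m <- diagnosticMetrics(cc)
        perFold[[fold]] <- data.frame(fold = fold, n = nrow(pr),
                                      sensitivity = m$sensitivity,
                                      specificity = m$specificity,
                                      accuracy = m$accuracy, f1 = m$f1)
    }
    patients <- do.call(rbind, patRows)
    pooled <- confusionCounts(patients$pred, patients$truth)
    list(pooled = pooled, pooledMetrics = diagnosticMetrics(pooled),
         perFold = do.call(rbind, perFold), patients = patients,
         segments = do.call(rbind, segRows), folds = foldOf)
}

#' Serialize / restore a tree model as versioned JSON
#'
#' The JSON carries the node table, feature schema, training config and
#' seed. Because prediction traverses the node table, a model read back
#' predicts identically to the one written.
#'
#' @param model a [SegmentTreeModel-class].
#' @param path JSON file path.
#' @return `writeTreeModel`: the path, invisibly. `readTreeModel`: the
#'   restored [SegmentTreeModel-class].
#' @export
writeTreeModel <- function(model, path) {
    stopifnot(is(model, "SegmentTreeModel"))
    obj <- list(format = "esoMorph-tree", version = 1L,
                schema = model@schema, config = model@config,
                seed = model@seed, nodes = model@nodes)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeTreeModel
#' @export
readTreeModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "esoMorph-tree"))
        stop("not a serialized tree model", call. = FALSE)
    nd <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    nd$var <- as.character(nd$var)
    new("SegmentTreeModel", nodes = nd, schema = obj$schema,
        config = obj$config, seed = as.integer(obj$seed))
}
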