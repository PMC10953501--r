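#' Default pipeline configuration
#'
#' All tunable pipeline parameters with their defaults: air-removal
#' threshold -500 HU (midway between air and soft tissue), 1 mm isotropic
#' resampling for medial analysis, 5-point centerline smoothing, 2.5 mm
#' cut-plane sampling (half the routine slice thickness), 20 mm plane
#' half-width at 1 mm pixels, the 50 mm / 100 mm upper/middle segment rule,
#' and the [treeConfig()] hyperparameters.
#'
#' @return A nested named list of class `PipelineConfig`.
#' @seealso [readPipelineConfig()], [runCase()], [runExperiment()]
#' @export
defaultPipelineConfig <- function() {
    structure(list(
        hu_threshold = -500,
        iso_mm = 1,
        smooth_window = 5L,
        step_mm = 2.5,
        plane_half_width_mm = 20,
        plane_pixel_mm = 1,
        end_margin_mm = 2.5,
        segment_upper_mm = 50,
        segment_middle_mm = 100,
        tree = treeConfig(),
        seed = 1L), class = "PipelineConfig")
}

.validateConfig <- function(config) {
    need <- names(defaultPipelineConfig())
    missing <- setdiff(need, names(config))
    if (length(missing))
        stop("config missing fields: ", paste(missing, collapse = ", "),
             call. = FALSE)
    with(config, stopifnot(
        hu_threshold > -1000, iso_mm > 0, step_mm > 0,
        plane_half_width_mm > 0, plane_pixel_mm > 0,
        segment_upper_mm > 0, segment_middle_mm > 0, smooth_window >= 1))
    invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round-trips losslessly; unknown keys are rejected and missing
#' keys are an error, so a config file fully determines a run.
#'
#' @param path YAML file path.
#' @param config a config list as from [defaultPipelineConfig()].
#' @return `readPipelineConfig`: the validated config list.
#' @export
readPipelineConfig <- function(path) {
    config <- yaml::read_yaml(path)
    extra <- setdiff(names(config), names(defaultPipelineConfig()))
    if (length(extra))
        stop("unknown config fields: ", paste(extra, collapse = ", "),
             call. = FALSE)
    config$smooth_window <- as.integer(config$smooth_window)
    config$seed <- as.integer(config$seed)
    config$tree$seed <- as.integer(config$tree$seed)
    structure(.validateConfig(config), class = "PipelineConfig")
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

# Stable hash of a config for provenance lines in reports.
.configHash <- function(config) {
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(unclass(config), tf)
    unname(tools::md5sum(tf))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Morphometry feature extraction for one case
#'
#' Runs the measurement chain on a CT + esophagus-mask pair: air removal,
#' centerline extraction, straightening of the wall mask, the per-cut-plane
#' thickness profile, segment division and per-segment features.
#'
#' @param ct a [CTVolume-class].
#' @param mask the paired [BinaryMask-class].
#' @param config a pipeline config list.
#' @return list: `features` (per-segment data.frame), `profile`,
#'   `centerline`, `qc` (truncated-plane count, skipped planes, total arc).
#' @export
caseFeatures <- function(ct, mask, config = defaultPipelineConfig()) {
    .stage("volumetric_io", .stopIfGridMismatch(mask, ct))
    wall <- .stage("wall_morphometry",
                   removeLumenAir(mask, ct, config$hu_threshold))
    cl <- .stage("centerline",
                 extractCenterline(mask, isoMm = config$iso_mm,
                                   smoothWindow = config$smooth_window))
    stack <- .stage("centerline", withCallingHandlers(
        straighten(wall, cl,
                   planeHalfWidthMm = config$plane_half_width_mm,
                   planePixelMm = config$plane_pixel_mm,
                   stepMm = config$step_mm),
        warning = function(w) invokeRestart("muffleWarning")))
    profile <- .stage("wall_morphometry",
                      suppressMessages(thicknessProfile(stack)))
    # planes straddling the organ ends cut the wall obliquely or partially;
    # keep them out of the segment features
    margin <- if (is.null(config$end_margin_mm)) 0 else config$end_margin_mm
    L <- arcLength(cl)
    featProfile <- profile[profile$arc_mm >= margin &
                           profile$arc_mm <= L - margin, , drop = FALSE]
    if (nrow(featProfile) == 0) featProfile <- profile
    bounds <- .stage("segment_features",
                     divideSegments(arcLength(cl),
                                    upperMm = config$segment_upper_mm,
                                    middleMm = config$segment_middle_mm))
    feats <- .stage("segment_features",
                    computeSegmentFeatures(featProfile, bounds))
    list(features = feats, profile = profile, centerline = cl,
         qc = list(n_truncated = sum(stack@truncated),
                   n_planes = dim(stack@planes)[3],
                   n_measured = nrow(profile),
                   arc_length_mm = arcLength(cl)))
}

#' Run the full pipeline on one case
#'
#' Feature extraction ([caseFeatures()]) followed by per-segment prediction
#' and patient-level aggregation, with a JSON case report carrying QC flags
#' and provenance (config hash, seed, package version).
#'
#' @param ct,mask objects or NIfTI file paths.
#' @param model a [SegmentTreeModel-class] or path to a serialized model.
#' @param config pipeline config list.
#' @param caseId identifier used in the report.
#' @param reportPath optional path; when given the report is written as JSON.
#' @return The case report list.
#' @export
runCase <- function(ct, mask, model, config = defaultPipelineConfig(),
                    caseId = "case", reportPath = NULL) {
    if (is.character(ct)) ct <- .stage("volumetric_io", readVolume(ct))
    if (is.character(mask)) mask <- .stage("volumetric_io", readMask(mask))
    if (is.character(model)) model <- .stage("classification",
                                             readTreeModel(model))
    cf <- caseFeatures(ct, mask, config)
    feats <- cf$features
    pred <- .stage("classification", predictSegments(model, feats))
    agg <- .stage("classification", suppressWarnings(aggregatePatient(pred)))
    report <- list(
        case_id = caseId,
        patient_label = agg$patient_label,
        patient_prob = agg$patient_prob,
        segments = pred[, c("segment", "n_planes", "mean_outer_mm",
                            "var_outer_mm2", "mean_thickness_mm",
                            "var_thickness_mm2", "max_thickness_mm",
                            "missing", "prob_pos", "pred_label")],
        qc = cf$qc,
        provenance = list(config_hash = .configHash(config),
                          seed = config$seed,
                          version = as.character(utils::packageVersion("esoMorph"))))
    if (!is.null(reportPath))
        jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                             digits = NA, na = "null", pretty = TRUE)
    report
}

# Per-segment feature table for a whole cohort, joined to truth labels.
.cohortFeatureTable <- function(cohort, config, verbose = FALSE) {
    man <- cohort$manifest
    rows <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
        ph <- cohort$cases[[i]]
        if (is.null(ph)) {
            ct <- readVolume(man$ct_path[i])
            mask <- readMask(man$mask_path[i])
        } else {
            ct <- ph$ct; mask <- ph$mask
        }
        cf <- caseFeatures(ct, mask, config)
        f <- cf$features
        f$case_id <- man$case_id[i]
        f$label <- as.logical(man[i, c("upper", "middle", "lower")])[
            match(f$segment, c("upper", "middle", "lower"))]
        f$patient_label <- man$patient_label[i]
        rows[[i]] <- f
        if (verbose) message("measured ", man$case_id[i])
    }
    do.call(rbind, rows)
}

#' Run a cohort experiment: features, cross-validated tree, metrics
#'
#' Measures every case of a cohort, cross-validates the decision tree at
#' patient level and reports pooled diagnostic metrics, per-fold metrics,
#' and segment localization accuracy — among truly positive patients that
#' were called positive, the fraction whose truly lesioned segment is among
#' the predicted-positive segments.
#'
#' @param cohort list from [generateCohort()] (or a manifest data.frame with
#'   `ct_path`/`mask_path` columns, in which case volumes are read from
#'   disk).
#' @param config pipeline config list.
#' @param k cross-validation folds (default 5).
#' @param verbose print progress.
#' @return list: `featureTable`, `cv` (see [crossValidate()]), `metrics`
#'   (pooled [diagnosticMetrics()]), `localization_accuracy`, `report`
#'   (reader-style table for the cross-validated model), `provenance`.
#' @export
runExperiment <- function(cohort, config = defaultPipelineConfig(), k = 5,
                          verbose = FALSE) {
    if (is.data.frame(cohort))
        cohort <- list(manifest = cohort,
                       cases = vector("list", nrow(cohort)))
    if (nrow(cohort$manifest) == 0) stop("empty manifest", call. = FALSE)
    ft <- .cohortFeatureTable(cohort, config, verbose)
    cv <- crossValidate(ft, k = k, config = config$tree, seed = config$seed)

    # localization among true-positive patient calls
    man <- cohort$manifest
    segs <- cv$segments
    tpIds <- cv$patients$case_id[cv$patients$truth & cv$patients$pred]
    hit <- vapply(tpIds, function(id) {
        trueSegs <- c("upper", "middle", "lower")[
            as.logical(man[man$case_id == id, c("upper", "middle", "lower")])]
        predSegs <- segs$segment[segs$case_id == id &
                                 !is.na(segs$pred_label) & segs$pred_label]
        all(trueSegs %in% predSegs)
    }, logical(1))
    locAcc <- if (length(hit)) mean(hit) else NA_real_

    list(featureTable = ft, cv = cv, metrics = cv$pooledMetrics,
         localization_accuracy = locAcc,
         report = readerStudyReport(list(model = cv$pooled)),
         provenance = list(config_hash = .configHash(config),
                           seed = config$seed, k = k))
}
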