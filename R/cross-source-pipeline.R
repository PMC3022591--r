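#' Plan a cross-source classification experiment
#'
#' @param trainSources source(s) whose samples form the training set.
#' @param validationSources source(s) validated in full (their controls and
#'   cancers); disjoint from \code{trainSources}.
#' @param thirdSource control-only source used as an independent control
#'   validation set (\code{NA} for none).
#' @param normalize apply per-source control-decile normalization (fitted
#'   on each source's own controls, including the third source) before
#'   averaging and feature selection. When on, the intensity grid is
#'   disabled.
#' @param holdoutCancer number of cancer samples drawn uniformly without
#'   replacement out of the training set and reserved for validation
#'   (mixed-set protocol).
#' @param p_grid,i_grid filter search grids.
#' @param cv_folds,seed,cost as elsewhere.
#' @return an \linkS4class{ExperimentPlan}
#' @export
experimentPlan <- function(trainSources, validationSources = character(0),
                           thirdSource = NA_character_, normalize = FALSE,
                           holdoutCancer = 0L, p_grid = defaultPGrid(),
                           i_grid = defaultIntensityGrid(), cv_folds = 10L,
                           seed = 1L, cost = 1) {
    if (length(intersect(trainSources, validationSources)))
        stop("training and validation sources must be disjoint")
    if (!is.na(thirdSource) && thirdSource %in% trainSources)
        stop("the third source may only be used for validation")
    new("ExperimentPlan", trainSources = as.character(trainSources),
        validationSources = as.character(validationSources),
        thirdSource = as.character(thirdSource), normalize = normalize,
        holdoutCancer = as.integer(holdoutCancer), pGrid = p_grid,
        iGrid = i_grid, cvFolds = as.integer(cv_folds),
        seed = as.integer(seed), cost = cost)
}

.countsRow <- function(pred, truth, cls) {
    i <- truth == cls
    c(correct = sum(pred[i] == truth[i]), total = sum(i))
}

#' Run one cross-source experiment
#'
#' Executes the full pipeline a plan describes: optional per-source
#' control-decile normalization (before averaging), replicate averaging,
#' zero-feature filtering (over all samples in the experiment, as the
#' matrix-level filter is defined), filter-cutoff optimization by
#' ten-fold CV on the training set, final training, and validation. The
#' validation MCC pools the validation source's samples with the third
#' source's controls (and any held-out cancers); cancer is the positive
#' class.
#'
#' @param plan an \linkS4class{ExperimentPlan}
#' @param x replicate-level \linkS4class{PeptidomeExperiment} containing
#'   every planned source
#' @return an \linkS4class{ExperimentReport}
#' @export
runExperiment <- function(plan, x) {
    need <- unique(c(plan@trainSources, plan@validationSources,
                     if (!is.na(plan@thirdSource)) plan@thirdSource))
    have <- unique(sampleInfo(x)$source)
    miss <- setdiff(need, have)
    if (length(miss))
        stop("planned source(s) absent from the data: ",
             paste(miss, collapse = ", "))
    x <- x[, sampleInfo(x)$source %in% need]
    if (plan@normalize)
        x <- suppressWarnings(applyQuantileMap(x, fitQuantileMap(x)))
    sm <- averageReplicates(x)
    flt <- filterZeroFeatures(sm)
    sm <- flt$experiment
    cd <- sampleInfo(sm)

    trainIdx <- which(cd$source %in% plan@trainSources)
    holdoutIdx <- integer(0)
    if (plan@holdoutCancer > 0L) {
        canc <- trainIdx[cd$class[trainIdx] == "cancer"]
        if (length(canc) < plan@holdoutCancer)
            stop("not enough cancer samples for the requested holdout")
        set.seed(plan@seed)
        holdoutIdx <- sort(sample(canc, plan@holdoutCancer))
        trainIdx <- setdiff(trainIdx, holdoutIdx)
    }
    iGrid <- if (plan@normalize) NA_real_ else plan@iGrid
    sel <- optimizeFilters(intensities(sm)[, trainIdx, drop = FALSE],
                           cd$class[trainIdx], p_grid = plan@pGrid,
                           i_grid = iGrid, cv_folds = plan@cvFolds,
                           seed = plan@seed, cost = plan@cost)
    model <- trainClassifier(intensities(sm)[, trainIdx, drop = FALSE],
                             cd$class[trainIdx], features = sel@features,
                             cost = plan@cost)
    predTrain <- predictClass(model, intensities(sm)[, trainIdx, drop = FALSE])
    training <- confusionReport(predTrain, cd$class[trainIdx])
    counts <- list(
        training_controls = .countsRow(predTrain, cd$class[trainIdx], "control"),
        training_cancers = .countsRow(predTrain, cd$class[trainIdx], "cancer"))

    valPred <- character(0); valTruth <- character(0)
    for (s in plan@validationSources) {
        i <- which(cd$source == s)
        p <- predictClass(model, intensities(sm)[, i, drop = FALSE])
        counts[[paste0("validation_", s, "_controls")]] <-
            .countsRow(p, cd$class[i], "control")
        counts[[paste0("validation_", s, "_cancers")]] <-
            .countsRow(p, cd$class[i], "cancer")
        valPred <- c(valPred, p); valTruth <- c(valTruth, cd$class[i])
    }
    if (length(holdoutIdx)) {
        p <- predictClass(model, intensities(sm)[, holdoutIdx, drop = FALSE])
        counts$validation_holdout_cancers <-
            .countsRow(p, cd$class[holdoutIdx], "cancer")
        valPred <- c(valPred, p); valTruth <- c(valTruth, cd$class[holdoutIdx])
    }
    if (!is.na(plan@thirdSource)) {
        i <- which(cd$source == plan@thirdSource & cd$class == "control")
        p <- predictClass(model, intensities(sm)[, i, drop = FALSE])
        counts[[paste0("validation_", plan@thirdSource, "_controls")]] <-
            .countsRow(p, cd$class[i], "control")
        valPred <- c(valPred, p); valTruth <- c(valTruth, cd$class[i])
    }
    validation <- if (length(valPred)) confusionReport(valPred, valTruth)
                  else NULL
    new("ExperimentReport", plan = plan, pCutoff = sel@pCutoff,
        intensityCutoff = sel@intensityCutoff,
        nFeatures = length(sel@features), cvAccuracy = sel@cvAccuracy,
        training = training, validation = validation, counts = counts,
        selectedFeatures = sel@features, model = model)
}

#' Effect of normalization on a matched pair of runs
#'
#' Compares two reports whose plans are identical except for the
#' normalization flag (and therefore the intensity grid), returning the
#' change in pooled-validation MCC and in cross-validated accuracy and
#' whether normalization improved cross-source generalization.
#'
#' @param report_no_norm,report_norm \linkS4class{ExperimentReport}s from
#'   the unnormalized and normalized runs
#' @return list(delta_validation_mcc, delta_cv_accuracy,
#'   delta_training_mcc, improved)
#' @export
compareRuns <- function(report_no_norm, report_norm) {
    a <- report_no_norm@plan; b <- report_norm@plan
    same <- identical(a@trainSources, b@trainSources) &&
        identical(a@validationSources, b@validationSources) &&
        identical(a@thirdSource, b@thirdSource) &&
        identical(a@holdoutCancer, b@holdoutCancer) &&
        identical(a@seed, b@seed)
    if (!same)
        stop("plans differ beyond the normalization flag")
    dmcc <- validationMCC(report_norm) - validationMCC(report_no_norm)
    dacc <- report_norm@cvAccuracy - report_no_norm@cvAccuracy
    dtr <- trainingMCC(report_norm) - trainingMCC(report_no_norm)
    list(delta_validation_mcc = dmcc, delta_cv_accuracy = dacc,
         delta_training_mcc = dtr,
         improved = isTRUE(dmcc > 0))
}
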