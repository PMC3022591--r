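#' Accessors for PeptidomeExperiment
#'
#' \code{intensities} returns the feature-by-observation intensity matrix
#' (0 = missing reading); \code{sampleInfo} the observation metadata as a
#' plain data.frame; \code{featureMz} the numeric m/z of each feature;
#' \code{dataLevel} \code{"replicate"} or \code{"sample"};
#' \code{isNormalized} whether values are control-decile bins.
#'
#' @param x a \linkS4class{PeptidomeExperiment}
#' @return see description
#' @name peptidome-accessors
NULL

#' @rdname peptidome-accessors
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @rdname peptidome-accessors
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @rdname peptidome-accessors
#' @export
featureMz <- function(x) SummarizedExperiment::rowData(x)$mz

#' @rdname peptidome-accessors
#' @export
dataLevel <- function(x) S4Vectors::metadata(x)$level

#' @rdname peptidome-accessors
#' @export
isNormalized <- function(x) isTRUE(S4Vectors::metadata(x)$normalized)

#' Class labels of a PeptidomeExperiment
#'
#' @param x a \linkS4class{PeptidomeExperiment}
#' @return character vector of "control"/"cancer", one per column
#' @export
classLabels <- function(x) as.character(SummarizedExperiment::colData(x)$class)

setMethod("show", "PeptidomeExperiment", function(object) {
    cat(sprintf("PeptidomeExperiment (%s level%s): %d features x %d observations\n",
                dataLevel(object),
                if (isNormalized(object)) ", control-decile normalized" else "",
                nrow(object), ncol(object)))
    cd <- sampleInfo(object)
    tab <- table(cd$source, cd$class)
    cat("observations per source x class:\n")
    print(tab)
    invisible(NULL)
})

setMethod("show", "MassSpectrum", function(object) {
    cat(sprintf("MassSpectrum %s/%s (source %s): %d points, m/z %.1f-%.1f\n",
                object@sampleId, object@replicateId, object@source,
                length(object@mz),
                if (length(object@mz)) min(object@mz) else NA,
                if (length(object@mz)) max(object@mz) else NA))
    invisible(NULL)
})

setMethod("show", "PeakList", function(object) {
    cat(sprintf("PeakList: %d peaks", length(object@mz)))
    if (length(object@mz))
        cat(sprintf(", m/z %.1f-%.1f", min(object@mz), max(object@mz)))
    cat("\n")
    invisible(NULL)
})

#' @rdname PeakList-class
#' @param x a PeakList
#' @export
peakMz <- function(x) x@mz

#' @rdname PeakList-class
#' @export
peakHalfWidth <- function(x) x@halfWidth

setMethod("length", "PeakList", function(x) length(x@mz))

setMethod("show", "QuantileMap", function(object) {
    cat(sprintf("QuantileMap: %d features, sources: %s\n",
                length(object@features),
                paste(names(object@thresholds), collapse = ", ")))
    nun <- vapply(object@unmapped, length, integer(1))
    if (any(nun > 0))
        cat("unfittable (passed through unnormalized): ",
            paste(sprintf("%s: %d", names(nun), nun), collapse = ", "), "\n")
    invisible(NULL)
})

#' @rdname QuantileMap-class
#' @param x a QuantileMap
#' @param source source name
#' @return matrix of thresholds (features x 9) for one source
#' @export
quantileThresholds <- function(x, source) {
    if (!source %in% names(x@thresholds))
        stop("no quantile map fitted for source '", source, "'")
    x@thresholds[[source]]
}

setMethod("show", "MarginClassifier", function(object) {
    cat(sprintf("MarginClassifier: linear margin on %d features (cost %g)\n",
                length(object@features), object@cost))
    cat("decision d(x) = w.x + b; d >= 0 predicts control\n")
    invisible(NULL)
})

#' @rdname MarginClassifier-class
#' @param x a MarginClassifier
#' @export
modelWeights <- function(x) x@weights

#' @rdname MarginClassifier-class
#' @export
modelIntercept <- function(x) x@intercept

#' @rdname MarginClassifier-class
#' @export
modelFeatures <- function(x) x@features

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: TP %g FP %g TN %g FN %g | accuracy %.3f | MCC %.3f\n",
                object@tp, object@fp, object@tn, object@fn,
                object@accuracy, object@mcc))
    invisible(NULL)
})

#' Extract accuracy / MCC / counts from an EvaluationReport
#'
#' @param x an \linkS4class{EvaluationReport}
#' @return numeric value(s)
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
reportAccuracy <- function(x) x@accuracy

#' @rdname report-accessors
#' @export
reportMCC <- function(x) x@mcc

#' @rdname report-accessors
#' @export
reportCounts <- function(x) c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn)

setMethod("show", "SelectionResult", function(object) {
    ic <- if (is.na(object@intensityCutoff)) "NA" else
        format(object@intensityCutoff)
    cat(sprintf(paste0("SelectionResult: p-cutoff %.4g, intensity cutoff %s, ",
                       "%d features, CV accuracy %.3f\n"),
                object@pCutoff, ic, length(object@features), object@cvAccuracy))
    invisible(NULL)
})

#' Accessors for SelectionResult
#'
#' @param x a \linkS4class{SelectionResult}
#' @name selection-accessors
NULL

#' @rdname selection-accessors
#' @export
selectedFeatures <- function(x) x@features

#' @rdname selection-accessors
#' @export
selectionPValues <- function(x) x@pValues

#' @rdname selection-accessors
#' @export
selectionCutoffs <- function(x)
    c(p_cutoff = x@pCutoff, intensity_cutoff = x@intensityCutoff)

#' @rdname selection-accessors
#' @export
selectionCVAccuracy <- function(x) x@cvAccuracy

#' @rdname selection-accessors
#' @export
selectionGrid <- function(x) x@grid

setMethod("show", "RuleSet", function(object) {
    cat("RuleSet on features:", paste(object@features, collapse = ", "), "\n")
    cat(formatRules(object), sep = "\n")
    invisible(NULL)
})

setMethod("show", "ExperimentPlan", function(object) {
    cat(sprintf("ExperimentPlan: train [%s]%s%s, normalization %s, seed %d\n",
                paste(object@trainSources, collapse = "+"),
                if (length(object@validationSources))
                    paste0(", validate [",
                           paste(object@validationSources, collapse = "+"), "]")
                else "",
                if (!is.na(object@thirdSource))
                    paste0(", third-source controls [", object@thirdSource, "]")
                else "",
                if (object@normalize) "ON" else "OFF", object@seed))
    if (object@holdoutCancer > 0L)
        cat(sprintf("  holdout: %d cancer samples reserved for validation\n",
                    object@holdoutCancer))
    invisible(NULL)
})

setMethod("show", "ExperimentReport", function(object) {
    ic <- if (is.na(object@intensityCutoff)) "NA" else
        format(object@intensityCutoff)
    cat(sprintf(paste0("ExperimentReport | p cutoff %.4g | intensity cutoff %s | ",
                       "%d features | CV accuracy %.1f%%\n"),
                object@pCutoff, ic, object@nFeatures, 100 * object@cvAccuracy))
    cat(sprintf("  training: accuracy %.3f, MCC %.2f\n",
                object@training@accuracy, object@training@mcc))
    for (nm in names(object@counts)) {
        ct <- object@counts[[nm]]
        cat(sprintf("  %s: %d/%d correct\n", nm, ct[["correct"]], ct[["total"]]))
    }
    if (is(object@validation, "EvaluationReport"))
        cat(sprintf("  validation (pooled): MCC %.2f\n", object@validation@mcc))
    else
        cat("  validation: NA\n")
    invisible(NULL)
})

#' Accessors for ExperimentReport
#'
#' @param x an \linkS4class{ExperimentReport}
#' @name experiment-accessors
NULL

#' @rdname experiment-accessors
#' @export
trainingMCC <- function(x) x@training@mcc

#' @rdname experiment-accessors
#' @export
validationMCC <- function(x)
    if (is(x@validation, "EvaluationReport")) x@validation@mcc else NA_real_

#' @rdname experiment-accessors
#' @export
cvAccuracy <- function(x) x@cvAccuracy

#' @rdname experiment-accessors
#' @export
experimentFeatures <- function(x) x@selectedFeatures

#' @rdname experiment-accessors
#' @export
experimentCounts <- function(x) x@counts
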