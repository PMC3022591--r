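.CLINICAL_MARKERS <- c("apoC_I", "apoC_III", "apoB_100", "CRP", "CA19_9")
.RULE_FEATURES <- c("apoCI_ratio", "apoCIII_ratio", "CRP", "CA19_9")

#' Derive the four panel features from clinical records
#'
#' apoC-I and apoC-III are divided by apoB-100 (which shows no disease
#' trend and so controls for overall lipoprotein level); CRP and CA19-9
#' enter directly. Records with a missing marker or with apoB-100 missing
#' or nonpositive are excluded and logged.
#'
#' @param records data.frame with columns \code{sample_id}, \code{source},
#'   \code{class} and the five markers (apoC_I ug/ml, apoC_III mg/dl,
#'   apoB_100 mg/dl, CRP ug/ml, CA19_9 U/ml)
#' @return list with \code{features} (data.frame: sample_id, source,
#'   class, apoCI_ratio, apoCIII_ratio, CRP, CA19_9) and \code{excluded}
#'   (data.frame: sample_id, reason)
#' @examples
#' rec <- data.frame(sample_id = "s1", source = "A", class = "control",
#'                   apoC_I = 60, apoC_III = 8, apoB_100 = 120,
#'                   CRP = 2, CA19_9 = 10)
#' deriveClinicalFeatures(rec)$features$apoCI_ratio  # 0.5
#' @export
deriveClinicalFeatures <- function(records) {
    miss <- setdiff(c("sample_id", "class", .CLINICAL_MARKERS),
                    colnames(records))
    if (length(miss))
        stop("records lack column(s): ", paste(miss, collapse = ", "))
    anyMissing <- Reduce(`|`, lapply(.CLINICAL_MARKERS,
                                     function(k) is.na(records[[k]])))
    badApoB <- !anyMissing & records$apoB_100 <= 0
    drop <- anyMissing | badApoB
    excluded <- data.frame(
        sample_id = records$sample_id[drop],
        reason = ifelse(anyMissing, "missing marker",
                        "apoB_100 not positive")[drop],
        stringsAsFactors = FALSE)
    keep <- records[!(anyMissing | badApoB), , drop = FALSE]
    features <- data.frame(
        sample_id = keep$sample_id,
        source = if ("source" %in% colnames(keep)) keep$source else NA,
        class = keep$class,
        apoCI_ratio = keep$apoC_I / keep$apoB_100,
        apoCIII_ratio = keep$apoC_III / keep$apoB_100,
        CRP = keep$CRP, CA19_9 = keep$CA19_9,
        stringsAsFactors = FALSE)
    list(features = features, excluded = excluded)
}

.gini <- function(counts) {
    n <- sum(counts)
    if (n == 0) return(0)
    p <- counts / n
    1 - sum(p^2)
}

.majorityClass <- function(cls) {
    nc <- sum(cls == "cancer"); nk <- sum(cls == "control")
    # deterministic tie rule: ties go to control
    if (nc > nk) "cancer" else "control"
}

.growTree <- function(fm, cls, featNames, depth, max_depth, min_leaf) {
    n <- length(cls)
    leaf <- list(type = "leaf", class = .majorityClass(cls), n = n,
                 n_cancer = sum(cls == "cancer"),
                 n_control = sum(cls == "control"))
    if (depth >= max_depth || length(unique(cls)) < 2L || n < 2 * min_leaf)
        return(leaf)
    parentImp <- .gini(table(factor(cls, levels = c("control", "cancer"))))
    best <- NULL
    for (j in seq_along(featNames)) {
        v <- fm[, j]
        cuts <- sort(unique(v))
        if (length(cuts) < 2L) next
        thr <- (cuts[-1] + cuts[-length(cuts)]) / 2
        for (t in thr) {
            left <- v <= t
            nl <- sum(left); nr <- n - nl
            if (nl < min_leaf || nr < min_leaf) next
            imp <- (nl * .gini(table(factor(cls[left],
                                            levels = c("control", "cancer")))) +
                    nr * .gini(table(factor(cls[!left],
                                            levels = c("control", "cancer"))))) / n
            # strict improvement required; ties keep the earlier candidate
            # (lowest feature index, then lowest threshold)
            if (imp < parentImp - 1e-12 &&
                (is.null(best) || imp < best$imp - 1e-12)) {
                best <- list(j = j, t = t, imp = imp)
            }
        }
    }
    if (is.null(best)) return(leaf)
    left <- fm[, best$j] <= best$t
    list(type = "split", feature = featNames[best$j], threshold = best$t,
         n = n,
         left = .growTree(fm[left, , drop = FALSE], cls[left], featNames,
                          depth + 1L, max_depth, min_leaf),
         right = .growTree(fm[!left, , drop = FALSE], cls[!left], featNames,
                           depth + 1L, max_depth, min_leaf))
}

#' Train the clinical decision-rule panel
#'
#' Grows a binary decision tree on the four derived features by greedy
#' best-split search under Gini impurity, with deterministic
#' tie-breaking (lowest feature index, then lowest threshold; candidate
#' thresholds are midpoints between consecutive observed values). A
#' single-class input yields a single-leaf tree with a warning.
#'
#' @param records clinical records as in
#'   \code{\link{deriveClinicalFeatures}}
#' @param max_depth maximum tree depth (number of tests on any path)
#' @param min_leaf minimum samples per leaf
#' @return a \linkS4class{RuleSet}
#' @export
trainRules <- function(records, max_depth = 4L, min_leaf = 5L) {
    der <- deriveClinicalFeatures(records)
    ft <- der$features
    if (!nrow(ft)) stop("no usable training records")
    cls <- as.character(ft$class)
    if (length(unique(cls)) < 2L)
        warning("training records contain a single class; ",
                "returning a single-leaf tree")
    fm <- as.matrix(ft[, .RULE_FEATURES])
    tree <- .growTree(fm, cls, .RULE_FEATURES, 0L, max_depth, min_leaf)
    rs <- new("RuleSet", tree = tree, features = .RULE_FEATURES,
              trainingSummary = list())
    pred <- predictRules(rs, records)
    rs@trainingSummary <- list(
        n = nrow(ft), accuracy = mean(pred == cls),
        excluded = nrow(der$excluded),
        class_counts = table(factor(cls, levels = c("control", "cancer"))))
    rs
}

.predictNode <- function(node, row) {
    while (node$type == "split") {
        node <- if (row[[node$feature]] <= node$threshold) node$left
                else node$right
    }
    node$class
}

#' Predict classes with a rule set
#'
#' @param rs a \linkS4class{RuleSet}
#' @param records clinical records (markers; features are derived
#'   internally). Records excluded by feature derivation get \code{NA}.
#' @return character vector of predictions aligned to \code{records}
#' @export
predictRules <- function(rs, records) {
    der <- deriveClinicalFeatures(records)
    ft <- der$features
    out <- rep(NA_character_, nrow(records))
    ok <- match(ft$sample_id, records$sample_id)
    out[ok] <- vapply(seq_len(nrow(ft)),
                      function(i) .predictNode(rs@tree, ft[i, ]),
                      character(1))
    out
}

#' Evaluate a rule set on a validation cohort
#'
#' @param rs a \linkS4class{RuleSet}
#' @param records validation clinical records (non-empty)
#' @return list with \code{report} (an \linkS4class{EvaluationReport}),
#'   \code{accuracy}, \code{sensitivity} (correct cancers / cancers),
#'   \code{specificity} (correct controls / controls) and \code{n}
#' @export
evaluateRules <- function(rs, records) {
    if (!nrow(records)) stop("empty validation set")
    pred <- predictRules(rs, records)
    ok <- !is.na(pred)
    if (!any(ok)) stop("no validation record has complete markers")
    rep <- confusionReport(pred[ok], as.character(records$class)[ok])
    list(report = rep, accuracy = rep@accuracy,
         sensitivity = if (rep@tp + rep@fn > 0) rep@tp / (rep@tp + rep@fn)
                       else NA_real_,
         specificity = if (rep@tn + rep@fp > 0) rep@tn / (rep@tn + rep@fp)
                       else NA_real_,
         n = sum(ok))
}

#' One-sided rank-sum comparison of two marker groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) test with continuity correction,
#' one-sided in the stated direction (\code{"greater"}: location of
#' \code{x} exceeds that of \code{y}). Constant pooled data give p = 0.5
#' with a flag, as no ordering evidence exists.
#'
#' @param x,y numeric values of the two groups (both non-empty)
#' @param direction \code{"greater"} or \code{"less"}
#' @return list(p, flagged)
#' @export
groupCompare <- function(x, y, direction = c("greater", "less")) {
    direction <- match.arg(direction)
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    if (length(unique(c(x, y))) == 1L)
        return(list(p = 0.5, flagged = TRUE))
    p <- suppressWarnings(
        wilcox.test(x, y, alternative = direction, correct = TRUE)$p.value)
    list(p = p, flagged = FALSE)
}

#' Format a rule set as indented text
#'
#' @param rs a \linkS4class{RuleSet}
#' @return character vector of lines
#' @export
formatRules <- function(rs) {
    rec <- function(node, indent) {
        pad <- strrep("  ", indent)
        if (node$type == "leaf")
            return(sprintf("%s=> %s (n=%d: %d control, %d cancer)", pad,
                           node$class, node$n, node$n_control, node$n_cancer))
        c(sprintf("%sif %s <= %.4g:", pad, node$feature, node$threshold),
          rec(node$left, indent + 1L),
          sprintf("%selse (%s > %.4g):", pad, node$feature, node$threshold),
          rec(node$right, indent + 1L))
    }
    rec(rs@tree, 0L)
}

#' Serialize a rule set to JSON
#'
#' @param rs a \linkS4class{RuleSet}
#' @return JSON string
#' @export
rulesToJSON <- function(rs)
    jsonlite::toJSON(rs@tree, auto_unbox = TRUE, digits = NA)
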