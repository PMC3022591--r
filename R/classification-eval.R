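#' Stratified fold assignment
#'
#' Samples are shuffled within each class (fixed seed) and dealt
#' round-robin to folds, so every fold holds a near-proportional share of
#' each class.
#'
#' @param labels class label per sample
#' @param k number of folds
#' @param seed shuffle seed
#' @return integer fold id per sample
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
    n <- length(labels)
    if (k > n) stop("k must not exceed the number of samples")
    set.seed(as.integer(seed))
    fold <- integer(n)
    offset <- 0L
    for (cl in unique(labels)) {
        i <- which(labels == cl)
        # rotating offset keeps folds balanced across classes and makes
        # k = n exact leave-one-out
        fold[sample(i)] <- ((offset + seq_along(i) - 1L) %% k) + 1L
        offset <- offset + length(i)
    }
    fold
}

.fitLinearSVM <- function(m, labels, cost, tolerance = 1e-6) {
    # m: features x samples; control encoded +1. Features are standardized
    # (training mean/sd) before the margin fit, as is standard LIBSVM
    # practice; the weights are folded back to the original scale so the
    # stored model is a plain linear function of raw inputs.
    y <- factor(labels, levels = c("control", "cancer"))
    ctr <- rowMeans(m)
    scl <- apply(m, 1L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    ms <- (m - ctr) / scl
    fit <- e1071::svm(x = t(ms), y = y, kernel = "linear", cost = cost,
                      scale = FALSE, tolerance = tolerance)
    ws <- drop(t(fit$coefs) %*% fit$SV)
    bs <- -fit$rho
    # orient the decision function so positive values predict control
    pr <- predict(fit, t(ms))
    d <- drop(ws %*% ms) + bs
    agree <- mean((d >= 0) == (pr == "control"))
    if (agree < 0.5) { ws <- -ws; bs <- -bs }
    w <- ws / scl
    b <- bs - sum(ws * ctr / scl)
    names(w) <- rownames(m)
    list(w = w, b = b)
}

#' Train a linear maximum-margin classifier
#'
#' Fits a linear-kernel soft-margin SVM (LIBSVM via \pkg{e1071}) on the
#' selected features and stores it as an explicit linear decision
#' function d(x) = w.x + b with the convention +1 = control, -1 = cancer:
#' nonnegative decision values predict control.
#'
#' @param x sample-level \linkS4class{PeptidomeExperiment} or matrix
#'   (features x samples)
#' @param labels optional explicit labels
#' @param features subset of features to use (default all rows)
#' @param cost margin-softness constant C
#' @return a \linkS4class{MarginClassifier}
#' @export
trainClassifier <- function(x, labels = NULL, features = NULL, cost = 1) {
    d <- .resolveMatrixLabels(x, labels)
    if (!is.null(features)) d$m <- d$m[features, , drop = FALSE]
    tab <- table(factor(d$labels, levels = c("control", "cancer")))
    if (any(tab == 0)) stop("both classes are required for training")
    if (any(tab < 2)) stop("at least 2 samples per class are required")
    fit <- .fitLinearSVM(d$m, d$labels, cost)
    new("MarginClassifier", weights = fit$w, intercept = fit$b,
        features = rownames(d$m), cost = cost)
}

#' Decision values of a linear classifier
#'
#' @param model a \linkS4class{MarginClassifier}
#' @param x matrix (features x samples) or sample-level
#'   \linkS4class{PeptidomeExperiment}; must contain the model's features
#' @return numeric decision value per sample (>= 0 predicts control)
#' @export
decisionValues <- function(model, x) {
    m <- if (is(x, "PeptidomeExperiment")) intensities(x) else x
    miss <- setdiff(model@features, rownames(m))
    if (length(miss))
        stop("data lack model feature(s): ", paste(head(miss, 5), collapse = ", "))
    drop(model@weights %*% m[model@features, , drop = FALSE]) + model@intercept
}

#' @describeIn decisionValues predicted class labels
#' @export
predictClass <- function(model, x)
    ifelse(decisionValues(model, x) >= 0, "control", "cancer")

#' Matthews correlation coefficient
#'
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' Returns 0 when any marginal factor is zero. Cancer is the positive
#' class throughout the package.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts
#' @return value in [-1, 1]
#' @examples
#' mcc(tp = 22, fp = 18, tn = 15, fn = 0)  # 0.5
#' @export
mcc <- function(tp, fp, tn, fn) {
    if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be nonnegative")
    if (tp + fp + tn + fn == 0) stop("at least one count must be positive")
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / den
}

#' Confusion report from predictions
#'
#' @param predicted,truth character vectors of "control"/"cancer"
#' @return an \linkS4class{EvaluationReport} (cancer = positive class)
#' @export
confusionReport <- function(predicted, truth) {
    evaluationReport(tp = sum(predicted == "cancer" & truth == "cancer"),
                     fp = sum(predicted == "cancer" & truth == "control"),
                     tn = sum(predicted == "control" & truth == "control"),
                     fn = sum(predicted == "control" & truth == "cancer"))
}

.cvAccuracy <- function(m, labels, folds, cost) {
    accs <- vapply(sort(unique(folds)), function(f) {
        tr <- folds != f
        if (length(unique(labels[tr])) < 2) return(NA_real_)
        fit <- .fitLinearSVM(m[, tr, drop = FALSE], labels[tr], cost)
        d <- drop(fit$w %*% m[, !tr, drop = FALSE]) + fit$b
        pred <- ifelse(d >= 0, "control", "cancer")
        mean(pred == labels[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Mean over folds of the held-out fold accuracy of a linear-margin
#' classifier, with stratified folds and a fixed seed. \code{k = n} gives
#' leave-one-out.
#'
#' @param x sample-level \linkS4class{PeptidomeExperiment} or matrix
#' @param labels optional explicit labels
#' @param k folds
#' @param seed fold seed
#' @param features optional feature subset
#' @param cost margin constant C
#' @return mean fold accuracy
#' @export
crossValidate <- function(x, labels = NULL, k = 10, seed = 1L,
                          features = NULL, cost = 1) {
    d <- .resolveMatrixLabels(x, labels)
    if (!is.null(features)) d$m <- d$m[features, , drop = FALSE]
    folds <- stratifiedFolds(d$labels, k, seed)
    .cvAccuracy(d$m, d$labels, folds, cost)
}

#' Per-feature influence on the decision function
#'
#' The influence of feature j is the change in decision value between the
#' all-zero input vector and a vector that is zero except for feature j at
#' its maximum observed value: d(M_j e_j) - d(0) = w_j M_j. With the
#' package's class encoding, negative influence pushes toward cancer and
#' positive toward control. Features absent from the model have influence
#' 0.
#'
#' @param model a \linkS4class{MarginClassifier}
#' @param feature_maxima named vector of per-feature maximum observed
#'   values
#' @return data.frame(feature, influence)
#' @export
featureInfluence <- function(model, feature_maxima) {
    infl <- setNames(numeric(length(feature_maxima)), names(feature_maxima))
    inModel <- intersect(names(feature_maxima), model@features)
    infl[inModel] <- model@weights[inModel] * feature_maxima[inModel]
    data.frame(feature = names(infl), influence = unname(infl),
               stringsAsFactors = FALSE)
}

#' Label-shuffling control for the selection + classification pipeline
#'
#' For each shuffle the class labels are permuted and the full pipeline —
#' filter optimization, training, cross-validation — is rerun. Because
#' features are selected on the same samples that are cross-validated,
#' shuffled labels expose any optimistic bias: shuffled CV accuracies far
#' below the unshuffled one indicate genuine class signal.
#'
#' @param x sample-level \linkS4class{PeptidomeExperiment} or matrix
#' @param labels optional explicit labels
#' @param n_shuffles number of permutations (>= 1)
#' @param seed master seed (drives permutation and fold seeds)
#' @param p_grid,i_grid,cv_folds,cost forwarded to
#'   \code{\link{optimizeFilters}}
#' @return list with \code{observed} (unshuffled
#'   \linkS4class{SelectionResult}) and \code{shuffled}
#'   (data.frame: shuffle, cv_accuracy, n_features, median_p)
#' @export
permutationControl <- function(x, labels = NULL, n_shuffles = 20, seed = 1L,
                               p_grid = defaultPGrid(),
                               i_grid = defaultIntensityGrid(),
                               cv_folds = 10, cost = 1) {
    if (n_shuffles < 1) stop("n_shuffles must be at least 1")
    d <- .resolveMatrixLabels(x, labels)
    if (is(x, "PeptidomeExperiment") && isNormalized(x)) i_grid <- NA_real_
    observed <- optimizeFilters(d$m, d$labels, p_grid = p_grid,
                                i_grid = i_grid, cv_folds = cv_folds,
                                seed = seed, cost = cost)
    rows <- lapply(seq_len(n_shuffles), function(b) {
        set.seed(as.integer(seed) + b)
        perm <- sample(d$labels)
        res <- optimizeFilters(d$m, perm, p_grid = p_grid, i_grid = i_grid,
                               cv_folds = cv_folds, seed = seed, cost = cost)
        data.frame(shuffle = b, cv_accuracy = res@cvAccuracy,
                   n_features = length(res@features),
                   median_p = stats::median(res@pValues))
    })
    list(observed = observed, shuffled = do.call(rbind, rows))
}

#' Concordance between paired marker measurements
#'
#' Tie-corrected Kendall rank correlation (tau-b) with a two-sided
#' p-value, for checking that an orthogonal assay (e.g. ELISA) follows
#' the trend of the corresponding mass peak across the same samples.
#'
#' @param x,y paired numeric vectors over the same samples (n >= 3)
#' @return list(tau, p)
#' @export
markerConcordance <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must be paired")
    if (length(x) < 3) stop("at least 3 paired observations are required")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        stop("tau is undefined for a constant vector")
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    list(tau = unname(ct$estimate), p = ct$p.value)
}
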