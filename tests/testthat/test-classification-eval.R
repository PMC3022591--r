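test_that("training on separable data fits it perfectly", {
    x <- separableExperiment()
    model <- trainClassifier(x)
    expect_identical(unname(predictClass(model, x)), classLabels(x))
    expect_error(trainClassifier(intensities(x),
                                 rep("control", ncol(x))), "both classes")
    expect_error(trainClassifier(intensities(x)[, 1:3],
                                 c("control", "control", "cancer")),
                 "2 samples per class")
})

test_that("inverting the labels negates the decision function", {
    x <- separableExperiment(seed = 3)
    lab <- classLabels(x)
    inv <- ifelse(lab == "control", "cancer", "control")
    m1 <- trainClassifier(intensities(x), lab)
    m2 <- trainClassifier(intensities(x), inv)
    expect_lt(max(abs(modelWeights(m1) + modelWeights(m2))), 1e-4)
    expect_lt(abs(modelIntercept(m1) + modelIntercept(m2)), 1e-4)
})

test_that("duplicating every sample leaves the boundary unchanged", {
    x <- separableExperiment(seed = 6)
    m <- intensities(x); lab <- classLabels(x)
    m1 <- trainClassifier(m, lab)
    m2 <- trainClassifier(cbind(m, m), c(lab, lab))
    expect_lt(max(abs(modelWeights(m1) - modelWeights(m2))), 1e-5)
    expect_lt(abs(modelIntercept(m1) - modelIntercept(m2)), 1e-5)
})

test_that("mcc reproduces hand-computed and boundary values", {
    expect_equal(round(mcc(tp = 22, fp = 18, tn = 15, fn = 0), 2), 0.5)
    expect_equal(mcc(10, 0, 10, 0), 1)
    expect_equal(mcc(1, 1, 1, 1), 0)
    expect_equal(mcc(5, 0, 0, 5), 0)  # zero marginal -> 0 by convention
    expect_error(mcc(-1, 0, 0, 1), "nonnegative")
    rep <- evaluationReport(22, 18, 15, 0)
    expect_equal(reportAccuracy(rep), 37 / 55)
    expect_equal(reportMCC(rep), 0.5)
})

test_that("mcc equals the Pearson correlation of binary vectors", {
    set.seed(123)
    for (i in 1:200) {
        cnt <- rmultinom(1, sample(8:60, 1), prob = runif(4, 0.05, 1))[, 1]
        truth <- rep(c(1, 1, 0, 0), cnt)       # 1 = cancer
        pred <- rep(c(1, 0, 0, 1), cnt)        # TP, FN, TN, FP
        expected <- suppressWarnings(cor(pred, truth))
        got <- mcc(tp = cnt[1], fn = cnt[2], tn = cnt[3], fp = cnt[4])
        if (is.na(expected)) expected <- 0     # zero-variance margin
        expect_equal(got, expected, tolerance = 1e-12)
    }
})

test_that("mcc is invariant under swapping the class roles", {
    set.seed(77)
    for (i in 1:25) {
        k <- sample(0:20, 4, replace = TRUE)
        expect_equal(mcc(k[1], k[2], k[3], k[4]),
                     mcc(k[3], k[4], k[1], k[2]))
    }
})

test_that("confusion reports agree with per-sample recomputation", {
    set.seed(11)
    truth <- sample(c("control", "cancer"), 40, replace = TRUE)
    pred <- ifelse(runif(40) < 0.8, truth,
                   ifelse(truth == "control", "cancer", "control"))
    rep <- confusionReport(pred, truth)
    expect_equal(reportAccuracy(rep), mean(pred == truth))
    cnt <- reportCounts(rep)
    expect_equal(unname(sum(cnt)), 40)
    expect_equal(reportMCC(rep),
                 mcc(cnt[["tp"]], cnt[["fp"]], cnt[["tn"]], cnt[["fn"]]))
})

test_that("cross-validation is perfect on separable data and near-chance on noise", {
    x <- separableExperiment(n_per_class = 15)
    expect_equal(crossValidate(x, k = 5, seed = 1), 1)
    set.seed(20)
    accs <- vapply(1:20, function(s) {
        m <- matrix(rnorm(20 * 30), 20, 30,
                    dimnames = list(as.character(1:20 + 1000), NULL))
        lab <- rep(c("control", "cancer"), 15)
        crossValidate(m, lab, k = 5, seed = s)
    }, numeric(1))
    expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("leave-one-out matches a manual enumeration oracle", {
    m <- matrix(c(1, 2, 8, 9,
                  5, 1, 2, 8), 2, 4, byrow = TRUE,
                dimnames = list(c("1001", "1002"), NULL))
    lab <- c("control", "control", "cancer", "cancer")
    got <- crossValidate(m, lab, k = 4, seed = 1)
    # oracle: explicit loop, standardized linear SVM per held-out sample
    oracle <- mean(vapply(1:4, function(i) {
        tr <- m[, -i, drop = FALSE]
        ctr <- rowMeans(tr); scl <- apply(tr, 1, sd); scl[scl == 0] <- 1
        fit <- e1071::svm(x = t((tr - ctr) / scl),
                          y = factor(lab[-i], levels = c("control", "cancer")),
                          kernel = "linear", cost = 1, scale = FALSE)
        as.character(predict(fit, t((m[, i, drop = FALSE] - ctr) / scl))) ==
            lab[i]
    }, logical(1)))
    expect_equal(got, oracle)
    expect_error(crossValidate(m, lab, k = 9), "exceed")
})

test_that("feature influence is weight times maximum, signed by class push", {
    x <- separableExperiment()
    model <- trainClassifier(x)
    mx <- apply(intensities(x), 1, max)
    infl <- featureInfluence(model, mx)
    w <- modelWeights(model)
    expect_equal(infl$influence[infl$feature == "1500"],
                 unname(w["1500"] * mx["1500"]))
    # the separating feature is higher in controls: influence positive
    expect_gt(infl$influence[infl$feature == "1500"], 0)
    # features absent from the model have influence 0
    infl2 <- featureInfluence(model, c(mx, "9999" = 50))
    expect_equal(infl2$influence[infl2$feature == "9999"], 0)
    # closed form
    toy <- new("MarginClassifier", weights = c(f = 2), intercept = 0,
               features = "f", cost = 1)
    expect_equal(featureInfluence(toy, c(f = 5))$influence, 10)
    toy0 <- new("MarginClassifier", weights = c(f = 0), intercept = 1,
                features = "f", cost = 1)
    expect_equal(featureInfluence(toy0, c(f = 5))$influence, 0)
})

test_that("label shuffling destroys real signal", {
    sim <- simulatePeptidome(generatorConfig(seed = 61, n_features = 100,
        sources = list(A = c(control = 20L, cancer = 20L)),
        source_bias_sd = 0, source_batches = 1L,
        discordant_source_offset = 0, effect_size = 1.6))
    sm <- filterZeroFeatures(averageReplicates(sim$experiment))$experiment
    pc <- permutationControl(sm, n_shuffles = 8, seed = 5,
                             p_grid = c(0.001, 0.005, 0.01),
                             i_grid = c(0, 100), cv_folds = 5)
    expect_lt(median(pc$shuffled$cv_accuracy),
              pc$observed@cvAccuracy - 0.2)
    # shuffled median feature p-values sit near the null center
    expect_gt(median(pc$shuffled$median_p), 0.2)
    expect_error(permutationControl(sm, n_shuffles = 0), "at least 1")
})

test_that("a shuffle equal to the original labels reproduces the observed run", {
    x <- separableExperiment(n_per_class = 6)
    res1 <- optimizeFilters(x, p_grid = 0.05, i_grid = 0, cv_folds = 3,
                            seed = 4)
    res2 <- optimizeFilters(intensities(x), classLabels(x), p_grid = 0.05,
                            i_grid = 0, cv_folds = 3, seed = 4)
    expect_identical(res1@cvAccuracy, res2@cvAccuracy)
})

test_that("Kendall concordance matches hand counts", {
    x <- c(1, 2, 3)
    expect_equal(markerConcordance(x, x)$tau, 1)
    expect_equal(markerConcordance(x, -x)$tau, -1)
    expect_equal(markerConcordance(x, c(1, 3, 2))$tau, 1 / 3)
    expect_error(markerConcordance(x, c(2, 2, 2)), "constant")
    expect_error(markerConcordance(1:2, 1:2), "3 paired")
    # strongly dependent markers are detected
    set.seed(2)
    a <- rlnorm(60); b <- a * exp(rnorm(60, 0, 0.2))
    conc <- markerConcordance(a, b)
    expect_lt(conc$p, 1e-4)
    expect_gt(conc$tau, 0.5)
})
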