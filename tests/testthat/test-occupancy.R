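test_that("SES cutoff maximizes the ECDF gap with ties to the smallest score", {
    res <- sesCutoff(c(1, 2, 9, 10), c(1, 2, 3, 4))
    expect_equal(res$cutoff, 4)
    expect_equal(res$gap, 0.5)
    ## observed == control: zero gap, smallest score, warning
    expect_warning(res0 <- sesCutoff(c(1, 2, 3), c(1, 2, 3)), "no specific")
    expect_equal(res0$cutoff, 1)
    expect_equal(res0$gap, 0)
    ## stochastically larger observed: positive gap
    set.seed(4)
    resS <- sesCutoff(rnorm(500, 2), rnorm(500, 0))
    expect_gt(resS$gap, 0)
    expect_warning(resC <- sesCutoff(c(5, 5), c(5, 5)), "constant")
    expect_equal(resC$cutoff, 5)
    expect_error(sesCutoff(numeric(0), 1), "nonempty")
})

test_that("sigmoid transform anchors cutoff at 0.1 and midpoint at 0.5", {
    set.seed(5)
    raw <- c(rnorm(200, 0), rnorm(100, 4))
    cut <- 2
    tr <- occupancyTransform(raw, cut)
    m <- median(raw[raw > cut])
    expect_equal(unname(tr$midpoint), m)
    ## occupancy at the exact midpoint / cutoff values
    o <- occupancyTransform(c(m, cut), cut)$occupancy
    expect_equal(o[1], 0.5, tolerance = 1e-9)
    expect_equal(o[2], 0.1, tolerance = 1e-9)
    ## monotone
    xs <- sort(runif(50, -3, 8))
    expect_true(all(diff(occupancyTransform(xs, cut)$occupancy) >= 0))
    ## nothing above cutoff: flagged uninformative, all zero
    tr0 <- occupancyTransform(c(0, 1, 2), 5)
    expect_true(tr0$uninformative)
    expect_equal(tr0$occupancy, c(0, 0, 0))
})

test_that("occupancy table masks missing scores as zero occupancy", {
    set.seed(6)
    raw <- matrix(rnorm(60, 5), 20, 3,
                  dimnames = list(paste0("r", 1:20), paste0("F", 1:3)))
    raw[1, 1] <- NA
    ctrl <- matrix(rnorm(60, 5), 20, 3, dimnames = dimnames(raw))
    tab <- buildOccupancyTable(raw, ctrl)
    expect_true(missingMask(tab)[1, 1])
    expect_equal(occupancyMatrix(tab)[1, 1], 0)
    expect_true(all(occupancyMatrix(tab) >= 0 &
                    occupancyMatrix(tab) <= 1))
})

test_that("region feature takes the max over the 750-bp window", {
    expect_equal(regionFeature(rep(0.3, 15), (0:14) * 50, center = 375),
                 0.3)
    vals <- rep(0.1, 15); vals[7] <- 0.9
    expect_equal(regionFeature(vals, (0:14) * 50, center = 375), 0.9)
    set.seed(7)
    v <- runif(15)
    expect_equal(regionFeature(v, (0:14) * 50, center = 375), max(v))
    ## bins outside the window are ignored
    far <- c(1, 0.2)
    expect_equal(regionFeature(far, c(5000, 100), center = 375), 0.2)
    expect_true(is.na(regionFeature(0.5, 5000, center = 375)))
})

test_that("training set reproduces the class-balancing arithmetic", {
    set.seed(8)
    n <- 286 + 465 + 2479
    ids <- sprintf("r%05d", seq_len(n))
    calls <- setNames(rep(c("inducible", "constitutive", "inactive"),
                          c(286, 465, 2479)), ids)
    occ <- matrix(runif(n * 4), n, 4,
                  dimnames = list(ids, paste0("F", 1:4)))
    sp <- makeTrainingSet(occ, calls, nNonInducible = 500,
                          trainFrac = 0.8, seed = 9)
    expect_equal(length(sp$trainIds) + length(sp$testIds), 1251)
    ## per-class test counts are floor(0.2 n), remainder trains
    expect_equal(length(sp$testIds),
                 floor(0.2 * 286) + floor(0.2 * 465) + floor(0.2 * 500))
    expect_equal(length(sp$trainIds), 1001)
    expect_length(intersect(sp$trainIds, sp$testIds), 0)
    ## reproducible under the seed
    sp2 <- makeTrainingSet(occ, calls, nNonInducible = 500,
                           trainFrac = 0.8, seed = 9)
    expect_identical(sp$trainIds, sp2$trainIds)
    ## fewer inactive than requested: all used, with warning
    small <- calls[c(1:300, 287:500, 752:800)]
    expect_warning(makeTrainingSet(occ[names(small), ], small,
        nNonInducible = 500), "using all")
})

test_that("ensemble recovers a single planted informative factor", {
    cfg <- simulationConfig(nClinical = 600, nAreOnly = 0,
        nPositiveCtrl = 0, nFactors = 20L, informativeFactors = 1L,
        missingRate = 0, seed = 71)
    sim <- simulateRegions(cfg)
    occ <- simulateOccupancy(sim$regions, sim$truth, cfg)
    tab <- buildOccupancyTable(occ$raw, occ$control)
    cls <- plantedClasses(sim$truth)
    sp <- makeTrainingSet(occupancyMatrix(tab), cls,
                          nNonInducible = 200, seed = 72)
    model <- fitBaggedMultinomialLasso(sp$xTrain, sp$yTrain,
        nEstimators = 2000, seed = 72)
    inf <- names(which(sim$truth@informativeFactor))
    W <- classWeights(model)
    expect_gt(W[inf, "inducible"], 0)
    expect_lte(rank(-abs(W[, "inducible"]))[inf], 3)
    ## every factor got sampled at this estimator count
    expect_true(all(model@factorSampleCount > 0))
})

test_that("infinite penalty collapses weights; permuted labels are chance", {
    set.seed(10)
    n <- 150
    x <- matrix(runif(n * 6), n, 6,
                dimnames = list(paste0("r", 1:n), paste0("F", 1:6)))
    y <- factor(sample(c("inducible", "constitutive", "inactive"), n,
                       replace = TRUE, prob = c(0.2, 0.3, 0.5)))
    model <- fitBaggedMultinomialLasso(x, y, nEstimators = 50,
                                       l1Penalty = 1e6, seed = 11)
    expect_true(all(classWeights(model) == 0))
    pr <- predict(model, x)
    expect_lt(max(abs(rowSums(pr$prob) - 1)), 1e-9)
    expect_lt(max(apply(pr$prob, 2, function(col) diff(range(col)))),
              1e-12)

    ## permuted labels: held-out accuracy near the majority rate
    cfg <- simulationConfig(nClinical = 500, nAreOnly = 0,
        nPositiveCtrl = 0, nFactors = 10L, informativeFactors = 2L,
        missingRate = 0, seed = 73)
    sim <- simulateRegions(cfg)
    occ <- simulateOccupancy(sim$regions, sim$truth, cfg)
    tab <- buildOccupancyTable(occ$raw, occ$control)
    cls <- plantedClasses(sim$truth)
    set.seed(12)
    perm <- setNames(sample(cls), names(cls))
    sp <- makeTrainingSet(occupancyMatrix(tab), perm,
                          nNonInducible = 200, seed = 13)
    model2 <- fitBaggedMultinomialLasso(sp$xTrain, sp$yTrain,
        nEstimators = 400, seed = 13)
    ev <- evaluateModel(model2, sp$xTest, sp$yTest)
    maj <- max(table(sp$yTest)) / length(sp$yTest)
    nT <- length(sp$yTest)
    expect_lt(abs(ev$accuracy - maj),
              3 * sqrt(maj * (1 - maj) / nT) + 0.05)
})

test_that("prediction probabilities are proper and monotone", {
    W <- matrix(0, 2, 3, dimnames = list(c("F1", "F2"),
        c("inducible", "constitutive", "inactive")))
    W["F1", "inducible"] <- 2
    model <- new("EnsembleModel",
        classLabels = colnames(W), weights = W,
        intercepts = setNames(rep(0, 3), colnames(W)),
        nEstimators = 1L,
        factorSampleCount = setNames(c(1L, 1L), rownames(W)),
        hyperparams = list(maxSamples = 50, maxFeatures = 5,
                           l1Penalty = 0.1, seed = 1))
    x <- cbind(F1 = seq(0, 1, 0.1), F2 = 0.5)
    rownames(x) <- paste0("r", 1:11)
    pr <- predict(model, x)
    expect_lt(max(abs(rowSums(pr$prob) - 1)), 1e-9)
    expect_true(all(diff(pr$prob[, "inducible"]) > 0))
    expect_error(predict(model, x[, 1, drop = FALSE]), "lacks")
})

test_that("evaluation metrics: perfect, random and the AUC rank identity", {
    ## perfect separation via a handcrafted model
    W <- matrix(0, 1, 3, dimnames = list("F1",
        c("inducible", "constitutive", "inactive")))
    W["F1", "inducible"] <- 100; W["F1", "inactive"] <- -100
    model <- new("EnsembleModel", classLabels = colnames(W), weights = W,
        intercepts = setNames(c(0, -1000, 0), colnames(W)),
        nEstimators = 1L, factorSampleCount = c(F1 = 1L),
        hyperparams = list())
    x <- cbind(F1 = c(rep(1, 10), rep(-1, 10)))
    rownames(x) <- paste0("r", 1:20)
    y <- factor(rep(c("inducible", "inactive"), each = 10),
                levels = colnames(W))
    ev <- evaluateModel(model, x, y)
    expect_equal(ev$accuracy, 1)
    expect_equal(unname(ev$precision[c("inducible", "inactive")]),
                 c(1, 1))
    expect_equal(unname(ev$auc[["inducible"]]), 1)
    expect_true(is.na(ev$precision[["constitutive"]]))

    ## AUC equals the Mann-Whitney statistic
    set.seed(14)
    sc <- rnorm(60); lab <- rep(c(TRUE, FALSE), each = 30)
    U <- unname(suppressWarnings(
        wilcox.test(sc[lab], sc[!lab])$statistic))
    expect_equal(aucRank(sc, lab), U / (30 * 30))

    ## random scores give AUC near 0.5
    set.seed(15)
    aucs <- replicate(100, aucRank(rnorm(80), rep(c(TRUE, FALSE), 40)))
    expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(100))
})

test_that("binding energy ranks planted factors and is antisymmetric", {
    cfg <- simulationConfig(nClinical = 500, nAreOnly = 0,
        nPositiveCtrl = 0, nFactors = 20L, informativeFactors = 2L,
        missingRate = 0, seed = 74)
    sim <- simulateRegions(cfg)
    occ <- simulateOccupancy(sim$regions, sim$truth, cfg)
    tab <- buildOccupancyTable(occ$raw, occ$control)
    cls <- plantedClasses(sim$truth)
    sp <- makeTrainingSet(occupancyMatrix(tab), cls,
                          nNonInducible = 200, seed = 75)
    model <- fitBaggedMultinomialLasso(sp$xTrain, sp$yTrain,
        nEstimators = 800, seed = 75)
    be <- bindingEnergy(model, occupancyMatrix(tab), cls)
    ## zero-weight factors have zero energy
    zero <- rownames(classWeights(model))[
        classWeights(model)[, "inducible"] == 0]
    if (length(zero))
        expect_true(all(be$energy[zero, "inducible"] == 0))
    ## antisymmetry
    d1 <- be$differential$inducible_vs_inactive
    d2 <- be$differential$inactive_vs_inducible
    expect_equal(d1[sort(names(d1))], -d2[sort(names(d2))])
    ## the planted factors carry the top differential energies
    inf <- names(which(sim$truth@informativeFactor))
    expect_true(all(inf %in% names(d1)[1:3]))
})

test_that("feature down-sampling: identity subset reproduces the full model", {
    cfg <- simulationConfig(nClinical = 400, nAreOnly = 0,
        nPositiveCtrl = 0, nFactors = 10L, informativeFactors = 1L,
        missingRate = 0, seed = 76)
    sim <- simulateRegions(cfg)
    occ <- simulateOccupancy(sim$regions, sim$truth, cfg)
    tab <- buildOccupancyTable(occ$raw, occ$control)
    cls <- plantedClasses(sim$truth)
    sp <- makeTrainingSet(occupancyMatrix(tab), cls,
                          nNonInducible = 150, seed = 77)
    full <- fitBaggedMultinomialLasso(sp$xTrain, sp$yTrain,
        nEstimators = 300, seed = 78)
    keep <- sp$yTest %in% c("inducible", "inactive")
    prF <- predict(full, sp$xTest[keep, , drop = FALSE])
    fullAuc <- aucRank(prF$prob[, "inducible"],
                       sp$yTest[keep] == "inducible")
    inf <- names(which(sim$truth@informativeFactor))
    uninf <- setdiff(colnames(sp$xTrain), inf)[1:3]
    res <- featureDownsampleEval(sp,
        c(list(all = colnames(sp$xTrain), informative = inf),
          setNames(as.list(uninf), paste0("noise", 1:3))),
        nEstimators = 300, seed = 78)
    expect_equal(res$auc[res$subset == "all"], fullAuc)
    ## one uninformative factor: near-chance AUC
    noiseAuc <- res$auc[grepl("^noise", res$subset)]
    nP <- sum(sp$yTest[keep] == "inducible")
    nN <- sum(keep) - nP
    se3 <- 3 * sqrt((nP + nN + 1) / (12 * nP * nN))
    expect_true(all(abs(noiseAuc - 0.5) < se3 + 0.05))
    ## the informative factor beats every uninformative singleton
    expect_true(all(res$auc[res$subset == "informative"] > noiseAuc))
    expect_error(featureDownsampleEval(sp, list(bad = "nope")),
                 "unknown factor")
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(18)
    for (i in 1:5) {
        sc <- rnorm(100) + rep(c(0.8, 0), c(40, 60))
        lab <- rep(c(TRUE, FALSE), c(40, 60))
        ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<")))
        expect_equal(aucRank(sc, lab), ref, tolerance = 1e-9)
    }
})
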