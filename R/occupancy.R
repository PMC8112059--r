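#' @importFrom glmnet glmnet
#' @importFrom stats coef setNames plogis predict
NULL

#' SES cutoff separating specific from non-specific binding
#'
#' Signal-extraction-scaling style normalization: among the pooled sorted
#' unique scores, the cutoff is the score x maximizing the gap
#' F_control(x) - F_observed(x) between the two empirical cumulative
#' distributions; ties break to the smallest x. A zero maximal gap (e.g.
#' observed identical to control) means no specific binding is detectable;
#' the minimum score is returned with a warning.
#'
#' @param observed numeric vector of observed (ChIP) scores.
#' @param control numeric vector of matched control scores.
#' @return A list: \code{cutoff}, \code{gap} (the maximal ECDF difference).
#' @examples
#' sesCutoff(c(1, 2, 9, 10), c(1, 2, 3, 4))  # cutoff 4, gap 0.5
#' @export
sesCutoff <- function(observed, control) {
    if (!length(observed) || !length(control))
        stop("observed and control must be nonempty")
    cand <- sort(unique(c(observed, control)))
    if (length(cand) == 1L) {
        warning("all scores constant; cutoff set to that constant")
        return(list(cutoff = cand, gap = 0))
    }
    Fo <- stats::ecdf(observed)(cand)
    Fc <- stats::ecdf(control)(cand)
    gap <- Fc - Fo
    best <- which.max(gap)   # which.max takes the first (smallest x) tie
    if (gap[best] <= 0)
        warning("no positive ECDF gap: no specific binding detected")
    list(cutoff = cand[best], gap = gap[best])
}

#' Sigmoid occupancy transform
#'
#' Maps raw binding scores to [0,1]: occupancy(x) = 1/(1 + exp(-(x - m)/s))
#' with midpoint m the median of scores strictly above the cutoff and scale
#' s = (m - cutoff)/ln(9), anchoring occupancy(cutoff) = 0.1 and
#' occupancy(m) = 0.5. If m coincides with the cutoff the scale is floored
#' near machine epsilon (step behavior). With no scores above the cutoff
#' the factor carries no specific signal: all occupancies are 0 and the
#' factor is flagged uninformative. NA scores map to NA (the table builder
#' imputes them as 0 and masks them).
#'
#' @param raw numeric scores (NA allowed).
#' @param cutoff SES cutoff from \code{\link{sesCutoff}}.
#' @return A list: \code{occupancy}, \code{midpoint}, \code{scale},
#'   \code{uninformative}.
#' @export
occupancyTransform <- function(raw, cutoff) {
    above <- raw[!is.na(raw) & raw > cutoff]
    if (!length(above)) {
        return(list(occupancy = ifelse(is.na(raw), NA_real_, 0),
                    midpoint = NA_real_, scale = NA_real_,
                    uninformative = TRUE))
    }
    m <- median(above)
    s <- max((m - cutoff) / log(9), 1e-12)
    list(occupancy = plogis((raw - m) / s), midpoint = m, scale = s,
         uninformative = FALSE)
}

#' Build an occupancy feature table
#'
#' Applies per-factor SES cutoff estimation and the sigmoid transform to a
#' raw score matrix with matched controls. Missing raw scores become
#' occupancy 0 and are flagged in the mask (zero-imputation mirrors how
#' absent ChIP-seq coverage depresses a region's apparent binding, the
#' documented source of classifier false negatives).
#'
#' @param raw numeric matrix regions x factors, NA where missing.
#' @param control numeric matrix (or list of vectors) of control scores per
#'   factor.
#' @return An \code{\link{OccupancyTable-class}}.
#' @examples
#' cfg <- simulationConfig(nClinical = 30, nAreOnly = 0, nPositiveCtrl = 0,
#'   nFactors = 4L, informativeFactors = 1L, seed = 5)
#' sim <- simulateRegions(cfg)
#' occ <- simulateOccupancy(sim$regions, sim$truth, cfg)
#' buildOccupancyTable(occ$raw, occ$control)
#' @export
buildOccupancyTable <- function(raw, control) {
    fids <- colnames(raw)
    stopifnot(!is.null(fids))
    ctrlList <- if (is.list(control)) control
                else lapply(seq_len(ncol(control)),
                            function(j) control[, j])
    names(ctrlList) <- fids
    occ <- matrix(0, nrow(raw), ncol(raw), dimnames = dimnames(raw))
    cutoff <- midpoint <- setNames(rep(NA_real_, length(fids)), fids)
    uninf <- setNames(logical(length(fids)), fids)
    for (f in fids) {
        obs <- raw[, f][!is.na(raw[, f])]
        if (!length(obs)) {
            uninf[f] <- TRUE
            next
        }
        ses <- suppressWarnings(sesCutoff(obs, ctrlList[[f]]))
        tr <- occupancyTransform(raw[, f], ses$cutoff)
        v <- tr$occupancy
        v[is.na(v)] <- 0
        occ[, f] <- v
        cutoff[f] <- ses$cutoff
        midpoint[f] <- tr$midpoint
        uninf[f] <- tr$uninformative
    }
    new("OccupancyTable", occupancy = occ, raw = raw,
        control = ctrlList, cutoff = cutoff, midpoint = midpoint,
        mask = is.na(raw), uninformative = uninf)
}

#' Maximum-occupancy region feature
#'
#' Collapses a binned occupancy profile to a scalar: the maximum occupancy
#' over the bins of a \code{window}-bp (default 750) window centered on the
#' region midpoint. Bins are \code{resolution}-bp (default 50), 0-based
#' half-open at \code{binStarts}. A region with no covered bin yields NA
#' (to be masked).
#'
#' @param values numeric occupancy per bin.
#' @param binStarts integer start of each bin.
#' @param center region midpoint coordinate.
#' @param window feature window in bp.
#' @param resolution bin width in bp.
#' @return Scalar feature (max occupancy) or NA if uncovered.
#' @examples
#' regionFeature(c(0.1, 0.9, 0.1), binStarts = c(0, 50, 100), center = 75)
#' @export
regionFeature <- function(values, binStarts, center, window = 750,
                          resolution = 50) {
    lo <- center - window / 2
    hi <- center + window / 2
    inWin <- (binStarts + resolution) > lo & binStarts < hi
    inWin <- inWin & !is.na(values)
    if (!any(inWin)) return(NA_real_)
    max(values[inWin])
}

#' Class-balanced train/test split
#'
#' Emulates the study's balancing: the dataset is all inducible and all
#' constitutive regions plus \code{nNonInducible} randomly sampled inactive
#' regions (all of them, with a warning, if fewer exist). It is then split
#' into train and test stratified by class: per class the test set gets
#' floor((1 - trainFrac) n) regions and the remainder trains. Seeded and
#' reproducible; the two sets are disjoint and exhaustive.
#'
#' @param occupancy matrix regions x factors (e.g.
#'   \code{occupancyMatrix(tab)}).
#' @param calls named character/factor of class per region.
#' @param nNonInducible inactive regions to sample (default 500).
#' @param trainFrac training fraction (default 0.8).
#' @param seed integer RNG seed.
#' @return A list: \code{xTrain}, \code{yTrain}, \code{xTest},
#'   \code{yTest}, \code{trainIds}, \code{testIds}.
#' @export
makeTrainingSet <- function(occupancy, calls, nNonInducible = 500,
                            trainFrac = 0.8, seed = 1) {
    calls <- setNames(as.character(calls), names(calls))
    calls <- calls[intersect(rownames(occupancy), names(calls))]
    need <- c("inducible", "constitutive", "inactive")
    if (!all(need %in% calls))
        stop("calls must include all of: ", paste(need, collapse = ", "))
    set.seed(seed)
    inact <- names(calls)[calls == "inactive"]
    if (length(inact) < nNonInducible) {
        warning("only ", length(inact), " inactive regions available; ",
                "using all")
        pick <- inact
    } else pick <- sample(inact, nNonInducible)
    ids <- c(names(calls)[calls %in% c("inducible", "constitutive")], pick)
    y <- factor(calls[ids], levels = need)

    testIds <- unlist(lapply(need, function(cl) {
        clIds <- ids[y == cl]
        ## epsilon guards against 1 - 0.8 = 0.19999... flooring one short
        nTest <- floor((1 - trainFrac) * length(clIds) + 1e-9)
        if (nTest > 0) sample(clIds, nTest) else character(0)
    }), use.names = FALSE)
    trainIds <- setdiff(ids, testIds)
    list(xTrain = occupancy[trainIds, , drop = FALSE],
         yTrain = factor(calls[trainIds], levels = need),
         xTest = occupancy[testIds, , drop = FALSE],
         yTest = factor(calls[testIds], levels = need),
         trainIds = trainIds, testIds = testIds)
}

## stratified allocation of maxSamples across classes, >= 1 each
.strataSizes <- function(tbl, maxSamples) {
    k <- .apportion(maxSamples, tbl / sum(tbl))
    k <- pmax(k, 1L)
    k <- pmin(k, as.integer(tbl))
    k
}

#' Bagged L1 multinomial logistic ensemble
#'
#' Fits \code{nEstimators} small L1-penalized multinomial logistic
#' regressions (coordinate descent via glmnet, single fixed penalty,
#' standardized features), each on a class-stratified subsample of at most
#' \code{maxSamples} training rows (without replacement) and
#' \code{maxFeatures} randomly drawn occupancy features. The aggregate
#' weight of a factor for a class is the mean of its fitted weights over
#' the base estimators that sampled it (never-sampled factors have weight 0
#' and sample count 0); intercepts are averaged over all estimators.
#' Averaging over random small feature subsets decorrelates collinear
#' features and yields a robust importance measure.
#'
#' @param x numeric matrix, training regions x factors.
#' @param y factor of class labels (3 classes).
#' @param nEstimators number of base estimators (the study used 1e5; a few
#'   thousand give stable aggregate weights at desk scale).
#' @param maxSamples,maxFeatures per-estimator subsample caps (50, 5).
#' @param l1Penalty glmnet lambda (default 0.1).
#' @param seed integer RNG seed.
#' @return An \code{\link{EnsembleModel-class}}.
#' @export
fitBaggedMultinomialLasso <- function(x, y, nEstimators = 2000,
    maxSamples = 50, maxFeatures = 5, l1Penalty = 0.1, seed = 1) {
    stopifnot(is.matrix(x), nrow(x) == length(y))
    y <- droplevels(as.factor(y))
    classes <- levels(y)
    if (length(classes) < 2) stop("need >= 2 classes")
    p <- ncol(x)
    fids <- colnames(x)
    if (is.null(fids)) stop("x must have factor (column) names")
    if (nrow(x) < maxSamples)
        maxSamples <- nrow(x)
    mf <- min(maxFeatures, p)
    set.seed(seed)
    classIdx <- split(seq_len(nrow(x)), y)
    sizes <- .strataSizes(vapply(classIdx, length, integer(1)), maxSamples)

    wSum <- matrix(0, p, length(classes), dimnames = list(fids, classes))
    wCnt <- integer(p)
    iSum <- setNames(numeric(length(classes)), classes)
    nFit <- 0L
    for (b in seq_len(nEstimators)) {
        rows <- unlist(lapply(seq_along(classIdx), function(k)
            sample(classIdx[[k]], sizes[k])), use.names = FALSE)
        feats <- if (mf < p) sample.int(p, mf) else seq_len(p)
        xs <- x[rows, feats, drop = FALSE]
        ys <- y[rows]
        excl <- NULL
        if (ncol(xs) == 1L) {   # glmnet needs >= 2 columns
            xs <- cbind(xs, `.dummy` = 0)
            excl <- 2L
        }
        ## glmnet warns on classes with < 8 observations; expected here
        fit <- tryCatch(suppressWarnings(
            glmnet::glmnet(xs, ys, family = "multinomial", alpha = 1,
                           lambda = l1Penalty, exclude = excl,
                           standardize = TRUE)),
            error = function(e) NULL)
        if (is.null(fit)) next
        co <- coef(fit)
        for (cl in classes) {
            v <- as.numeric(co[[cl]])
            iSum[cl] <- iSum[cl] + v[1]
            wSum[feats, cl] <- wSum[feats, cl] +
                v[seq_along(feats) + 1L]
        }
        wCnt[feats] <- wCnt[feats] + 1L
        nFit <- nFit + 1L
    }
    if (nFit == 0L) stop("all base estimators failed to fit")
    W <- sweep(wSum, 1, pmax(wCnt, 1L), "/")
    W[wCnt == 0L, ] <- 0
    new("EnsembleModel", classLabels = classes, weights = W,
        intercepts = iSum / nFit, nEstimators = nFit,
        factorSampleCount = setNames(as.integer(wCnt), fids),
        hyperparams = list(maxSamples = maxSamples,
                           maxFeatures = maxFeatures,
                           l1Penalty = l1Penalty, seed = seed))
}

#' @describeIn EnsembleModel-class predict per-class probabilities
#'   (softmax over aggregated linear scores) and the argmax class.
#' @param object an \code{EnsembleModel}.
#' @param newdata matrix of occupancy features covering the model's factors.
#' @param ... ignored.
#' @export
setMethod("predict", "EnsembleModel", function(object, newdata, ...) {
    fids <- rownames(object@weights)
    miss <- setdiff(fids, colnames(newdata))
    if (length(miss))
        stop("newdata lacks model factor(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
    xs <- newdata[, fids, drop = FALSE]
    eta <- sweep(xs %*% object@weights, 2, object@intercepts, "+")
    eta <- eta - apply(eta, 1, max)
    prob <- exp(eta) / rowSums(exp(eta))
    cls <- factor(object@classLabels[max.col(prob, ties.method = "first")],
                  levels = object@classLabels)
    list(prob = prob, class = setNames(cls, rownames(newdata)))
})

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic over
#' the positive-class score, U / (n_pos n_neg), with the midrank convention
#' for ties.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector, TRUE for positive-class observations.
#' @return AUC in [0, 1] (NA if either class is absent).
#' @export
aucRank <- function(scores, positive) {
    nP <- sum(positive); nN <- sum(!positive)
    if (nP == 0 || nN == 0) return(NA_real_)
    r <- rank(scores)
    (sum(r[positive]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Evaluate an ensemble on held-out data
#'
#' Standard confusion-matrix metrics plus one-vs-rest AUC per class from
#' the predicted class probability (rank statistic, midranks on ties).
#' Classes absent from the test set give NA metrics.
#'
#' @param model an \code{EnsembleModel}.
#' @param xTest matrix of test features.
#' @param yTest factor of true labels.
#' @return A list: \code{confusion} (table), \code{accuracy},
#'   \code{precision}, \code{recall}, \code{auc} (named per class),
#'   \code{prob}.
#' @export
evaluateModel <- function(model, xTest, yTest) {
    pr <- predict(model, xTest)
    yTest <- factor(yTest, levels = model@classLabels)
    conf <- table(predicted = pr$class, truth = yTest)
    classes <- model@classLabels
    precision <- recall <- auc <- setNames(rep(NA_real_, length(classes)),
                                           classes)
    for (cl in classes) {
        tp <- conf[cl, cl]
        predN <- sum(conf[cl, ])
        truthN <- sum(conf[, cl])
        if (predN > 0) precision[cl] <- tp / predN
        if (truthN > 0) {
            recall[cl] <- tp / truthN
            auc[cl] <- aucRank(pr$prob[, cl], yTest == cl)
        }
    }
    list(confusion = conf, accuracy = sum(diag(conf)) / sum(conf),
         precision = precision, recall = recall, auc = auc,
         prob = pr$prob)
}

#' Binding-energy report
#'
#' The average binding energy of a factor for a class is its aggregated
#' model weight for that class times the factor's mean occupancy over all
#' regions of that class; factors with zero weight have zero energy. The
#' differential energy between two classes, energy(g1) - energy(g2), ranks
#' factors that differentially predict one class over the other and is
#' antisymmetric in the pair.
#'
#' @param model an \code{EnsembleModel}.
#' @param occupancy matrix regions x factors.
#' @param calls named character/factor of class per region.
#' @return A list: \code{energy} (factors x classes matrix) and
#'   \code{differential} (named list over ordered class pairs, each a
#'   factor-named vector sorted decreasingly).
#' @export
bindingEnergy <- function(model, occupancy, calls) {
    calls <- setNames(as.character(calls), names(calls))
    fids <- rownames(model@weights)
    classes <- model@classLabels
    energy <- matrix(0, length(fids), length(classes),
                     dimnames = list(fids, classes))
    for (cl in classes) {
        ids <- intersect(names(calls)[calls == cl], rownames(occupancy))
        if (!length(ids)) stop("no regions for class ", cl)
        meanOcc <- colMeans(occupancy[ids, fids, drop = FALSE])
        energy[, cl] <- model@weights[, cl] * meanOcc
    }
    pairs <- expand.grid(g1 = classes, g2 = classes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$g1 != pairs$g2, ]
    differential <- lapply(seq_len(nrow(pairs)), function(i) {
        d <- energy[, pairs$g1[i]] - energy[, pairs$g2[i]]
        sort(d, decreasing = TRUE)
    })
    names(differential) <- paste0(pairs$g1, "_vs_", pairs$g2)
    list(energy = energy, differential = differential)
}

#' Down-sampled feature-set evaluation
#'
#' Refits the ensemble restricted to each factor subset (per-estimator
#' feature cap reduced to the subset size when smaller) and reports the
#' inducible-vs-inactive ROC AUC on the held-out split, quantifying how
#' much single features or small panels retain of the full model's
#' discriminative power.
#'
#' @param split output of \code{\link{makeTrainingSet}}.
#' @param factorSubsets named list of character vectors of factor ids.
#' @param nEstimators,maxSamples,maxFeatures,l1Penalty,seed passed to
#'   \code{\link{fitBaggedMultinomialLasso}}.
#' @return \code{data.frame}: subset, nFactors, auc.
#' @export
featureDownsampleEval <- function(split, factorSubsets, nEstimators = 500,
    maxSamples = 50, maxFeatures = 5, l1Penalty = 0.1, seed = 1) {
    stopifnot(length(factorSubsets) > 0)
    if (is.null(names(factorSubsets)))
        names(factorSubsets) <- paste0("subset", seq_along(factorSubsets))
    res <- lapply(names(factorSubsets), function(nm) {
        fs <- factorSubsets[[nm]]
        unknown <- setdiff(fs, colnames(split$xTrain))
        if (length(unknown))
            stop("unknown factor(s) in subset ", nm, ": ",
                 paste(unknown, collapse = ", "))
        model <- fitBaggedMultinomialLasso(
            split$xTrain[, fs, drop = FALSE], split$yTrain,
            nEstimators = nEstimators, maxSamples = maxSamples,
            maxFeatures = min(maxFeatures, length(fs)),
            l1Penalty = l1Penalty, seed = seed)
        keep <- split$yTest %in% c("inducible", "inactive")
        pr <- predict(model, split$xTest[keep, fs, drop = FALSE])
        data.frame(subset = nm, nFactors = length(fs),
            auc = aucRank(pr$prob[, "inducible"],
                          split$yTest[keep] == "inducible"))
    })
    do.call(rbind, res)
}
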