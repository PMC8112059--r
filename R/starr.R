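#' @importFrom BiocGenerics sizeFactors estimateSizeFactors
#' @importFrom SummarizedExperiment assay colData colData<- rowData
#' @importFrom stats pnorm p.adjust wilcox.test sd var
NULL

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the median over regions of
#' the ratio of its count to the row geometric mean, computed on regions
#' with all-positive counts.
#'
#' @param counts integer matrix, regions x samples.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' medianOfRatios(cbind(a = c(2, 2), b = c(4, 4)))
#' @export
medianOfRatios <- function(counts) {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos))
        stop("no region has positive counts in all samples; ",
             "add a pseudocount before normalization")
    lg <- log(counts[pos, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- apply(exp(lg - geo), 2, median)
    if (any(sf <= 0)) stop("non-positive size factor estimated")
    sf
}

#' @describeIn StarrExperiment-class estimate median-of-ratios size factors
#'   and store them in \code{colData()$sizeFactor}.
#' @param object a \code{StarrExperiment}.
#' @export
setMethod("estimateSizeFactors", "StarrExperiment", function(object) {
    colData(object)$sizeFactor <-
        medianOfRatios(assay(object, "counts"))
    object
})

#' @describeIn StarrExperiment-class retrieve stored size factors (estimating
#'   them on the fly if absent).
#' @export
setMethod("sizeFactors", "StarrExperiment", function(object) {
    sf <- colData(object)$sizeFactor
    if (is.null(sf)) sf <- medianOfRatios(assay(object, "counts"))
    else names(sf) <- colnames(object)
    sf
})

## Method-of-moments NB dispersion on the normalized scale, per region,
## unfloored (can go negative at low replication):
## E[s2_g] = mu_g * mean(1/sf_g) + alpha * mu_g^2, pooled across groups.
.momDispersion <- function(q, groups, sf) {
    num <- 0; den <- 0; bias <- 0
    for (g in groups) {
        qg <- q[, g, drop = FALSE]
        ng <- length(g)
        if (ng < 2) next
        m <- rowMeans(qg)
        s2 <- rowSums((qg - m)^2) / (ng - 1)
        cg <- mean(1 / sf[g])
        num <- num + (ng - 1) * s2
        bias <- bias + (ng - 1) * m * cg
        den <- den + (ng - 1) * m^2
    }
    (num - bias) / pmax(den, 1e-12)
}

#' Negative-binomial Wald test for differential activity
#'
#' Per-region two-group comparison of normalized counts under a
#' mean-dispersion NB model (var = mu + alpha mu^2). Size factors are
#' median-of-ratios over all samples of the experiment; dispersion is
#' estimated by method of moments on the normalized scale. The log2 fold
#' change uses a pseudocount on the normalized scale, and the Wald
#' statistic lfc/se is referred to the standard normal.
#'
#' With a handful of replicates the per-region moment estimator has so few
#' degrees of freedom that a normal-referenced Wald statistic is
#' anticonservative; the default therefore pools a single common dispersion
#' across regions (the mean of the unfloored per-region estimates, clipped
#' below at 1e-8), which restores near-nominal type-I error under the
#' shared-dispersion count model. \code{dispersion = "per-region"} keeps
#' the floored per-region estimates instead.
#'
#' @param se a \code{StarrExperiment} (or plain count matrix).
#' @param groupA,groupB character vectors of sample (column) names.
#' @param pseudocount added to normalized group means before log2 (default 1).
#' @param sf optional precomputed size factors for all columns of \code{se}.
#' @param dispersion "pooled" (common across regions, default) or
#'   "per-region".
#' @return A \code{DataFrame} with \code{baseMeanA}, \code{baseMeanB},
#'   \code{lfc} (B vs A), \code{se}, \code{stat}, \code{pvalue},
#'   \code{dispersion}, one row per region.
#' @examples
#' cfg <- simulationConfig(nClinical = 50, nAreOnly = 0, nPositiveCtrl = 0,
#'   seed = 3)
#' sim <- simulateRegions(cfg)
#' se <- simulateStarrCounts(sim$regions, sim$truth, cfg)
#' res <- nbWaldTest(se, paste0("etoh_", 1:3), paste0("dht_", 1:3))
#' head(res)
#' @export
nbWaldTest <- function(se, groupA, groupB, pseudocount = 1, sf = NULL,
                       dispersion = c("pooled", "per-region")) {
    dispersion <- match.arg(dispersion)
    counts <- if (is(se, "SummarizedExperiment")) assay(se, "counts") else se
    if (length(groupA) == 0L || length(groupB) == 0L)
        stop("both groups need at least one sample")
    missing <- setdiff(c(groupA, groupB), colnames(counts))
    if (length(missing))
        stop("unknown sample(s): ", paste(missing, collapse = ", "))
    if (is.null(sf)) sf <- medianOfRatios(counts)
    q <- sweep(counts, 2, sf, "/")

    mA <- rowMeans(q[, groupA, drop = FALSE])
    mB <- rowMeans(q[, groupB, drop = FALSE])
    alpha <- .momDispersion(q, list(groupA, groupB), sf)
    alpha <- if (dispersion == "pooled")
        rep(max(mean(alpha), 1e-8), length(alpha))
    else pmax(alpha, 1e-8)
    varA <- (mA * mean(1 / sf[groupA]) + alpha * mA^2) / length(groupA)
    varB <- (mB * mean(1 / sf[groupB]) + alpha * mB^2) / length(groupB)

    lfc <- log2(mB + pseudocount) - log2(mA + pseudocount)
    seLfc <- sqrt(varA / (mA + pseudocount)^2 +
                  varB / (mB + pseudocount)^2) / log(2)
    stat <- ifelse(seLfc > 0, lfc / seLfc, 0)
    p <- 2 * pnorm(-abs(stat))
    p[lfc == 0] <- 1
    S4Vectors::DataFrame(baseMeanA = mA, baseMeanB = mB, lfc = lfc,
        se = seLfc, stat = stat, pvalue = p, dispersion = alpha,
        row.names = rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; thin wrapper over \code{p.adjust} that rejects
#' missing values instead of silently propagating them.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return Adjusted p-values (monotone, capped at 1, elementwise >= input).
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p))) stop("p-values must not contain NA/NaN")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
    p.adjust(p, method = "BH")
}

#' Classification thresholds for enhancer calling
#'
#' The decision rules' cutoffs: a region is \emph{inducible} when its
#' DHT/EtOH LFC exceeds \code{inducedLfcMin} with adjusted p below
#' \code{inducedPadjMax}; \emph{constitutive} when both plasmid-normalized
#' LFCs exceed \code{activePlasmidLfcMin} without DHT induction (DHT/EtOH
#' LFC below \code{constitutiveInductionCeiling}); \emph{inactive} when both
#' plasmid-normalized LFCs fall below \code{inactivePlasmidLfcMax}. All
#' comparisons are strict.
#'
#' @param inducedLfcMin,inducedPadjMax,activePlasmidLfcMin
#'   rule cutoffs (defaults 1, 0.05, 1).
#' @param constitutiveInductionCeiling,inactivePlasmidLfcMax defaults 1, 1.
#' @return A named list of thresholds.
#' @export
classificationThresholds <- function(inducedLfcMin = 1,
    inducedPadjMax = 0.05, activePlasmidLfcMin = 1,
    constitutiveInductionCeiling = 1, inactivePlasmidLfcMax = 1) {
    stopifnot(inducedLfcMin > 0, activePlasmidLfcMin > 0,
              constitutiveInductionCeiling > 0, inactivePlasmidLfcMax > 0,
              inducedPadjMax > 0, inducedPadjMax < 1)
    list(inducedLfcMin = inducedLfcMin, inducedPadjMax = inducedPadjMax,
         activePlasmidLfcMin = activePlasmidLfcMin,
         constitutiveInductionCeiling = constitutiveInductionCeiling,
         inactivePlasmidLfcMax = inactivePlasmidLfcMax)
}

#' Per-region activity statistics from a STARR-seq experiment
#'
#' Computes everything enhancer calling needs: the DHT-vs-EtOH NB Wald test
#' on RNA replicates (LFC, p, BH-adjusted p) and the plasmid-normalized
#' log2 activity of each condition, defined from replicate means as
#' log2(mean normalized RNA + pseudocount) - log2(mean normalized plasmid +
#' pseudocount).
#'
#' @param se a \code{StarrExperiment} with plasmid and RNA samples.
#' @param pseudocount pseudocount on the normalized scale (default 1).
#' @param dispersion passed to \code{\link{nbWaldTest}}.
#' @return A \code{DataFrame}: \code{lfcInduction}, \code{pvalue},
#'   \code{padj}, \code{lfcPlasmidEtoh}, \code{lfcPlasmidDht}, and mean
#'   normalized counts per sample role.
#' @examples
#' cfg <- simulationConfig(nClinical = 40, nAreOnly = 0, nPositiveCtrl = 0,
#'   seed = 4)
#' sim <- simulateRegions(cfg)
#' se <- simulateStarrCounts(sim$regions, sim$truth, cfg)
#' head(enhancerActivity(se))
#' @export
enhancerActivity <- function(se, pseudocount = 1,
                             dispersion = c("pooled", "per-region")) {
    stopifnot(is(se, "StarrExperiment"))
    cd <- colData(se)
    plasmid <- colnames(se)[cd$role == "plasmid"]
    etoh <- colnames(se)[cd$condition == "EtOH"]
    dht <- colnames(se)[cd$condition == "DHT"]
    if (!length(plasmid) || !length(etoh) || !length(dht))
        stop("experiment must contain plasmid, EtOH and DHT samples")
    sf <- medianOfRatios(assay(se, "counts"))
    wald <- nbWaldTest(se, etoh, dht, pseudocount = pseudocount, sf = sf,
                       dispersion = dispersion)
    q <- sweep(assay(se, "counts"), 2, sf, "/")
    mP <- rowMeans(q[, plasmid, drop = FALSE])
    mE <- rowMeans(q[, etoh, drop = FALSE])
    mD <- rowMeans(q[, dht, drop = FALSE])
    S4Vectors::DataFrame(
        lfcInduction = wald$lfc,
        pvalue = wald$pvalue,
        padj = bhAdjust(wald$pvalue),
        lfcPlasmidEtoh = log2(mE + pseudocount) - log2(mP + pseudocount),
        lfcPlasmidDht = log2(mD + pseudocount) - log2(mP + pseudocount),
        meanPlasmid = mP, meanEtoh = mE, meanDht = mD,
        row.names = rownames(se))
}

#' Three-class enhancer calling
#'
#' Applies the decision rules in order: \emph{inducible} (androgen-induced
#' reporter activity: DHT/EtOH LFC above threshold at controlled FDR), then
#' \emph{constitutive} (plasmid-normalized LFC above threshold in both
#' conditions, no DHT induction), then \emph{inactive} (plasmid-normalized
#' LFC below threshold in both conditions). Regions satisfying none of the
#' rules are called \emph{ambiguous} rather than silently forced into a
#' class; the three rules are not exhaustive. All inequalities are strict.
#' The call is a pure function of the statistics and thresholds.
#'
#' @param stats output of \code{\link{enhancerActivity}} (or any table with
#'   \code{lfcInduction}, \code{padj}, \code{lfcPlasmidEtoh},
#'   \code{lfcPlasmidDht}).
#' @param thresholds see \code{\link{classificationThresholds}}.
#' @return A \code{DataFrame} with \code{class} (factor with levels
#'   inducible/constitutive/inactive/ambiguous) alongside the input stats.
#' @examples
#' st <- S4Vectors::DataFrame(lfcInduction = c(2, 0.2, 0), padj =
#'   c(0.01, 0.8, 0.9), lfcPlasmidEtoh = c(0, 1.5, 0.1),
#'   lfcPlasmidDht = c(2, 1.6, 0.2), row.names = c("a", "b", "c"))
#' classifyEnhancers(st)$class
#' @export
classifyEnhancers <- function(stats,
                              thresholds = classificationThresholds()) {
    need <- c("lfcInduction", "padj", "lfcPlasmidEtoh", "lfcPlasmidDht")
    miss <- setdiff(need, colnames(stats))
    if (length(miss))
        stop("missing statistic column(s): ", paste(miss, collapse = ", "))
    for (cn in need) {
        bad <- which(!is.finite(stats[[cn]]))
        if (length(bad))
            stop("non-finite ", cn, " for region ",
                 rownames(stats)[bad[1]])
    }
    th <- thresholds
    inducible <- stats$lfcInduction > th$inducedLfcMin &
                 stats$padj < th$inducedPadjMax
    constitutive <- !inducible &
        stats$lfcPlasmidEtoh > th$activePlasmidLfcMin &
        stats$lfcPlasmidDht > th$activePlasmidLfcMin &
        stats$lfcInduction < th$constitutiveInductionCeiling
    inactive <- !inducible & !constitutive &
        pmax(stats$lfcPlasmidEtoh, stats$lfcPlasmidDht) <
            th$inactivePlasmidLfcMax
    cls <- rep("ambiguous", nrow(stats))
    cls[inactive] <- "inactive"
    cls[constitutive] <- "constitutive"
    cls[inducible] <- "inducible"
    out <- S4Vectors::DataFrame(class = factor(cls,
        levels = c("inducible", "constitutive", "inactive", "ambiguous")))
    rownames(out) <- rownames(stats)
    cbind(out, stats)
}

#' Class enrichment test on external per-region scores
#'
#' Compares an external signal (e.g. tissue H3K27ac read counts over the
#' called regions) between enhancer classes. Scores are z-transformed per
#' sample to correct for library-size differences, summarized per region as
#' the median z across samples, and compared between classes with the
#' two-sided Mann-Whitney test; p-values are BH-adjusted across the
#' requested comparisons.
#'
#' @param scores numeric matrix, regions x samples.
#' @param classes named character/factor of class per region (names matching
#'   rownames of \code{scores}).
#' @param comparisons list of length-2 character vectors of class labels;
#'   default: all pairs present.
#' @return A \code{data.frame}: classA, classB, medianZA, medianZB, nA, nB,
#'   pvalue, padj.
#' @export
classEnrichmentTest <- function(scores, classes, comparisons = NULL) {
    classes <- setNames(as.character(classes), names(classes))
    ids <- intersect(rownames(scores), names(classes))
    scores <- scores[ids, , drop = FALSE]
    classes <- classes[ids]
    z <- scale(scores)
    medz <- apply(z, 1, median)
    present <- unique(classes)
    if (is.null(comparisons)) {
        if (length(present) < 2) stop("need at least two classes")
        comparisons <- utils::combn(sort(present), 2, simplify = FALSE)
    }
    rows <- lapply(comparisons, function(cmp) {
        a <- medz[classes == cmp[1]]
        b <- medz[classes == cmp[2]]
        if (length(a) < 2 || length(b) < 2)
            stop("class absent or degenerate: ",
                 paste(cmp, collapse = " vs "))
        data.frame(classA = cmp[1], classB = cmp[2],
            medianZA = median(a), medianZB = median(b),
            nA = length(a), nB = length(b),
            pvalue = suppressWarnings(wilcox.test(a, b)$p.value))
    })
    out <- do.call(rbind, rows)
    out$padj <- bhAdjust(out$pvalue)
    out
}
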