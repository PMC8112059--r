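#' @import methods
#' @importFrom S4Vectors metadata DataFrame
NULL

setOldClass("igraph")

#' Simulation configuration for synthetic pipeline inputs
#'
#' Holds every tunable of the synthetic-data generators: region-set sizes,
#' planted enhancer-class proportions, STARR-seq count model parameters,
#' occupancy-feature structure, loop hub enrichment and co-accessibility
#' gains. Defaults reproduce the study conditions of the clinical ARBS
#' screen: 4139 clinical AR binding sites of which 6.9% are inducible,
#' 11.2% constitutively active and 81.9% inactive, assayed in triplicate,
#' with 90 candidate DNA-binding factors of which 5 carry class-dependent
#' signal.
#'
#' @slot nClinical integer, clinical ARBS regions (planted classes).
#' @slot nAreOnly integer, ARE-motif-only control regions (class "none").
#' @slot nPositiveCtrl integer, non-AR positive-control enhancers.
#' @slot classProportions named numeric of length 3
#'   (inducible, constitutive, inactive) summing to 1.
#' @slot nReplicates integer, RNA replicates per condition (and plasmid).
#' @slot baselineMean numeric, expected plasmid count per region.
#' @slot fcInduced numeric, DHT/EtOH RNA fold change for inducible regions.
#' @slot fcActive numeric, RNA/plasmid fold change for active regions.
#' @slot nbDispersion numeric, NB dispersion alpha (var = mu + alpha mu^2).
#' @slot nFactors,informativeFactors integer, occupancy feature counts.
#' @slot occupancyShift numeric, raw-score shift (in SD units) of informative
#'   factors in their target class.
#' @slot missingRate numeric in [0,1), fraction of occupancy scores masked.
#' @slot hubEnrichment numeric, loop-degree multiplier for inducible regions.
#' @slot loopBaseDegree numeric, expected loop degree of a non-hub region.
#' @slot tssUpBias numeric in [0,1], probability that a loop emitted by an
#'   inducible region towards a TSS targets an up-regulated DEG promoter
#'   specifically (0 = no preference, uniform over all TSS).
#' @slot nTss integer, simulated TSS count (up/down/none DEG labels).
#' @slot coaccessGain numeric, additive DHT co-accessibility gain at pairs
#'   adjacent to inducible regions (clipped to [0,1]).
#' @slot coaccessNoise numeric, SD of condition-shared score noise.
#' @slot regionWidth integer, width of simulated regions (>= 500 bp).
#' @slot genomeLength integer, length of the synthetic contig "chrS".
#' @slot seed integer, master seed; all generators are deterministic in it.
#' @export
setClass("SimulationConfig", representation(
    nClinical = "integer", nAreOnly = "integer", nPositiveCtrl = "integer",
    classProportions = "numeric", nReplicates = "integer",
    baselineMean = "numeric", fcInduced = "numeric", fcActive = "numeric",
    nbDispersion = "numeric", nFactors = "integer",
    informativeFactors = "integer", occupancyShift = "numeric",
    missingRate = "numeric", hubEnrichment = "numeric",
    loopBaseDegree = "numeric", tssUpBias = "numeric", nTss = "integer",
    coaccessGain = "numeric", coaccessNoise = "numeric",
    regionWidth = "integer", genomeLength = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(nClinical = object@nClinical, nReplicates = object@nReplicates,
             nFactors = object@nFactors, regionWidth = object@regionWidth,
             nTss = object@nTss)
    if (any(cnt <= 0L))
        msg <- c(msg, paste("counts must be > 0:",
                 paste(names(cnt)[cnt <= 0L], collapse = ", ")))
    if (object@nAreOnly < 0L || object@nPositiveCtrl < 0L)
        msg <- c(msg, "nAreOnly and nPositiveCtrl must be >= 0")
    p <- object@classProportions
    if (length(p) != 3L || any(p < 0) || any(p > 1))
        msg <- c(msg, "classProportions must be 3 fractions in [0,1]")
    else if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "classProportions must sum to 1 (tol 1e-9)")
    if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must be in [0,1)")
    if (object@informativeFactors > object@nFactors)
        msg <- c(msg, "informativeFactors cannot exceed nFactors")
    if (object@coaccessGain < 0) msg <- c(msg, "coaccessGain must be >= 0")
    if (object@tssUpBias < 0 || object@tssUpBias > 1)
        msg <- c(msg, "tssUpBias must be in [0,1]")
    if (object@regionWidth < 500L)
        msg <- c(msg, "regionWidth must be >= 500 bp")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Constructor with study-scale defaults.
#' @param nClinical,nAreOnly,nPositiveCtrl,classProportions,nReplicates
#'   see slots.
#' @param baselineMean,fcInduced,fcActive,nbDispersion see slots.
#' @param nFactors,informativeFactors,occupancyShift,missingRate see slots.
#' @param hubEnrichment,loopBaseDegree,nTss see slots.
#' @param coaccessGain,coaccessNoise,regionWidth,genomeLength,seed see slots.
#' @return A validated \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nClinical = 100, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nClinical = 4139L, nAreOnly = 2783L,
    nPositiveCtrl = 500L,
    classProportions = c(inducible = 0.069, constitutive = 0.112,
                         inactive = 0.819),
    nReplicates = 3L, baselineMean = 100, fcInduced = 4, fcActive = 4,
    nbDispersion = 0.05, nFactors = 90L, informativeFactors = 5L,
    occupancyShift = 3, missingRate = 0.1, hubEnrichment = 3,
    loopBaseDegree = 1.5, tssUpBias = 0.8, nTss = 200L, coaccessGain = 0.3,
    coaccessNoise = 0.02, regionWidth = 600L, genomeLength = 5e7,
    seed = 1L) {
    if (is.null(names(classProportions)))
        names(classProportions) <- c("inducible", "constitutive", "inactive")
    new("SimulationConfig", nClinical = as.integer(nClinical),
        nAreOnly = as.integer(nAreOnly),
        nPositiveCtrl = as.integer(nPositiveCtrl),
        classProportions = classProportions,
        nReplicates = as.integer(nReplicates), baselineMean = baselineMean,
        fcInduced = fcInduced, fcActive = fcActive,
        nbDispersion = nbDispersion, nFactors = as.integer(nFactors),
        informativeFactors = as.integer(informativeFactors),
        occupancyShift = occupancyShift, missingRate = missingRate,
        hubEnrichment = hubEnrichment, loopBaseDegree = loopBaseDegree,
        tssUpBias = tssUpBias,
        nTss = as.integer(nTss), coaccessGain = coaccessGain,
        coaccessNoise = coaccessNoise, regionWidth = as.integer(regionWidth),
        genomeLength = genomeLength, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  regions: ", object@nClinical, " clinical / ", object@nAreOnly,
        " ARE-only / ", object@nPositiveCtrl, " positive-control\n", sep = "")
    cat("  class proportions:",
        paste(sprintf("%s=%.3f", names(object@classProportions),
                      object@classProportions), collapse = " "), "\n")
    cat("  counts: baseline ", object@baselineMean, ", fcInduced ",
        object@fcInduced, ", fcActive ", object@fcActive, ", dispersion ",
        object@nbDispersion, ", ", object@nReplicates,
        " replicates/condition\n", sep = "")
    cat("  occupancy: ", object@informativeFactors, "/", object@nFactors,
        " informative factors, missing rate ", object@missingRate,
        "\n", sep = "")
    cat("  network: hub enrichment ", object@hubEnrichment,
        ", co-accessibility gain ", object@coaccessGain, "\n", sep = "")
    cat("  seed:", object@seed, "\n")
})

#' Ground truth of a synthetic dataset
#'
#' Records what the generators planted so downstream estimators can be
#' scored against it: the enhancer class of every region, the design group,
#' the expected loop degree, and which occupancy factors carry signal (and
#' for which class).
#'
#' @slot regionClass named character; planted class per region id, one of
#'   inducible/constitutive/inactive/none.
#' @slot designGroup named character; clinical / ARE-only / positive-control.
#' @slot loopDegree named numeric; expected chromatin-loop degree per region.
#' @slot informativeFactor named logical; TRUE for factors with planted
#'   class-dependent signal.
#' @slot factorTargetClass named character; the class an informative factor
#'   marks ("" for uninformative factors).
#' @export
setClass("SyntheticTruth", representation(
    regionClass = "character", designGroup = "character",
    loopDegree = "numeric", informativeFactor = "logical",
    factorTargetClass = "character"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    ids <- names(object@regionClass)
    if (anyDuplicated(ids)) msg <- c(msg, "duplicated region ids")
    if (!all(object@regionClass %in%
             c("inducible", "constitutive", "inactive", "none")))
        msg <- c(msg, "invalid planted class label")
    if (!identical(names(object@designGroup), ids) ||
        !identical(names(object@loopDegree), ids))
        msg <- c(msg, "designGroup/loopDegree must share region ids")
    if (!identical(names(object@informativeFactor),
                   names(object@factorTargetClass)))
        msg <- c(msg, "factor annotations must share factor ids")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@regionClass), "regions,",
        sum(object@informativeFactor), "informative of",
        length(object@informativeFactor), "factors\n")
    print(table(planted = object@regionClass))
})

#' STARR-seq experiment container
#'
#' A \code{RangedSummarizedExperiment} with a \code{counts} assay and sample
#' metadata identifying each column's role in the reporter assay: plasmid
#' input or self-transcribed RNA, under vehicle (EtOH) or androgen (DHT)
#' treatment. Row metadata carries the design group and, for synthetic data,
#' the planted class.
#'
#' @slot .. see \code{\link[SummarizedExperiment]{RangedSummarizedExperiment}}.
#' @export
setClass("StarrExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("StarrExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("role", "condition") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'role' and 'condition'")
    else {
        if (!all(cd$role %in% c("plasmid", "rna")))
            msg <- c(msg, "role must be 'plasmid' or 'rna'")
        if (!all(cd$condition %in% c("none", "EtOH", "DHT")))
            msg <- c(msg, "condition must be none/EtOH/DHT")
    }
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(msg)) msg else TRUE
})

#' Construct a StarrExperiment
#'
#' @param counts integer matrix, regions x samples.
#' @param role character vector per sample: "plasmid" or "rna".
#' @param condition character per sample: "none" (plasmid), "EtOH" or "DHT".
#' @param rowRanges optional \code{GRanges} of the assayed regions.
#' @param rowData optional \code{DataFrame} of region annotations.
#' @return A \code{StarrExperiment}.
#' @examples
#' cnt <- matrix(rpois(12, 50), 2, 6,
#'   dimnames = list(c("r1", "r2"), paste0("s", 1:6)))
#' se <- starrExperiment(cnt, role = rep(c("plasmid", "rna", "rna"), each = 2),
#'   condition = rep(c("none", "EtOH", "DHT"), each = 2))
#' se
#' @export
starrExperiment <- function(counts, role, condition, rowRanges = NULL,
                            rowData = NULL) {
    cd <- S4Vectors::DataFrame(role = role, condition = condition,
                               row.names = colnames(counts))
    args <- list(assays = list(counts = counts), colData = cd)
    if (!is.null(rowRanges)) {
        if (!is.null(rowData))
            S4Vectors::mcols(rowRanges) <- cbind(
                S4Vectors::mcols(rowRanges),
                rowData[, setdiff(colnames(rowData),
                    colnames(S4Vectors::mcols(rowRanges))), drop = FALSE])
        args$rowRanges <- rowRanges
    } else if (!is.null(rowData)) args$rowData <- rowData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    if (!is(se, "RangedSummarizedExperiment"))
        se <- as(se, "RangedSummarizedExperiment")
    new("StarrExperiment", se)
}

#' Typed cis-regulatory element network
#'
#' Undirected graph whose nodes are typed CREs (enhancer classes, DEG
#' promoters, untested ARBS) and whose edges are chromatin loops or
#' co-accessibility links. Self-edges are permitted (a loop joining two
#' intervals that map to the same node); duplicate edges are collapsed at
#' construction.
#'
#' @slot graph an \code{igraph} object (undirected, simple up to self-loops).
#' @slot nodeClass named character, class per node id.
#' @export
setClass("CRENetwork", representation(graph = "igraph",
                                      nodeClass = "character"))

setValidity("CRENetwork", function(object) {
    msg <- character()
    vn <- igraph::V(object@graph)$name
    if (is.null(vn)) msg <- c(msg, "graph vertices must be named")
    else if (!setequal(vn, names(object@nodeClass)) ||
             length(vn) != length(object@nodeClass))
        msg <- c(msg, "nodeClass must annotate exactly the graph's vertices")
    if (igraph::any_multiple(object@graph))
        msg <- c(msg, "duplicate edges are not allowed")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CRENetwork", function(object) {
    g <- object@graph
    comp <- igraph::components(g)
    cat("CRENetwork: ", igraph::vcount(g), " nodes, ", igraph::ecount(g),
        " edges, ", comp$no, " components\n", sep = "")
    print(table(class = object@nodeClass))
})

#' Occupancy feature table
#'
#' Per-region, per-factor DNA-binding occupancy in [0,1], produced by SES
#' cutoff estimation against matched control scores followed by a sigmoid
#' transform anchored at the cutoff (occupancy 0.1) and at the median of
#' above-cutoff scores (occupancy 0.5). Missing raw scores are imputed as
#' occupancy 0 and flagged in the mask.
#'
#' @slot occupancy numeric matrix regions x factors in [0,1].
#' @slot raw numeric matrix of raw scores (NA where missing).
#' @slot control list of numeric control-score vectors, one per factor.
#' @slot cutoff named numeric, per-factor SES cutoff.
#' @slot midpoint named numeric, per-factor sigmoid midpoint m.
#' @slot mask logical matrix, TRUE where the raw score was missing.
#' @slot uninformative named logical, TRUE where no score exceeded the
#'   cutoff (occupancy all zero).
#' @export
setClass("OccupancyTable", representation(
    occupancy = "matrix", raw = "matrix", control = "list",
    cutoff = "numeric", midpoint = "numeric", mask = "matrix",
    uninformative = "logical"))

setValidity("OccupancyTable", function(object) {
    msg <- character()
    occ <- object@occupancy
    if (any(occ < 0 | occ > 1, na.rm = TRUE))
        msg <- c(msg, "occupancy must lie in [0,1]")
    if (!identical(dim(occ), dim(object@raw)) ||
        !identical(dim(occ), dim(object@mask)))
        msg <- c(msg, "occupancy, raw and mask must share dimensions")
    fids <- colnames(occ)
    if (!identical(names(object@cutoff), fids) ||
        !identical(names(object@midpoint), fids))
        msg <- c(msg, "cutoff/midpoint must be named by factor")
    if (length(msg)) msg else TRUE
})

setMethod("show", "OccupancyTable", function(object) {
    cat("OccupancyTable: ", nrow(object@occupancy), " regions x ",
        ncol(object@occupancy), " factors; ",
        sum(object@mask), " masked scores (",
        sprintf("%.1f%%", 100 * mean(object@mask)), "); ",
        sum(object@uninformative), " uninformative factors\n", sep = "")
})

#' Bagged multinomial LASSO ensemble
#'
#' Aggregated per-class weights from many small L1-regularized multinomial
#' logistic fits, each trained on a subsample of at most \code{maxSamples}
#' regions and \code{maxFeatures} occupancy features. The aggregate weight of
#' a factor is the mean over the base estimators that sampled it; factors
#' never sampled have weight 0 and are flagged.
#'
#' @slot classLabels character, the modeled classes.
#' @slot weights numeric matrix, factors x classes (aggregated).
#' @slot intercepts named numeric per class (mean over estimators).
#' @slot nEstimators integer, base estimators fitted.
#' @slot factorSampleCount named integer, times each factor was sampled.
#' @slot hyperparams list: maxSamples, maxFeatures, l1Penalty, seed.
#' @export
setClass("EnsembleModel", representation(
    classLabels = "character", weights = "matrix", intercepts = "numeric",
    nEstimators = "integer", factorSampleCount = "integer",
    hyperparams = "list"))

setValidity("EnsembleModel", function(object) {
    msg <- character()
    if (!identical(colnames(object@weights), object@classLabels))
        msg <- c(msg, "weights columns must match classLabels")
    if (!identical(names(object@intercepts), object@classLabels))
        msg <- c(msg, "intercepts must be named by class")
    if (!identical(names(object@factorSampleCount),
                   rownames(object@weights)))
        msg <- c(msg, "factorSampleCount must be named by factor")
    if (length(msg)) msg else TRUE
})

setMethod("show", "EnsembleModel", function(object) {
    cat("EnsembleModel: ", object@nEstimators, " base estimators, ",
        nrow(object@weights), " factors, classes: ",
        paste(object@classLabels, collapse = "/"), "\n", sep = "")
    cat("  never-sampled factors:", sum(object@factorSampleCount == 0L), "\n")
    cat("  l1 penalty ", object@hyperparams$l1Penalty, ", <= ",
        object@hyperparams$maxSamples, " samples / ",
        object@hyperparams$maxFeatures, " features per estimator\n",
        sep = "")
})

#' DeltaCon affinity matrix
#'
#' Node-affinity matrix S = (I + eps^2 D - eps A)^-1 of an undirected graph
#' on a fixed node ordering, where A is the 0/1 adjacency, D the diagonal
#' degree matrix and eps = 1/(1 + max degree). Graphs under comparison share
#' the ordering and eps, so their affinities are directly comparable.
#'
#' @slot S numeric square matrix of affinities.
#' @slot epsilon the eps constant used.
#' @slot nodeOrder character, row/column node ids.
#' @export
setClass("AffinityMatrix", representation(
    S = "matrix", epsilon = "numeric", nodeOrder = "character"))

setValidity("AffinityMatrix", function(object) {
    msg <- character()
    S <- object@S
    if (nrow(S) != ncol(S)) msg <- c(msg, "S must be square")
    if (length(object@nodeOrder) != nrow(S))
        msg <- c(msg, "nodeOrder length must match S")
    if (max(abs(S - t(S))) > 1e-9)
        msg <- c(msg, "S must be symmetric (tol 1e-9)")
    if (object@epsilon <= 0 || object@epsilon > 1)
        msg <- c(msg, "epsilon must lie in (0,1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AffinityMatrix", function(object) {
    cat("AffinityMatrix: ", nrow(object@S), " nodes, epsilon = ",
        format(object@epsilon, digits = 4), "\n", sep = "")
})
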