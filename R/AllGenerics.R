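#' @importFrom BiocGenerics counts
NULL

#' Accessors for StarrCRE classes
#'
#' Small accessor generics: \code{nodeClasses} returns the per-node class
#' labels of a \code{CRENetwork}; \code{interactionGraph} the underlying
#' igraph; \code{occupancyMatrix} the [0,1] feature matrix of an
#' \code{OccupancyTable}; \code{classWeights} the aggregated factor-by-class
#' weight matrix of an \code{EnsembleModel}; \code{plantedClasses} the
#' ground-truth labels of a \code{SyntheticTruth}.
#'
#' @param x the object.
#' @return The extracted component (see details above).
#' @examples
#' truth <- simulateRegions(simulationConfig(nClinical = 20, nAreOnly = 0,
#'   nPositiveCtrl = 0, seed = 1))$truth
#' table(plantedClasses(truth))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeClasses", function(x) standardGeneric("nodeClasses"))
#' @rdname accessors
#' @export
setMethod("nodeClasses", "CRENetwork", function(x) x@nodeClass)

#' @rdname accessors
#' @export
setGeneric("interactionGraph",
           function(x) standardGeneric("interactionGraph"))
#' @rdname accessors
#' @export
setMethod("interactionGraph", "CRENetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("occupancyMatrix",
           function(x) standardGeneric("occupancyMatrix"))
#' @rdname accessors
#' @export
setMethod("occupancyMatrix", "OccupancyTable", function(x) x@occupancy)

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setMethod("missingMask", "OccupancyTable", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("classWeights", function(x) standardGeneric("classWeights"))
#' @rdname accessors
#' @export
setMethod("classWeights", "EnsembleModel", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("plantedClasses", function(x) standardGeneric("plantedClasses"))
#' @rdname accessors
#' @export
setMethod("plantedClasses", "SyntheticTruth", function(x) x@regionClass)
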