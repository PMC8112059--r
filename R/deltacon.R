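#' @importFrom igraph as_adjacency_matrix
NULL

#' Threshold a scored co-accessibility edge list into a graph
#'
#' Keeps a pair as an (unweighted) edge iff its co-accessibility score
#' strictly exceeds \code{threshold}; scores are not carried as weights.
#' Nodes are the supplied node table, so the two condition graphs share a
#' vertex set even when their edges differ.
#'
#' @param scoredEdges \code{data.frame} with \code{region_a},
#'   \code{region_b}, \code{score}.
#' @param nodeClass named character of class per node id.
#' @param threshold score cutoff (default 0.1, strict).
#' @return A \code{\link{CRENetwork-class}}.
#' @examples
#' ed <- data.frame(region_a = c("a", "a"), region_b = c("b", "c"),
#'   score = c(0.1, 0.4))
#' net <- buildCoaccessGraph(ed, c(a = "inducible", b = "inactive",
#'   c = "inactive"))
#' igraph::ecount(interactionGraph(net))  # only the 0.4 edge survives
#' @export
buildCoaccessGraph <- function(scoredEdges, nodeClass, threshold = 0.1) {
    stopifnot(is.numeric(scoredEdges$score))
    keep <- scoredEdges$score > threshold
    buildGraph(data.frame(nodeA = scoredEdges$region_a[keep],
                          nodeB = scoredEdges$region_b[keep],
                          stringsAsFactors = FALSE),
               nodeClass)
}

.adjacencyOn <- function(graph, nodeOrder) {
    vn <- igraph::V(graph)$name
    extra <- setdiff(vn, nodeOrder)
    if (length(extra))
        stop("nodeOrder does not cover graph node(s): ",
             paste(utils::head(extra, 5), collapse = ", "))
    A <- matrix(0, length(nodeOrder), length(nodeOrder),
                dimnames = list(nodeOrder, nodeOrder))
    if (igraph::ecount(graph) > 0) {
        el <- igraph::as_edgelist(graph, names = TRUE)
        A[cbind(el[, 1], el[, 2])] <- 1
        A[cbind(el[, 2], el[, 1])] <- 1
    }
    A
}

#' DeltaCon affinity matrix
#'
#' Computes S = (I + eps^2 D - eps A)^-1 on a fixed node ordering, where A
#' is the 0/1 adjacency (absent nodes giving zero rows/columns), D the
#' diagonal degree matrix and eps = 1/(1 + max degree). When two graphs are
#' compared, pass a shared \code{epsilon} computed from the maximum degree
#' across both (see \code{\link{deltaCon}}), so their affinities are on the
#' same scale. The system matrix is strictly diagonally dominant, hence
#' invertible; a singular matrix is a hard error. An edgeless graph yields
#' eps = 1 and S = I.
#'
#' @param graph an \code{igraph} or \code{CRENetwork}.
#' @param nodeOrder character vector fixing row/column order (must cover the
#'   graph's nodes; defaults to the graph's own nodes).
#' @param epsilon optional shared eps; default 1/(1 + max degree of this
#'   graph).
#' @return An \code{\link{AffinityMatrix-class}}.
#' @examples
#' g <- igraph::make_graph(~ a - b)
#' affinityMatrix(g)
#' @export
affinityMatrix <- function(graph, nodeOrder = NULL, epsilon = NULL) {
    if (is(graph, "CRENetwork")) graph <- graph@graph
    if (is.null(nodeOrder)) nodeOrder <- igraph::V(graph)$name
    A <- .adjacencyOn(graph, nodeOrder)
    dii <- rowSums(A)
    if (is.null(epsilon)) epsilon <- 1 / (1 + max(dii, 0))
    M <- diag(length(nodeOrder)) + epsilon^2 * diag(dii,
        nrow = length(dii)) - epsilon * A
    S <- tryCatch(solve(M), error = function(e)
        stop("affinity system singular (should be impossible: ",
             "matrix is diagonally dominant): ", conditionMessage(e)))
    S <- (S + t(S)) / 2
    dimnames(S) <- list(nodeOrder, nodeOrder)
    new("AffinityMatrix", S = S, epsilon = epsilon, nodeOrder = nodeOrder)
}

.sqrtClip <- function(S) {
    neg <- S < 0
    if (any(neg)) {
        warning(sum(neg), " negative affinities clipped to 0 before sqrt")
        S[neg] <- 0
    }
    sqrt(S)
}

#' Root Euclidean distance between affinity matrices
#'
#' d = sqrt(sum_ij (sqrt(s1_ij) - sqrt(s2_ij))^2). Small negative
#' affinities (numerically possible) are clipped to 0 before the square
#' root, with a warning. Zero iff the matrices are equal; symmetric.
#'
#' @param S1,S2 \code{AffinityMatrix} objects or plain matrices with
#'   identical node ordering and shape.
#' @return The RootED distance (>= 0).
#' @export
rootedDistance <- function(S1, S2) {
    if (is(S1, "AffinityMatrix")) S1 <- S1@S
    if (is(S2, "AffinityMatrix")) S2 <- S2@S
    if (!identical(dim(S1), dim(S2)))
        stop("affinity matrices differ in shape")
    sqrt(sum((.sqrtClip(S1) - .sqrtClip(S2))^2))
}

#' Per-node impact of a graph perturbation
#'
#' For each node whose incident edge set differs between the two graphs
#' (symmetric difference nonempty), the impact w is the RootED distance
#' between the corresponding rows of the two affinity matrices; for all
#' other nodes w = 0 by rule. Both affinities are computed on the union
#' node ordering with a shared eps from the maximum degree across both
#' graphs.
#'
#' @param graphA,graphB \code{igraph} or \code{CRENetwork} objects on a
#'   shared node universe.
#' @param nodeOrder optional explicit ordering (default: union of nodes,
#'   sorted).
#' @return Named numeric vector of impacts w (>= 0).
#' @export
nodeImpact <- function(graphA, graphB, nodeOrder = NULL) {
    if (is(graphA, "CRENetwork")) graphA <- graphA@graph
    if (is(graphB, "CRENetwork")) graphB <- graphB@graph
    if (is.null(nodeOrder))
        nodeOrder <- sort(union(igraph::V(graphA)$name,
                                igraph::V(graphB)$name))
    Aa <- .adjacencyOn(graphA, nodeOrder)
    Ab <- .adjacencyOn(graphB, nodeOrder)
    eps <- 1 / (1 + max(rowSums(Aa), rowSums(Ab)))
    Sa <- affinityMatrix(graphA, nodeOrder, epsilon = eps)@S
    Sb <- affinityMatrix(graphB, nodeOrder, epsilon = eps)@S
    altered <- rowSums(Aa != Ab) > 0
    w <- numeric(length(nodeOrder))
    names(w) <- nodeOrder
    if (any(altered)) {
        d1 <- .sqrtClip(Sa[altered, , drop = FALSE]) -
              .sqrtClip(Sb[altered, , drop = FALSE])
        w[altered] <- sqrt(rowSums(d1^2))
    }
    w
}

#' DeltaCon comparison of two condition graphs
#'
#' Convenience wrapper: shared-eps affinity matrices on the union node
#' ordering, the RootED distance d between them, and the per-node impact
#' vector w.
#'
#' @inheritParams nodeImpact
#' @return A list: \code{d}, \code{impact} (named numeric), \code{epsilon},
#'   \code{nodeOrder}.
#' @examples
#' g1 <- igraph::make_graph(~ a - b, c)
#' g2 <- igraph::make_graph(~ a - b, a - c)
#' deltaCon(g1, g2)$d
#' @export
deltaCon <- function(graphA, graphB, nodeOrder = NULL) {
    if (is(graphA, "CRENetwork")) graphA <- graphA@graph
    if (is(graphB, "CRENetwork")) graphB <- graphB@graph
    if (is.null(nodeOrder))
        nodeOrder <- sort(union(igraph::V(graphA)$name,
                                igraph::V(graphB)$name))
    Aa <- .adjacencyOn(graphA, nodeOrder)
    Ab <- .adjacencyOn(graphB, nodeOrder)
    eps <- 1 / (1 + max(rowSums(Aa), rowSums(Ab)))
    Sa <- affinityMatrix(graphA, nodeOrder, epsilon = eps)
    Sb <- affinityMatrix(graphB, nodeOrder, epsilon = eps)
    list(d = rootedDistance(Sa, Sb),
         impact = nodeImpact(graphA, graphB, nodeOrder),
         epsilon = eps, nodeOrder = nodeOrder)
}

#' Class-level summary of node impacts
#'
#' Groups per-node DeltaCon impacts by enhancer class and compares classes
#' pairwise with the two-sided Mann-Whitney test (BH-corrected). Classes
#' with fewer than 2 nodes are skipped with a warning; an all-tied
#' comparison (e.g. all impacts zero under a null perturbation) reports
#' p = 1 rather than failing.
#'
#' @param impact named numeric vector from \code{\link{nodeImpact}}.
#' @param classes named character of class per node.
#' @return A list: \code{summary} (per-class n/median/mean) and
#'   \code{tests} (pairwise table).
#' @export
classImpactSummary <- function(impact, classes) {
    ids <- intersect(names(impact), names(classes))
    if (!length(ids)) stop("no shared node ids")
    w <- impact[ids]; cls <- as.character(classes[ids])
    summ <- do.call(rbind, lapply(sort(unique(cls)), function(cl) {
        data.frame(class = cl, n = sum(cls == cl),
                   median = median(w[cls == cl]),
                   mean = mean(w[cls == cl]))
    }))
    list(summary = summ, tests = .pairwiseWilcox(w, cls))
}
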