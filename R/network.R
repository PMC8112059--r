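#' @importFrom GenomicRanges findOverlaps distanceToNearest
#' @importFrom igraph graph_from_data_frame components V vcount ecount
#'   degree betweenness induced_subgraph simplify any_multiple
NULL

.grFromBedpeAnchor <- function(df, which = 1) {
    s <- df[[paste0("start", which)]]
    e <- df[[paste0("end", which)]]
    GenomicRanges::GRanges(df[[paste0("chrom", which)]],
                           IRanges::IRanges(s + 1L, e))
}

#' Label loop anchors with overlapping regions and DEG promoters
#'
#' Intersects each end of every chromatin loop with the region set and with
#' windows of +/- \code{window} bp around DEG transcription start sites
#' (only TSS labeled \code{up} or \code{down} become network nodes). All
#' coordinates of \code{interactions} are 0-based half-open (BEDPE); region
#' and TSS coordinates are 1-based \code{GRanges}. An anchor overlapping k
#' features emits k labels and every label pair across the two ends becomes
#' an edge; loops with an unlabeled end emit nothing.
#'
#' @param interactions BEDPE-layout \code{data.frame} (chrom1, start1, end1,
#'   chrom2, start2, end2, name, ...).
#' @param regions named \code{GRanges} of candidate CREs.
#' @param tss \code{GRanges} of TSS with mcols \code{gene} and
#'   \code{direction} (up/down/none).
#' @param window half-width of the promoter window in bp (default 5000).
#' @return \code{data.frame} with \code{nodeA}, \code{nodeB}, \code{loop}.
#' @examples
#' loops <- data.frame(chrom1 = "chrS", start1 = 100, end1 = 200,
#'   chrom2 = "chrS", start2 = 10000, end2 = 10100, name = "loop_1")
#' regs <- GenomicRanges::GRanges("chrS", IRanges::IRanges(151, 750))
#' names(regs) <- "r1"
#' tss <- GenomicRanges::GRanges("chrS", IRanges::IRanges(5101, width = 1),
#'   gene = "g1", direction = "up")
#' names(tss) <- "g1"
#' anchorOverlap(loops, regs, tss)
#' @export
anchorOverlap <- function(interactions, regions, tss, window = 5000) {
    deg <- tss[tss$direction %in% c("up", "down")]
    win <- GenomicRanges::GRanges(GenomicRanges::seqnames(deg),
        IRanges::IRanges(pmax(1L, GenomicRanges::start(deg) - window),
                         GenomicRanges::start(deg) + window - 1L))
    names(win) <- names(deg)

    labelsFor <- function(anchors) {
        hr <- GenomicRanges::findOverlaps(anchors, regions)
        ht <- GenomicRanges::findOverlaps(anchors, win)
        list(split(names(regions)[S4Vectors::subjectHits(hr)],
                   factor(S4Vectors::queryHits(hr),
                          levels = seq_along(anchors))),
             split(names(win)[S4Vectors::subjectHits(ht)],
                   factor(S4Vectors::queryHits(ht),
                          levels = seq_along(anchors))))
    }
    a1 <- .grFromBedpeAnchor(interactions, 1)
    a2 <- .grFromBedpeAnchor(interactions, 2)
    l1 <- labelsFor(a1); l2 <- labelsFor(a2)
    out <- vector("list", nrow(interactions))
    for (i in seq_len(nrow(interactions))) {
        la <- c(l1[[1]][[i]], l1[[2]][[i]])
        lb <- c(l2[[1]][[i]], l2[[2]][[i]])
        if (!length(la) || !length(lb)) next
        grid <- expand.grid(nodeA = la, nodeB = lb,
                            stringsAsFactors = FALSE)
        grid$loop <- interactions$name[i]
        out[[i]] <- grid
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(nodeA = character(), nodeB = character(),
                          loop = character(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Build a typed CRE network
#'
#' Assembles a deduplicated undirected graph from a labeled edge list; a
#' loop whose two ends map to the same node is kept as a self-edge. Nodes
#' are the supplied node table (edges referencing unknown nodes are an
#' error), so isolated CREs remain in the graph.
#'
#' @param edges \code{data.frame} with columns \code{nodeA}, \code{nodeB}.
#' @param nodeClass named character vector: class per node id, drawn from
#'   inducible/constitutive/inactive/ambiguous/untested_ARBS/TSS_up/TSS_down.
#' @return A \code{\link{CRENetwork-class}}.
#' @examples
#' net <- buildGraph(data.frame(nodeA = c("a", "a"), nodeB = c("b", "b")),
#'   c(a = "inducible", b = "TSS_up", c = "inactive"))
#' net
#' @export
buildGraph <- function(edges, nodeClass) {
    unknown <- setdiff(unique(c(edges$nodeA, edges$nodeB)),
                       names(nodeClass))
    if (length(unknown))
        stop("edge references unknown node(s): ",
             paste(utils::head(unknown, 5), collapse = ", "))
    g <- igraph::graph_from_data_frame(
        edges[, c("nodeA", "nodeB"), drop = FALSE], directed = FALSE,
        vertices = data.frame(name = names(nodeClass)))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
    new("CRENetwork", graph = g, nodeClass = nodeClass)
}

#' Relative graph density
#'
#' D = 2 E_obs / (V (V + 1)): the observed edge count relative to the number
#' of unordered node pairs including self-pairs, so a complete graph with
#' all self-loops has density 1.
#'
#' @param eObs observed edge count.
#' @param v node count (>= 1).
#' @return Density in [0, 1].
#' @examples
#' graphDensity(6, 3)  # complete + self-loops on 3 nodes
#' @export
graphDensity <- function(eObs, v) {
    if (v < 1) stop("V must be >= 1")
    2 * eObs / (v * (v + 1))
}

#' Expected maximum edge count between classes
#'
#' Within a class the maximum is the number of combinations with repetition,
#' V (V + 1) / 2 (self-pairs allowed, duplicates not double-counted); across
#' two classes it is V x U.
#'
#' @param v node count of the first class.
#' @param u node count of the second class; omit (NULL) for the same-class
#'   case.
#' @return The maximum possible edge count.
#' @examples
#' expectedMaxEdges(3)       # 6
#' expectedMaxEdges(3, 4)    # 12
#' @export
expectedMaxEdges <- function(v, u = NULL) {
    stopifnot(v >= 1)
    if (is.null(u)) v * (v + 1) / 2 else {
        stopifnot(u >= 1)
        v * u
    }
}

.edgeEndClasses <- function(net) {
    el <- igraph::as_edgelist(net@graph, names = TRUE)
    cbind(net@nodeClass[el[, 1]], net@nodeClass[el[, 2]])
}

#' Interaction frequency between two node classes
#'
#' The observed edge count between (or within) classes relative to its
#' expected maximum, normalized by the whole-graph relative density:
#' IF = E_obs / (D * E_max). Self-edges count once; the same-class maximum
#' uses combinations with repetition. When the whole graph has no edges
#' (D = 0) the statistic is undefined and \code{NA} is returned.
#'
#' @param net a \code{CRENetwork}.
#' @param classU,classV class labels (may be equal).
#' @return A one-row \code{data.frame}: classU, classV, nU, nV, eObs, eMax,
#'   density, IF.
#' @export
interactionFrequency <- function(net, classU, classV) {
    cls <- net@nodeClass
    nU <- sum(cls == classU); nV <- sum(cls == classV)
    if (nU == 0 || nV == 0)
        stop("class not present in graph: ",
             if (nU == 0) classU else classV)
    ends <- .edgeEndClasses(net)
    if (classU == classV) {
        eObs <- sum(ends[, 1] == classU & ends[, 2] == classU)
        eMax <- expectedMaxEdges(nU)
    } else {
        eObs <- sum((ends[, 1] == classU & ends[, 2] == classV) |
                    (ends[, 1] == classV & ends[, 2] == classU))
        eMax <- expectedMaxEdges(nU, nV)
    }
    D <- graphDensity(igraph::ecount(net@graph),
                      igraph::vcount(net@graph))
    IF <- if (D == 0) NA_real_ else eObs / (D * eMax)
    data.frame(classU = classU, classV = classV, nU = nU, nV = nV,
               eObs = eObs, eMax = eMax, density = D, IF = IF)
}

.largestComponent <- function(g) {
    comp <- igraph::components(g)
    sizes <- comp$csize
    big <- which(sizes == max(sizes))
    if (length(big) > 1) {
        ## deterministic tie-break: component holding the smallest node id
        firstName <- vapply(big, function(ci)
            min(igraph::V(g)$name[comp$membership == ci]), character(1))
        big <- big[order(firstName)][1]
    }
    igraph::induced_subgraph(g,
        which(comp$membership == big))
}

#' Centrality on the largest connected component
#'
#' Degree centrality (degree / (n - 1), self-loops counting twice) and
#' betweenness centrality (normalized by (n - 1)(n - 2) / 2) for every node
#' of the largest connected component; a disconnected graph biases
#' whole-graph centrality comparisons, so smaller components are excluded.
#' Ties for the largest component go to the one containing the
#' lexicographically smallest node id.
#'
#' @param net a \code{CRENetwork}.
#' @return \code{data.frame}: node, class, degree, degreeCentrality,
#'   betweenness.
#' @export
networkCentrality <- function(net) {
    if (igraph::vcount(net@graph) == 0) stop("empty graph")
    sub <- .largestComponent(net@graph)
    n <- igraph::vcount(sub)
    deg <- igraph::degree(sub, loops = TRUE)
    btw <- igraph::betweenness(sub, directed = FALSE,
                               normalized = n > 2)
    data.frame(node = igraph::V(sub)$name,
               class = unname(net@nodeClass[igraph::V(sub)$name]),
               degree = unname(deg),
               degreeCentrality = if (n > 1) unname(deg) / (n - 1)
                                  else 0,
               betweenness = unname(btw), row.names = NULL)
}

.pairwiseWilcox <- function(values, groups, minPer = 2L) {
    lv <- sort(unique(groups))
    sizes <- table(groups)
    usable <- lv[sizes[lv] >= minPer]
    dropped <- setdiff(lv, usable)
    if (length(dropped))
        warning("class(es) with < ", minPer, " nodes skipped: ",
                paste(dropped, collapse = ", "))
    if (length(usable) < 2) stop("need >= 2 usable classes")
    cmb <- utils::combn(usable, 2, simplify = FALSE)
    res <- do.call(rbind, lapply(cmb, function(cmp) {
        a <- values[groups == cmp[1]]
        b <- values[groups == cmp[2]]
        p <- if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) 1
             else suppressWarnings(wilcox.test(a, b)$p.value)
        data.frame(classA = cmp[1], classB = cmp[2],
                   medianA = median(a), medianB = median(b),
                   nA = length(a), nB = length(b), pvalue = p)
    }))
    res$padj <- bhAdjust(res$pvalue)
    res
}

#' Loop counts per enhancer class
#'
#' Per-node edge counts (self-loops counting twice, so degrees sum to 2E)
#' grouped by node class, with two-sided Mann-Whitney comparisons between
#' all class pairs and BH correction.
#'
#' @param net a \code{CRENetwork}.
#' @param classes optional subset of classes to compare.
#' @return A list: \code{degrees} (data.frame node/class/degree) and
#'   \code{tests} (pairwise comparison table).
#' @export
loopCountByClass <- function(net, classes = NULL) {
    deg <- igraph::degree(net@graph, loops = TRUE)
    cls <- net@nodeClass[names(deg)]
    if (!is.null(classes)) {
        keep <- cls %in% classes
        deg <- deg[keep]; cls <- cls[keep]
    }
    if (length(unique(cls)) < 2) stop("need >= 2 classes")
    list(degrees = data.frame(node = names(deg), class = unname(cls),
                              degree = unname(deg), row.names = NULL),
         tests = .pairwiseWilcox(unname(deg), unname(cls)))
}

#' Binned ECDF of distance to the nearest up-regulated promoter
#'
#' For every region, the distance to the nearest up-DEG TSS (0 when
#' overlapping), floored to \code{bin}-bp bins; the cumulative distribution
#' is returned per enhancer class.
#'
#' @param regions named \code{GRanges} with an mcol \code{class}.
#' @param promoters \code{GRanges} of up-DEG TSS (width-1 positions).
#' @param bin bin width in bp (default 100).
#' @return Named list per class of \code{data.frame} (\code{bin},
#'   \code{cumfrac}); each ECDF is nondecreasing and ends at 1.
#' @export
distanceEcdf <- function(regions, promoters, bin = 100) {
    if (length(promoters) == 0) stop("promoter set is empty")
    hits <- GenomicRanges::distanceToNearest(regions, promoters)
    d <- rep(NA_real_, length(regions))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    binned <- floor(d / bin) * bin
    cls <- S4Vectors::mcols(regions)$class
    out <- list()
    for (cl in sort(unique(as.character(cls)))) {
        b <- sort(binned[cls == cl & !is.na(binned)])
        if (!length(b)) next
        ub <- unique(b)
        out[[cl]] <- data.frame(bin = ub,
            cumfrac = cumsum(as.numeric(table(factor(b, levels = ub)))) /
                length(b))
    }
    out
}
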