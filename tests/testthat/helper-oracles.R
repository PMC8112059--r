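## Independent oracles used across tests: deliberately naive
## implementations that do not share code paths with the package.

## connected components by breadth-first search over an edge list
bfsComponents <- function(nodes, edges) {
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
        a <- edges$nodeA[i]; b <- edges$nodeB[i]
        adj[[a]] <- union(adj[[a]], b)
        adj[[b]] <- union(adj[[b]], a)
    }
    seen <- setNames(logical(length(nodes)), nodes)
    comp <- 0L
    for (v in nodes) {
        if (seen[v]) next
        comp <- comp + 1L
        queue <- v
        while (length(queue)) {
            u <- queue[1]; queue <- queue[-1]
            if (seen[u]) next
            seen[u] <- TRUE
            queue <- c(queue, adj[[u]][!seen[adj[[u]]]])
        }
    }
    comp
}

## normalized betweenness by exhaustive shortest-path enumeration
bruteBetweenness <- function(g) {
    vs <- igraph::V(g)$name
    n <- length(vs)
    btw <- setNames(numeric(n), vs)
    if (n < 3) return(btw)
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            paths <- igraph::all_simple_paths(g, from = vs[i], to = vs[j])
            if (!length(paths)) next
            lens <- vapply(paths, length, integer(1))
            short <- paths[lens == min(lens)]
            inner <- unlist(lapply(short, function(p)
                setdiff(igraph::as_ids(p), c(vs[i], vs[j]))))
            if (length(inner)) {
                tb <- table(inner) / length(short)
                btw[names(tb)] <- btw[names(tb)] + as.numeric(tb)
            }
        }
    }
    btw / ((n - 1) * (n - 2) / 2)
}

## interaction frequency by direct edge counting on the raw edge list
bruteIF <- function(edges, classes, u, v) {
    nU <- sum(classes == u); nV <- sum(classes == v)
    ca <- classes[edges$nodeA]; cb <- classes[edges$nodeB]
    if (u == v) {
        eObs <- sum(ca == u & cb == u)
        eMax <- nU * (nU + 1) / 2
    } else {
        eObs <- sum((ca == u & cb == v) | (ca == v & cb == u))
        eMax <- nU * nV
    }
    Vt <- length(classes)
    D <- 2 * nrow(edges) / (Vt * (Vt + 1))
    if (D == 0) return(NA_real_)
    eObs / (D * eMax)
}

## random deduplicated labeled graph (self-loops allowed)
randomLabeledGraph <- function(nNodes, nEdges, nClasses = 3, seed = 1) {
    set.seed(seed)
    nodes <- sprintf("n%02d", seq_len(nNodes))
    a <- sample(nodes, nEdges, replace = TRUE)
    b <- sample(nodes, nEdges, replace = TRUE)
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste(lo, hi))
    edges <- data.frame(nodeA = lo[keep], nodeB = hi[keep],
                        stringsAsFactors = FALSE)
    classes <- setNames(sample(paste0("c", seq_len(nClasses)), nNodes,
                               replace = TRUE), nodes)
    list(nodes = nodes, edges = edges, classes = classes)
}

## small igraph with named vertices from an edge count
randomIgraph <- function(nNodes, pEdge, seed = 1) {
    set.seed(seed)
    nodes <- sprintf("v%02d", seq_len(nNodes))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < pEdge
    igraph::graph_from_data_frame(
        data.frame(from = pairs[keep, 1], to = pairs[keep, 2]),
        directed = FALSE, vertices = nodes)
}
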