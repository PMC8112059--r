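#' @importFrom utils read.delim write.table head
NULL

## All on-disk interval formats are 0-based half-open (BED/BEDPE);
## in-memory GRanges are 1-based closed, converted at the boundary.

#' Read and write 6-column BED region sets
#'
#' \code{writeBed} emits chrom/start/end/name/score/strand (0-based
#' half-open, score 0, strand "."); \code{readBed} returns a named
#' \code{GRanges}.
#'
#' @param gr a named \code{GRanges}.
#' @param path file path.
#' @return \code{readBed}: a \code{GRanges}; \code{writeBed}: invisibly,
#'   the path.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = if (is.null(names(gr))) "." else names(gr),
        score = 0L, strand = ".")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("BED needs >= 3 columns: ", path)
    gr <- GenomicRanges::GRanges(df[[1]],
        IRanges::IRanges(df[[2]] + 1L, df[[3]]))
    if (ncol(df) >= 4) names(gr) <- df[[4]]
    gr
}

#' Read and write 7-column BEDPE interaction files
#'
#' Anchor pairs with a pair id in column 7 (0-based half-open coordinates).
#' \code{readBedpe} validates every row and reports the 1-based line number
#' of the first malformed one.
#'
#' @param interactions \code{data.frame} with chrom1, start1, end1, chrom2,
#'   start2, end2, name (extra columns are dropped on write).
#' @param path file path.
#' @return \code{readBedpe}: the validated \code{data.frame};
#'   \code{writeBedpe}: invisibly, the path.
#' @export
writeBedpe <- function(interactions, path) {
    cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
              "name")
    write.table(interactions[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeBedpe
#' @export
readBedpe <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                     colClasses = c("character", "numeric", "numeric",
                                    "character", "numeric", "numeric",
                                    "character"))
    colnames(df) <- c("chrom1", "start1", "end1", "chrom2", "start2",
                      "end2", "name")
    bad <- which(!is.finite(df$start1) | !is.finite(df$end1) |
                 !is.finite(df$start2) | !is.finite(df$end2) |
                 df$end1 <= df$start1 | df$end2 <= df$start2 |
                 df$start1 < 0 | df$start2 < 0)
    if (length(bad))
        stop("malformed BEDPE row at line ", bad[1], " of ", path)
    df
}

#' Read and write STARR-seq counts with a sample-role sidecar
#'
#' The count matrix is a TSV with a header row of sample ids and region ids
#' in the first column; the sidecar TSV (\code{sample}, \code{role},
#' \code{condition}) declares each sample's role in the assay.
#'
#' @param se a \code{StarrExperiment}.
#' @param countsPath,rolesPath file paths.
#' @param regions optional \code{GRanges} for the rows when reading (a stub
#'   contig is used if absent).
#' @return \code{readStarrCounts}: a \code{StarrExperiment};
#'   \code{writeStarrCounts}: invisibly, \code{countsPath}.
#' @export
writeStarrCounts <- function(se, countsPath, rolesPath) {
    cnt <- SummarizedExperiment::assay(se, "counts")
    df <- data.frame(region_id = rownames(cnt), cnt, check.names = FALSE)
    write.table(df, countsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- SummarizedExperiment::colData(se)
    write.table(data.frame(sample = colnames(se), role = cd$role,
                           condition = cd$condition),
                rolesPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(countsPath)
}

#' @rdname writeStarrCounts
#' @export
readStarrCounts <- function(countsPath, rolesPath, regions = NULL) {
    df <- read.delim(countsPath, check.names = FALSE,
                     stringsAsFactors = FALSE)
    cnt <- as.matrix(df[, -1, drop = FALSE])
    rownames(cnt) <- df[[1]]
    roles <- read.delim(rolesPath, stringsAsFactors = FALSE)
    miss <- setdiff(colnames(cnt), roles$sample)
    if (length(miss))
        stop("samples missing from role sidecar: ",
             paste(miss, collapse = ", "))
    roles <- roles[match(colnames(cnt), roles$sample), ]
    if (is.null(regions)) {
        regions <- GenomicRanges::GRanges("chrU",
            IRanges::IRanges(seq_len(nrow(cnt)) * 1000L, width = 500L))
        names(regions) <- rownames(cnt)
    }
    starrExperiment(cnt, role = roles$role, condition = roles$condition,
                    rowRanges = regions[rownames(cnt)])
}

#' Serialize an ensemble model to JSON
#'
#' Weights, intercepts, per-factor sample counts and hyperparameters in a
#' single JSON document; \code{readModelJson} restores the
#' \code{EnsembleModel}.
#'
#' @param model an \code{EnsembleModel}.
#' @param path file path.
#' @return \code{readModelJson}: an \code{EnsembleModel};
#'   \code{writeModelJson}: invisibly, the path.
#' @export
writeModelJson <- function(model, path) {
    obj <- list(classes = model@classLabels,
        factors = rownames(model@weights),
        weights = unname(asplit(model@weights, 2)),
        intercepts = unname(model@intercepts),
        nEstimators = model@nEstimators,
        factorSampleCount = unname(model@factorSampleCount),
        hyperparams = model@hyperparams)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    obj <- list(classes = unlist(obj$classes),
        factors = unlist(obj$factors),
        weights = lapply(obj$weights, unlist),
        intercepts = unlist(obj$intercepts),
        nEstimators = obj$nEstimators,
        factorSampleCount = unlist(obj$factorSampleCount),
        hyperparams = lapply(obj$hyperparams, unlist))
    W <- do.call(cbind, obj$weights)   # one serialized column per class
    dimnames(W) <- list(obj$factors, obj$classes)
    new("EnsembleModel", classLabels = obj$classes, weights = W,
        intercepts = setNames(obj$intercepts, obj$classes),
        nEstimators = as.integer(obj$nEstimators),
        factorSampleCount = setNames(as.integer(obj$factorSampleCount),
                                     obj$factors),
        hyperparams = obj$hyperparams)
}
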