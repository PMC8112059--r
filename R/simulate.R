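#' @importFrom GenomicRanges GRanges mcols mcols<- start end width seqnames
#' @importFrom IRanges IRanges
#' @importFrom stats rpois rnbinom rlnorm rnorm runif median
NULL

## Each generator derives its RNG stream from config@seed plus a fixed
## offset, so any subset of generators is reproducible regardless of call
## order.
.SEED_OFFSETS <- c(regions = 0L, counts = 1L, tss = 2L, interactions = 3L,
                   coaccess = 4L, occupancy = 5L)

.seedFor <- function(config, stage) {
    set.seed((config@seed + .SEED_OFFSETS[[stage]]) %% .Machine$integer.max)
}

## Largest-remainder apportionment of n into length(p) integer counts.
## Deterministic: ties go to the earlier class.
.apportion <- function(n, p) {
    quota <- n * p
    k <- floor(quota)
    rem <- n - sum(k)
    if (rem > 0) {
        ord <- order(quota - k, decreasing = TRUE)
        k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
    }
    as.integer(k)
}

## Non-overlapping interval starts by rejection sampling on [0, L - w).
.placeIntervals <- function(n, width, genomeLength, maxIter = 100L) {
    if (n * width > genomeLength * 0.8)
        stop("synthetic genome too short for ", n, " regions of ", width,
             " bp; increase genomeLength")
    starts <- numeric(0)
    for (iter in seq_len(maxIter)) {
        need <- n - length(starts)
        if (need <= 0L) break
        cand <- floor(runif(2L * need, 0, genomeLength - width))
        pool <- sort(c(starts, cand))
        keep <- c(TRUE, diff(pool) >= width)
        starts <- pool[keep]
        if (length(starts) > n)
            starts <- sort(sample(starts, n))
    }
    if (length(starts) < n)
        stop("internal error: interval placement failed after ", maxIter,
             " rounds")
    as.integer(starts)
}

#' Simulate a region set with planted enhancer classes
#'
#' Places non-overlapping intervals on a synthetic contig \code{chrS} and
#' assigns design groups (clinical ARBS, ARE-motif-only, positive-control)
#' and, within the clinical group, planted enhancer classes according to
#' \code{classProportions} (largest-remainder apportionment, so planted
#' counts match the rounded proportions exactly). ARE-only regions get class
#' \code{"none"} with unit reporter activity; positive controls get class
#' \code{"none"} but constitutive-level activity.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A list with \code{regions} (a \code{GRanges} with mcols
#'   \code{region_id}, \code{design_group}, \code{planted_class}) and
#'   \code{truth} (a \code{\link{SyntheticTruth-class}}).
#' @examples
#' sim <- simulateRegions(simulationConfig(nClinical = 50, nAreOnly = 10,
#'   nPositiveCtrl = 5, seed = 7))
#' table(plantedClasses(sim$truth))
#' @export
simulateRegions <- function(config) {
    validObject(config)
    .seedFor(config, "regions")
    nTot <- config@nClinical + config@nAreOnly + config@nPositiveCtrl
    if (nTot == 0L) stop("zero regions requested")
    starts0 <- .placeIntervals(nTot, config@regionWidth, config@genomeLength)

    ids <- c(sprintf("clin_%05d", seq_len(config@nClinical)),
             if (config@nAreOnly) sprintf("are_%05d",
                                          seq_len(config@nAreOnly)),
             if (config@nPositiveCtrl) sprintf("pos_%05d",
                                       seq_len(config@nPositiveCtrl)))
    group <- rep(c("clinical", "ARE-only", "positive-control"),
                 c(config@nClinical, config@nAreOnly, config@nPositiveCtrl))

    nPer <- .apportion(config@nClinical, config@classProportions)
    clinClass <- sample(rep(names(config@classProportions), nPer))
    cls <- c(clinClass, rep("none", config@nAreOnly + config@nPositiveCtrl))
    names(cls) <- ids

    lam <- config@loopBaseDegree *
        ifelse(cls == "inducible", config@hubEnrichment, 1)
    names(lam) <- ids
    names(group) <- ids

    fids <- sprintf("F%03d", seq_len(config@nFactors))
    inf <- logical(config@nFactors)
    inf[sample(config@nFactors, config@informativeFactors)] <- TRUE
    names(inf) <- fids
    tgt <- ifelse(inf, "inducible", "")
    names(tgt) <- fids

    gr <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = starts0 + 1L,
                         width = config@regionWidth))
    names(gr) <- ids
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        region_id = ids, design_group = group, planted_class = unname(cls))

    truth <- new("SyntheticTruth", regionClass = cls, designGroup = group,
                 loopDegree = lam, informativeFactor = inf,
                 factorTargetClass = tgt)
    list(regions = gr, truth = truth)
}

## Per-class expected RNA/plasmid ratio under each condition.
.classRatios <- function(cls, config) {
    dhtInd <- max(config@fcInduced, config@fcActive)
    etoh <- switch(cls,
        inducible = dhtInd / config@fcInduced,
        constitutive = config@fcActive,
        inactive = 1, 1)
    dht <- switch(cls,
        inducible = dhtInd,
        constitutive = config@fcActive,
        inactive = 1, 1)
    c(EtOH = etoh, DHT = dht)
}

#' Simulate a STARR-seq count matrix
#'
#' Draws negative-binomial counts (variance mu + alpha mu^2; Poisson when
#' \code{nbDispersion} is 0) for plasmid input and RNA replicates under
#' vehicle (EtOH) and androgen (DHT). Planted means follow the region class:
#' inducible regions have a DHT/EtOH RNA ratio of \code{fcInduced} and a
#' DHT RNA/plasmid ratio of at least \code{fcActive}; constitutive (and
#' positive-control) regions sit at \code{fcActive} in both conditions;
#' inactive and ARE-only regions at 1. Per-sample library-size factors are
#' drawn log-normal (sdlog 0.2) and recorded in
#' \code{metadata()$libSizes}; per-region baseline plasmid abundance in
#' \code{metadata()$regionBaseline}.
#'
#' @param regions \code{GRanges} from \code{\link{simulateRegions}}.
#' @param truth matching \code{SyntheticTruth}.
#' @param config the \code{\link{simulationConfig}} used throughout.
#' @return A \code{\link{StarrExperiment-class}}.
#' @examples
#' cfg <- simulationConfig(nClinical = 30, nAreOnly = 0, nPositiveCtrl = 0,
#'   seed = 2)
#' sim <- simulateRegions(cfg)
#' se <- simulateStarrCounts(sim$regions, sim$truth, cfg)
#' se
#' @export
simulateStarrCounts <- function(regions, truth, config) {
    ids <- names(regions)
    if (!all(ids %in% names(truth@regionClass)))
        stop("missing planted class for region(s): ",
             paste(utils::head(setdiff(ids, names(truth@regionClass)), 3),
                   collapse = ", "))
    .seedFor(config, "counts")
    nRep <- config@nReplicates
    sampleNames <- c(sprintf("plasmid_%d", seq_len(nRep)),
                     sprintf("etoh_%d", seq_len(nRep)),
                     sprintf("dht_%d", seq_len(nRep)))
    role <- rep(c("plasmid", "rna", "rna"), each = nRep)
    condition <- rep(c("none", "EtOH", "DHT"), each = nRep)

    n <- length(ids)
    base <- config@baselineMean * rlnorm(n, meanlog = -0.125, sdlog = 0.5)
    names(base) <- ids
    libSizes <- rlnorm(length(sampleNames), meanlog = 0, sdlog = 0.2)
    names(libSizes) <- sampleNames

    ratios <- vapply(truth@regionClass[ids], .classRatios, numeric(2),
                     config = config)   # 2 x n (EtOH, DHT)
    mu <- matrix(0, n, length(sampleNames),
                 dimnames = list(ids, sampleNames))
    for (j in seq_along(sampleNames)) {
        condMult <- switch(condition[j], none = rep(1, n),
                           EtOH = ratios["EtOH", ], DHT = ratios["DHT", ])
        mu[, j] <- base * condMult * libSizes[j]
    }
    alpha <- config@nbDispersion
    cnt <- if (alpha == 0) {
        matrix(rpois(length(mu), lambda = mu), n,
               dimnames = dimnames(mu))
    } else {
        matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha), n,
               dimnames = dimnames(mu))
    }
    se <- starrExperiment(cnt, role = role, condition = condition,
        rowRanges = regions,
        rowData = S4Vectors::DataFrame(
            design_group = truth@designGroup[ids],
            planted_class = truth@regionClass[ids]))
    S4Vectors::metadata(se)$libSizes <- libSizes
    S4Vectors::metadata(se)$regionBaseline <- base
    se
}

#' Simulate TSS annotations with DEG direction labels
#'
#' Uniform TSS positions on the synthetic contig, labeled \code{up},
#' \code{down} or \code{none} for their response to androgen
#' (differentially expressed genes); proportions 0.35/0.35/0.30.
#'
#' @inheritParams simulateStarrCounts
#' @return A width-1 \code{GRanges} with mcols \code{gene}, \code{direction}.
#' @export
simulateTss <- function(config) {
    .seedFor(config, "tss")
    n <- config@nTss
    pos <- sort(sample.int(config@genomeLength - 1L, n))
    dir <- sample(rep(c("up", "down", "none"), .apportion(n,
        c(0.35, 0.35, 0.30))))
    gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(pos, width = 1),
        strand = sample(c("+", "-"), n, replace = TRUE))
    names(gr) <- sprintf("g%04d", seq_len(n))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene = names(gr), direction = dir)
    gr
}

#' Simulate chromatin-interaction anchor pairs (loops)
#'
#' Each region emits \code{Poisson(loopDegree)} loops; a loop's partner is a
#' TSS with probability 0.5, otherwise another region chosen with
#' probability proportional to its planted degree (so the realized
#' degree ratio between classes matches \code{hubEnrichment}). Inducible
#' regions pick up-regulated DEG TSS with probability \code{tssUpBias},
#' emulating their preferential looping to androgen-activated promoters. Anchors are the
#' region interval itself, or a 500-bp window on the TSS.
#'
#' @inheritParams simulateStarrCounts
#' @param tss \code{GRanges} from \code{\link{simulateTss}}.
#' @return A \code{data.frame} in BEDPE layout (\code{chrom1, start1, end1,
#'   chrom2, start2, end2, name}; 0-based half-open) plus bookkeeping
#'   columns \code{id1}, \code{id2} with the true partner identities.
#' @export
simulateInteractions <- function(regions, truth, tss, config) {
    if (length(regions) == 0L) stop("empty region set")
    .seedFor(config, "interactions")
    ids <- names(regions)
    lam <- truth@loopDegree[ids]
    nLoop <- rpois(length(ids), lam)
    src <- rep(ids, nLoop)
    if (length(src) == 0L)
        return(data.frame(chrom1 = character(), start1 = integer(),
            end1 = integer(), chrom2 = character(), start2 = integer(),
            end2 = integer(), name = character(), id1 = character(),
            id2 = character(), stringsAsFactors = FALSE))

    isTssPartner <- runif(length(src)) < 0.5
    up <- names(tss)[tss$direction == "up"]
    pickTss <- function(fromInducible) {
        if (fromInducible && length(up) && config@tssUpBias > 0 &&
            runif(1) < config@tssUpBias)
            sample(up, 1L)
        else sample(names(tss), 1L)
    }
    srcInducible <- truth@regionClass[src] == "inducible"
    partner <- character(length(src))
    w <- lam / sum(lam)
    for (k in seq_along(src)) {
        if (isTssPartner[k]) {
            partner[k] <- pickTss(srcInducible[k])
        } else {
            repeat {
                p <- sample(ids, 1L, prob = w)
                if (p != src[k]) break
            }
            partner[k] <- p
        }
    }
    anchorOf <- function(id) {
        if (id %in% ids) {
            i <- match(id, ids)
            c(GenomicRanges::start(regions)[i] - 1L,
              GenomicRanges::end(regions)[i])
        } else {
            p <- GenomicRanges::start(tss)[match(id, names(tss))]
            c(max(0L, p - 250L), p + 250L)
        }
    }
    a1 <- t(vapply(src, anchorOf, numeric(2)))
    a2 <- t(vapply(partner, anchorOf, numeric(2)))
    data.frame(chrom1 = "chrS", start1 = a1[, 1], end1 = a1[, 2],
               chrom2 = "chrS", start2 = a2[, 1], end2 = a2[, 2],
               name = sprintf("loop_%05d", seq_along(src)),
               id1 = src, id2 = partner,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate condition-specific co-accessibility edge lists
#'
#' Generates a shared set of region pairs with base scores uniform on
#' [0, 0.3]. EtOH scores are the base scores; DHT scores add Gaussian noise
#' (\code{coaccessNoise}) shared-pair-wise, plus \code{coaccessGain} for any
#' pair adjacent to an inducible region, clipped to [0, 1]. With gain and
#' noise 0 the two lists are identical.
#'
#' @inheritParams simulateStarrCounts
#' @return A list with \code{etoh} and \code{dht}, each a \code{data.frame}
#'   (\code{region_a, region_b, score}) over the same pairs.
#' @export
simulateCoaccessibility <- function(regions, truth, config) {
    .seedFor(config, "coaccess")
    ids <- names(regions)
    n <- length(ids)
    nPartner <- rpois(n, 2)
    a <- rep(ids, nPartner)
    b <- character(length(a))
    for (k in seq_along(a)) {
        repeat {
            p <- sample(ids, 1L)
            if (p != a[k]) break
        }
        b[k] <- p
    }
    ## canonical pair order, dedup
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste(lo, hi))
    lo <- lo[keep]; hi <- hi[keep]
    base <- runif(length(lo), 0, 0.3)
    noise <- if (config@coaccessNoise > 0)
        rnorm(length(lo), 0, config@coaccessNoise) else 0
    indAdj <- truth@regionClass[lo] == "inducible" |
              truth@regionClass[hi] == "inducible"
    dht <- pmin(1, pmax(0, base + noise + config@coaccessGain * indAdj))
    list(etoh = data.frame(region_a = lo, region_b = hi, score = base,
                           stringsAsFactors = FALSE),
         dht = data.frame(region_a = lo, region_b = hi, score = dht,
                          stringsAsFactors = FALSE))
}

#' Simulate raw occupancy scores with matched controls
#'
#' Emulates per-region ChIP-seq signal for \code{nFactors} DNA-binding
#' factors. Background scores are N(5, 1); a bound region adds
#' \code{occupancyShift} SD of signal. Uninformative factors bind a random
#' 20% of regions regardless of class; informative factors bind every
#' region of their target class and 2% of other regions (a clean planted
#' marker with a small off-target rate). Control scores are pure
#' background. A fraction \code{missingRate} of raw entries is set missing
#' (NA), emulating absent ChIP-seq coverage.
#'
#' @inheritParams simulateStarrCounts
#' @return A list with \code{raw} (regions x factors, NA where missing) and
#'   \code{control} (same shape, background draws).
#' @export
simulateOccupancy <- function(regions, truth, config) {
    stopifnot(config@nFactors >= config@informativeFactors)
    .seedFor(config, "occupancy")
    ids <- names(regions)
    n <- length(ids)
    fids <- names(truth@informativeFactor)
    raw <- matrix(rnorm(n * length(fids), 5, 1), n,
                  dimnames = list(ids, fids))
    control <- matrix(rnorm(n * length(fids), 5, 1), n,
                      dimnames = list(ids, fids))
    for (f in fids) {
        pBind <- if (truth@informativeFactor[[f]]) {
            ifelse(truth@regionClass[ids] ==
                   truth@factorTargetClass[[f]], 1.0, 0.02)
        } else rep(0.2, n)
        bound <- runif(n) < pBind
        raw[bound, f] <- raw[bound, f] + config@occupancyShift
    }
    if (config@missingRate > 0) {
        mask <- matrix(runif(length(raw)) < config@missingRate,
                       nrow = n)
        raw[mask] <- NA_real_
    }
    list(raw = raw, control = control)
}
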