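test_that("region simulation places valid intervals and apportions classes", {
    cfg <- simulationConfig(nClinical = 100, nAreOnly = 10,
        nPositiveCtrl = 5,
        classProportions = c(inducible = 0.07, constitutive = 0.11,
                             inactive = 0.82), seed = 1)
    sim <- simulateRegions(cfg)
    expect_length(sim$regions, 115)
    expect_true(all(GenomicRanges::width(sim$regions) >= 500))
    ## non-overlapping
    ord <- order(GenomicRanges::start(sim$regions))
    s <- GenomicRanges::start(sim$regions)[ord]
    e <- GenomicRanges::end(sim$regions)[ord]
    expect_true(all(s[-1] > e[-length(e)]))
    ## planted counts equal the apportioned proportions
    cls <- plantedClasses(sim$truth)
    clin <- cls[grepl("^clin", names(cls))]
    expect_equal(unname(table(clin)[c("inducible", "constitutive",
                                      "inactive")]),
                 structure(c(7L, 11L, 82L), class = "table"),
                 ignore_attr = TRUE)
    expect_true(all(cls[grepl("^are|^pos", names(cls))] == "none"))
    ## same seed, byte-identical
    sim2 <- simulateRegions(cfg)
    expect_identical(sim, sim2)
})

test_that("study-scale proportions plant counts near 286/465/3388", {
    cfg <- simulationConfig(seed = 1)
    sim <- simulateRegions(cfg)
    cls <- plantedClasses(sim$truth)
    clin <- cls[grepl("^clin", names(cls))]
    tab <- table(clin)
    expect_lte(abs(tab[["inducible"]] - 286), 2)
    expect_lte(abs(tab[["constitutive"]] - 465), 2)
    expect_lte(abs(tab[["inactive"]] - 3388), 2)
    expect_error(simulateRegions(
        simulationConfig(nClinical = 0)), "count")
})

test_that("null STARR counts have unit ratios; planted effects recovered", {
    ## null: all fold changes 1
    cfg <- simulationConfig(nClinical = 600, nAreOnly = 0,
        nPositiveCtrl = 0, fcInduced = 1, fcActive = 1, seed = 21)
    sim <- simulateRegions(cfg)
    se <- simulateStarrCounts(sim$regions, sim$truth, cfg)
    cnt <- SummarizedExperiment::assay(se, "counts")
    lib <- S4Vectors::metadata(se)$libSizes
    q <- sweep(cnt, 2, lib, "/")
    mE <- rowMeans(q[, paste0("etoh_", 1:3)])
    mD <- rowMeans(q[, paste0("dht_", 1:3)])
    ratio <- mD / mE
    cls <- plantedClasses(sim$truth)
    for (cl in c("inducible", "constitutive", "inactive")) {
        r <- ratio[cls == cl]
        se3 <- 3 * sd(r) / sqrt(length(r))
        expect_lt(abs(mean(r) - 1), se3)
    }

    ## dispersion 0 -> Poisson: variance/mean near 1 with many replicates
    cfgP <- simulationConfig(nClinical = 5, nAreOnly = 0,
        nPositiveCtrl = 0, nbDispersion = 0, nReplicates = 2000L,
        fcInduced = 1, fcActive = 1, seed = 22)
    simP <- simulateRegions(cfgP)
    seP <- simulateStarrCounts(simP$regions, simP$truth, cfgP)
    cntP <- SummarizedExperiment::assay(seP, "counts")
    libP <- S4Vectors::metadata(seP)$libSizes
    plas <- grepl("^plasmid", colnames(cntP))
    ## remove library-size effect, then check index of dispersion
    qP <- sweep(cntP[, plas], 2, libP[plas], "/")
    idx <- apply(qP, 1, var) / rowMeans(qP)
    expect_lt(max(abs(idx - 1)), 0.15)

    ## planted 4-fold induction: mean estimated log2 ratio within 0.15 of 2
    cfgE <- simulationConfig(nClinical = 1000, nAreOnly = 0,
        nPositiveCtrl = 0,
        classProportions = c(inducible = 1, constitutive = 0,
                             inactive = 0), seed = 23)
    simE <- simulateRegions(cfgE)
    seE <- simulateStarrCounts(simE$regions, simE$truth, cfgE)
    cntE <- SummarizedExperiment::assay(seE, "counts")
    libE <- S4Vectors::metadata(seE)$libSizes
    qE <- sweep(cntE, 2, libE, "/")
    lr <- log2(rowMeans(qE[, paste0("dht_", 1:3)]) /
               rowMeans(qE[, paste0("etoh_", 1:3)]))
    expect_lt(abs(mean(lr) - 2), 0.15)
})

test_that("counts generator demands planted classes for all regions", {
    cfg <- simulationConfig(nClinical = 10, nAreOnly = 0,
        nPositiveCtrl = 0, seed = 1)
    sim <- simulateRegions(cfg)
    extra <- c(sim$regions, GenomicRanges::GRanges("chrS",
        IRanges::IRanges(4.9e7, width = 600)))
    names(extra)[11] <- "orphan"
    expect_error(simulateStarrCounts(extra, sim$truth, cfg),
                 "missing planted class.*orphan")
})

test_that("occupancy generator: null factors, missingness, informative AUC", {
    ## no informative factors -> between-class rank-sum p approx uniform
    cfg0 <- simulationConfig(nClinical = 300, nAreOnly = 0,
        nPositiveCtrl = 0, nFactors = 60L, informativeFactors = 0L,
        missingRate = 0, seed = 31)
    sim0 <- simulateRegions(cfg0)
    occ0 <- simulateOccupancy(sim0$regions, sim0$truth, cfg0)
    cls0 <- plantedClasses(sim0$truth)
    grpA <- cls0 == "inducible"
    grpB <- cls0 == "inactive"
    pv <- apply(occ0$raw, 2, function(x)
        suppressWarnings(wilcox.test(x[grpA], x[grpB])$p.value))
    frac <- mean(pv < 0.05)
    ci3 <- 3 * sqrt(0.05 * 0.95 / length(pv))
    expect_lte(frac, 0.05 + ci3)

    ## missingness rate honored
    cfgM <- simulationConfig(nClinical = 400, nAreOnly = 0,
        nPositiveCtrl = 0, nFactors = 30L, missingRate = 0.3, seed = 32)
    simM <- simulateRegions(cfgM)
    occM <- simulateOccupancy(simM$regions, simM$truth, cfgM)
    rate <- mean(is.na(occM$raw))
    n <- length(occM$raw)
    expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / n))

    ## one strongly informative factor separates its class
    cfgI <- simulationConfig(nClinical = 500, nAreOnly = 0,
        nPositiveCtrl = 0, nFactors = 1L, informativeFactors = 1L,
        occupancyShift = 3, missingRate = 0, seed = 33)
    simI <- simulateRegions(cfgI)
    occI <- simulateOccupancy(simI$regions, simI$truth, cfgI)
    tab <- buildOccupancyTable(occI$raw, occI$control)
    clsI <- plantedClasses(simI$truth)
    auc <- aucRank(occupancyMatrix(tab)[, 1], clsI == "inducible")
    expect_gt(auc, 0.95)
})

test_that("loop generator plants hub enrichment and reproduces exactly", {
    ## null: degrees equal across classes
    cfg1 <- simulationConfig(nClinical = 400, nAreOnly = 0,
        nPositiveCtrl = 0, hubEnrichment = 1, tssUpBias = 0, seed = 41)
    sim1 <- simulateRegions(cfg1)
    tss1 <- simulateTss(cfg1)
    loops1 <- simulateInteractions(sim1$regions, sim1$truth, tss1, cfg1)
    deg1 <- table(factor(c(loops1$id1, loops1$id2),
                         levels = names(plantedClasses(sim1$truth))))
    cls1 <- plantedClasses(sim1$truth)
    dInd <- as.numeric(deg1[cls1 == "inducible"])
    dIna <- as.numeric(deg1[cls1 == "inactive"])
    se3 <- 3 * sqrt(var(dInd) / length(dInd) + var(dIna) / length(dIna))
    expect_lt(abs(mean(dInd) - mean(dIna)), se3)

    ## hub enrichment 3: realized inducible/inactive degree ratio near 3
    ratios <- vapply(1:5, function(s) {
        cfg3 <- simulationConfig(nClinical = 200, nAreOnly = 0,
            nPositiveCtrl = 0, hubEnrichment = 3, seed = 41 + s)
        sim3 <- simulateRegions(cfg3)
        tss3 <- simulateTss(cfg3)
        loops3 <- simulateInteractions(sim3$regions, sim3$truth, tss3,
                                       cfg3)
        deg3 <- table(factor(c(loops3$id1, loops3$id2),
                             levels = names(plantedClasses(sim3$truth))))
        cls3 <- plantedClasses(sim3$truth)
        mean(deg3[cls3 == "inducible"]) / mean(deg3[cls3 == "inactive"])
    }, numeric(1))
    expect_lt(abs(mean(ratios) - 3), 0.75)

    ## fixed seed -> identical BEDPE bytes
    cfg <- simulationConfig(nClinical = 50, nAreOnly = 0,
        nPositiveCtrl = 0, seed = 42)
    sim <- simulateRegions(cfg)
    tss <- simulateTss(cfg)
    f1 <- tempfile(); f2 <- tempfile()
    writeBedpe(simulateInteractions(sim$regions, sim$truth, tss, cfg), f1)
    writeBedpe(simulateInteractions(sim$regions, sim$truth, tss, cfg), f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_error(simulateInteractions(sim$regions[0], sim$truth, tss, cfg),
                 "empty region set")
})

test_that("co-accessibility generator: null identity and threshold crossings", {
    cfg0 <- simulationConfig(nClinical = 150, nAreOnly = 0,
        nPositiveCtrl = 0, coaccessGain = 0, coaccessNoise = 0, seed = 51)
    sim0 <- simulateRegions(cfg0)
    co0 <- simulateCoaccessibility(sim0$regions, sim0$truth, cfg0)
    expect_identical(co0$etoh, co0$dht)
    cls <- plantedClasses(sim0$truth)
    g1 <- buildCoaccessGraph(co0$etoh, cls)
    g2 <- buildCoaccessGraph(co0$dht, cls)
    expect_equal(deltaCon(g1, g2)$d, 0)

    ## planted gain: thresholded edge difference equals the direct count
    cfgG <- simulationConfig(nClinical = 150, nAreOnly = 0,
        nPositiveCtrl = 0, coaccessGain = 0.4, coaccessNoise = 0,
        seed = 52)
    simG <- simulateRegions(cfgG)
    coG <- simulateCoaccessibility(simG$regions, simG$truth, cfgG)
    k <- sum((coG$etoh$score > 0.1) != (coG$dht$score > 0.1))
    gE <- interactionGraph(buildCoaccessGraph(coG$etoh,
        plantedClasses(simG$truth)))
    gD <- interactionGraph(buildCoaccessGraph(coG$dht,
        plantedClasses(simG$truth)))
    dif <- igraph::difference
    expect_equal(igraph::ecount(dif(gE, gD)) +
                 igraph::ecount(dif(gD, gE)), k)

    co2 <- simulateCoaccessibility(simG$regions, simG$truth, cfgG)
    expect_identical(coG, co2)
})
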