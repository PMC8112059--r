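#' @importFrom tools md5sum
NULL

.roundHalfUp <- function(x, digits = 1) {
    floor(x * 10^digits + 0.5) / 10^digits
}

#' Class counts and percentages
#'
#' Summarizes enhancer calls as counts and percentages of the total tested
#' regions, with half-up rounding to \code{digits} decimals (1 for class
#' tables, 0 for small-n fractions). For example, counts of 286, 465 and
#' 3388 inducible/constitutive/inactive regions out of 4139 give 6.9%,
#' 11.2% and 81.9%.
#'
#' @param calls factor/character of class per region, or a named integer
#'   vector of class counts.
#' @param digits decimals for the percentage (default 1).
#' @return \code{data.frame}: class, count, percent.
#' @examples
#' summarizeClasses(c(inducible = 286, constitutive = 465,
#'   inactive = 3388))
#' @export
summarizeClasses <- function(calls, digits = 1) {
    counts <- if (is.numeric(calls)) calls else table(calls)
    if (!length(counts)) stop("no calls supplied")
    tot <- sum(counts)
    data.frame(class = names(counts), count = as.integer(counts),
        percent = .roundHalfUp(100 * as.integer(counts) / tot, digits),
        row.names = NULL)
}

.KNOWN_CONFIG_KEYS <- c("simulation", "thresholds", "pseudocount",
    "window", "coaccessThreshold", "ensemble", "stages", "seed",
    "logLevel")

#' Pipeline configuration
#'
#' A serializable configuration covering every stage: simulation parameters
#' (see \code{\link{simulationConfig}}), classification thresholds, the
#' promoter window, the co-accessibility threshold, ensemble
#' hyperparameters, the enabled stages and the global seed. Round-trips
#' through JSON; unknown keys are rejected on parse.
#'
#' @param simulation named list of \code{\link{simulationConfig}} arguments.
#' @param thresholds named list of \code{\link{classificationThresholds}}
#'   arguments.
#' @param pseudocount LFC pseudocount.
#' @param window promoter window (bp).
#' @param coaccessThreshold co-accessibility edge cutoff.
#' @param ensemble named list: nEstimators, maxSamples, maxFeatures,
#'   l1Penalty, nNonInducible, trainFrac.
#' @param stages character subset of
#'   simulate/classify/network/coaccess/train.
#' @param seed global seed (overrides \code{simulation$seed}).
#' @param logLevel "info" or "quiet".
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(simulation = list(), thresholds = list(),
    pseudocount = 1, window = 5000, coaccessThreshold = 0.1,
    ensemble = list(nEstimators = 2000, maxSamples = 50, maxFeatures = 5,
                    l1Penalty = 0.1, nNonInducible = 500,
                    trainFrac = 0.8),
    stages = c("simulate", "classify", "network", "coaccess", "train"),
    seed = 1L, logLevel = "info") {
    cfg <- list(simulation = simulation, thresholds = thresholds,
        pseudocount = pseudocount, window = window,
        coaccessThreshold = coaccessThreshold, ensemble = ensemble,
        stages = stages, seed = as.integer(seed), logLevel = logLevel)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Serialize / parse a pipeline configuration
#'
#' @param config a \code{PipelineConfig}.
#' @param json a JSON string (or file path for \code{parseConfig}).
#' @return \code{serializeConfig}: a JSON string; \code{parseConfig}: a
#'   \code{PipelineConfig}. Unknown keys are an error.
#' @export
serializeConfig <- function(config) {
    as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA))
}

#' @rdname serializeConfig
#' @export
parseConfig <- function(json) {
    obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
    unknown <- setdiff(names(obj), .KNOWN_CONFIG_KEYS)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    obj$simulation <- as.list(obj$simulation)
    obj$thresholds <- as.list(obj$thresholds)
    obj$ensemble <- as.list(obj$ensemble)
    do.call(pipelineConfig, obj)
}

.logStage <- function(config, stage, t0, ...) {
    if (identical(config$logLevel, "quiet")) return(invisible())
    message(sprintf("[%s] seed=%d elapsed=%.1fs %s", stage, config$seed,
        as.numeric(difftime(Sys.time(), t0, units = "secs")),
        paste(..., collapse = " ")))
}

.writeArtifact <- function(obj, path, writer) {
    writer(obj, path)
    path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order (simulate, classify,
#' network, coaccess, train); later stages require the earlier ones. When
#' \code{outDir} is given, every artifact (BED, BEDPE, TSVs, model JSON,
#' report JSON) is written there and listed in a manifest with size and
#' md5. Reruns with the same config are identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory.
#' @return A \code{RunReport} list: per-stage row counts, class counts and
#'   percentages, network summaries, DeltaCon distance, classifier metrics,
#'   package version and a config hash, plus the in-memory stage results in
#'   \code{$objects}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
    stages <- config$stages
    needs <- list(classify = "simulate", network = "classify",
                  coaccess = "classify", train = "classify")
    for (st in names(needs))
        if (st %in% stages && !all(needs[[st]] %in% stages))
            stop("stage '", st, "' requires stage '", needs[[st]], "'")
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    t0 <- Sys.time()
    report <- list(version = as.character(utils::packageVersion("StarrCRE")),
                   configHash = substr(digestConfig(config), 1, 12),
                   stages = stages, counts = list())
    objects <- list()
    artifacts <- character(0)

    simArgs <- config$simulation
    simArgs$seed <- config$seed
    cfg <- do.call(simulationConfig, simArgs)

    if ("simulate" %in% stages) {
        sim <- simulateRegions(cfg)
        se <- simulateStarrCounts(sim$regions, sim$truth, cfg)
        tss <- simulateTss(cfg)
        loops <- simulateInteractions(sim$regions, sim$truth, tss, cfg)
        coac <- simulateCoaccessibility(sim$regions, sim$truth, cfg)
        occ <- simulateOccupancy(sim$regions, sim$truth, cfg)
        objects[c("regions", "truth", "se", "tss", "loops", "coaccess",
                  "occRaw")] <-
            list(sim$regions, sim$truth, se, tss, loops, coac, occ)
        report$counts$regions <- length(sim$regions)
        report$counts$loops <- nrow(loops)
        if (!is.null(outDir)) {
            artifacts <- c(artifacts,
                .writeArtifact(sim$regions,
                    file.path(outDir, "regions.bed"), writeBed),
                .writeArtifact(loops,
                    file.path(outDir, "interactions.bedpe"), writeBedpe))
            writeStarrCounts(se, file.path(outDir, "starr_counts.tsv"),
                             file.path(outDir, "sample_roles.tsv"))
            artifacts <- c(artifacts,
                file.path(outDir, "starr_counts.tsv"),
                file.path(outDir, "sample_roles.tsv"))
            truthDf <- data.frame(
                region_id = names(plantedClasses(sim$truth)),
                planted_class = unname(plantedClasses(sim$truth)))
            p <- file.path(outDir, "truth.tsv")
            write.table(truthDf, p, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            artifacts <- c(artifacts, p)
            for (cond in c("etoh", "dht")) {
                p <- file.path(outDir, paste0("coaccess_", cond, ".tsv"))
                write.table(coac[[cond]], p, sep = "\t", quote = FALSE,
                            row.names = FALSE)
                artifacts <- c(artifacts, p)
            }
        }
        .logStage(config, "simulate", t0, length(sim$regions), "regions")
    }

    if ("classify" %in% stages) {
        stats <- enhancerActivity(objects$se,
                                  pseudocount = config$pseudocount)
        th <- do.call(classificationThresholds, config$thresholds)
        calls <- classifyEnhancers(stats, th)
        clin <- rownames(calls)[SummarizedExperiment::rowData(
            objects$se)$design_group == "clinical"]
        classTable <- summarizeClasses(calls[clin, "class"])
        objects$stats <- stats
        objects$calls <- calls
        report$classSummary <- classTable
        report$counts$classified <- nrow(calls)
        if (!is.null(outDir)) {
            p <- file.path(outDir, "enhancer_calls.tsv")
            write.table(data.frame(region_id = rownames(calls),
                as.data.frame(calls)), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
            artifacts <- c(artifacts, p)
        }
        .logStage(config, "classify", t0,
                  paste(classTable$class, classTable$count,
                        collapse = " "))
    }

    if ("network" %in% stages) {
        callCls <- setNames(as.character(objects$calls$class),
                            rownames(objects$calls))
        grp <- SummarizedExperiment::rowData(objects$se)$design_group
        nodeCls <- ifelse(grp == "clinical",
                          callCls[rownames(objects$calls)],
                          "untested_ARBS")
        names(nodeCls) <- rownames(objects$calls)
        deg <- objects$tss[objects$tss$direction %in% c("up", "down")]
        tssCls <- setNames(paste0("TSS_", deg$direction), names(deg))
        edges <- anchorOverlap(objects$loops, objects$regions,
                               objects$tss, window = config$window)
        net <- buildGraph(edges, c(nodeCls, tssCls))
        comp <- igraph::components(interactionGraph(net))
        report$network <- list(nodes = igraph::vcount(interactionGraph(net)),
            edges = igraph::ecount(interactionGraph(net)),
            components = comp$no)
        objects$net <- net
        objects$centrality <- networkCentrality(net)
        if (!is.null(outDir)) {
            p <- file.path(outDir, "network_edges.tsv")
            el <- igraph::as_edgelist(interactionGraph(net))
            write.table(data.frame(nodeA = el[, 1], nodeB = el[, 2]), p,
                        sep = "\t", quote = FALSE, row.names = FALSE)
            artifacts <- c(artifacts, p)
            p <- file.path(outDir, "network_nodes.json")
            jsonlite::write_json(as.list(nodeClasses(net)), p,
                                 auto_unbox = TRUE)
            artifacts <- c(artifacts, p)
        }
        .logStage(config, "network", t0, report$network$nodes, "nodes",
                  report$network$edges, "edges")
    }

    if ("coaccess" %in% stages) {
        callCls <- setNames(as.character(objects$calls$class),
                            rownames(objects$calls))
        gE <- buildCoaccessGraph(objects$coaccess$etoh, callCls,
                                 config$coaccessThreshold)
        gD <- buildCoaccessGraph(objects$coaccess$dht, callCls,
                                 config$coaccessThreshold)
        dc <- deltaCon(gE, gD)
        report$deltacon <- list(d = dc$d, epsilon = dc$epsilon)
        objects$deltacon <- dc
        objects$impactSummary <- classImpactSummary(dc$impact, callCls)
        if (!is.null(outDir)) {
            p <- file.path(outDir, "node_impact.tsv")
            write.table(data.frame(node = names(dc$impact),
                w = unname(dc$impact)), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
            artifacts <- c(artifacts, p)
        }
        .logStage(config, "coaccess", t0, "d =", signif(dc$d, 4))
    }

    if ("train" %in% stages) {
        tab <- buildOccupancyTable(objects$occRaw$raw,
                                   objects$occRaw$control)
        callCls <- setNames(as.character(objects$calls$class),
                            rownames(objects$calls))
        en <- config$ensemble
        split <- makeTrainingSet(occupancyMatrix(tab), callCls,
            nNonInducible = en$nNonInducible %||% 500,
            trainFrac = en$trainFrac %||% 0.8, seed = config$seed)
        model <- fitBaggedMultinomialLasso(split$xTrain, split$yTrain,
            nEstimators = en$nEstimators %||% 2000,
            maxSamples = en$maxSamples %||% 50,
            maxFeatures = en$maxFeatures %||% 5,
            l1Penalty = en$l1Penalty %||% 0.1, seed = config$seed)
        metrics <- evaluateModel(model, split$xTest, split$yTest)
        energy <- bindingEnergy(model, occupancyMatrix(tab), callCls)
        objects[c("occTable", "split", "model", "metrics", "energy")] <-
            list(tab, split, model, metrics, energy)
        report$classifier <- list(accuracy = metrics$accuracy,
            precision = as.list(metrics$precision),
            recall = as.list(metrics$recall),
            auc = as.list(metrics$auc))
        if (!is.null(outDir)) {
            artifacts <- c(artifacts,
                .writeArtifact(model, file.path(outDir, "model.json"),
                               writeModelJson))
            p <- file.path(outDir, "binding_energy.tsv")
            write.table(data.frame(factor = rownames(energy$energy),
                energy$energy, check.names = FALSE), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
            artifacts <- c(artifacts, p)
        }
        .logStage(config, "train", t0, "accuracy",
                  signif(metrics$accuracy, 3))
    }

    if (!is.null(outDir)) {
        manifest <- data.frame(file = basename(artifacts),
            bytes = file.size(artifacts),
            md5 = unname(tools::md5sum(artifacts)))
        write.table(manifest, file.path(outDir, "manifest.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        report$manifest <- manifest
        rp <- report
        rp$manifest <- NULL
        jsonlite::write_json(rp, file.path(outDir, "report.json"),
            auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    report$objects <- objects
    class(report) <- "RunReport"
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname serializeConfig
#' @export
digestConfig <- function(config) {
    ## order-stable hash of the serialized config (no external digest dep)
    js <- serializeConfig(config)
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(js, tf)
    unname(tools::md5sum(tf))
}

#' @export
print.RunReport <- function(x, ...) {
    cat("StarrCRE run report (v", x$version, ", config ", x$configHash,
        ")\n", sep = "")
    if (!is.null(x$classSummary)) {
        cat("Enhancer classes (clinical regions):\n")
        print(x$classSummary, row.names = FALSE)
    }
    if (!is.null(x$network))
        cat("CRE network:", x$network$nodes, "nodes,", x$network$edges,
            "edges,", x$network$components, "components\n")
    if (!is.null(x$deltacon))
        cat("DeltaCon d =", signif(x$deltacon$d, 4), "\n")
    if (!is.null(x$classifier))
        cat("Classifier accuracy:", signif(x$classifier$accuracy, 3),
            "\n")
    invisible(x)
}
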