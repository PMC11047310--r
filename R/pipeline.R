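#' Run the full ROH analysis pipeline
#'
#' Orchestrates QC, ROH calling, length-class and inbreeding summaries,
#' per-population island detection and consensus-region selection, and
#' writes a fixed artifact set to the output directory:
#' \code{qc_report.tsv}, \code{roh_segments.tsv},
#' \code{class_summary.tsv}, \code{froh.tsv},
#' \code{froh_population.tsv}, \code{incidence_<pop>.tsv},
#' \code{islands_<pop>.tsv} and \code{.bed}, \code{consensus.tsv},
#' \code{run.log} and \code{config.yaml} (the resolved configuration,
#' for provenance). Rerunning on the same inputs reproduces the same
#' artifacts. Any stage failure aborts with an error naming the stage.
#'
#' @param config a named list, or the path of a YAML file holding one,
#'   with entries:
#'   \describe{
#'     \item{input}{list with \code{vcf} or \code{genotype_tsv}, a
#'       \code{population_map} path, and optionally \code{genes}
#'       (BED/GFF3).}
#'     \item{qc}{list: \code{profile} ("roh" or "structure") plus any
#'       \code{\link{qcParams}} override.}
#'     \item{roh}{list of \code{\link{rohCallParams}} overrides.}
#'     \item{l_auto_mb}{autosomal panel length (Mb) for FROH; default
#'       2466.19, logged.}
#'     \item{islands}{list: \code{top_fraction} (0.001),
#'       \code{min_snps} (2).}
#'     \item{consensus}{list: \code{min_con_mb} (0.1), \code{min_frac}
#'       (0.30), \code{populations} (character vector; default all).}
#'     \item{output_dir}{directory to create/write.}
#'   }
#' @return the output directory path, invisibly.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    out <- config$output_dir
    if (is.null(out)) stop("config needs an 'output_dir'")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(out, "run.log")
    logCon <- file(logPath, "w")
    on.exit(close(logCon), add = TRUE)
    say <- function(...) {
        line <- paste0(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
        writeLines(line, logCon); message(...)
    }
    stage <- function(name, expr) {
        say("stage: ", name)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    say("rohscan ", as.character(utils::packageVersion("rohscan")),
        " / R ", getRversion())

    gm <- stage("read", {
        inp <- config$input
        if (!is.null(inp$vcf)) readVCF(inp$vcf)
        else if (!is.null(inp$genotype_tsv)) readGenotypeTSV(inp$genotype_tsv)
        else if (!is.null(inp$genotype_matrix)) inp$genotype_matrix
        else stop("no input: give input$vcf, input$genotype_tsv or input$genotype_matrix")
    })
    say("input: ", nrow(gm), " SNPs x ", ncol(gm), " samples")

    popmap <- stage("population_map", {
        pm <- config$input$population_map
        if (is.null(pm)) setNames(rep("ALL", ncol(gm)), sampleIDs(gm))
        else if (is.character(pm) && length(pm) == 1L && is.null(names(pm)))
            readPopulationMap(pm)   # a single unnamed string is a file path
        else pm
    })

    gm <- stage("qc", {
        qcc <- config$qc
        prof <- if (is.null(qcc$profile)) "roh" else qcc$profile
        args <- qcc[intersect(names(qcc), c("maxSampleMissing",
                    "maxGenoMissing", "hwePThreshold", "minMAF"))]
        params <- do.call(qcParams, c(list(profile = prof), args))
        res <- applyQC(gm, params)
        .writeTSV(qcReport(res), file.path(out, "qc_report.tsv"))
        for (i in seq_len(nrow(qcReport(res))))
            say("qc ", qcReport(res)$step[i], ": removed ",
                qcReport(res)$removed[i], ", remaining ",
                qcReport(res)$remaining[i])
        res
    })

    segments <- stage("call", {
        if (!nrow(gm) || !ncol(gm))
            stop("empty post-QC genotype matrix")
        params <- do.call(rohCallParams, as.list(config$roh))
        segs <- callROH(gm, params)
        segs$population <- unname(popmap[segs$sample])
        writeSegments(segs, file.path(out, "roh_segments.tsv"))
        say("called ", nrow(segs), " ROH segments in ",
            length(unique(segs$sample)), " samples")
        segs
    })

    lAuto <- if (is.null(config$l_auto_mb)) 2466.19 else config$l_auto_mb
    say("l_auto_mb = ", lAuto,
        if (is.null(config$l_auto_mb)) " (default)" else " (configured)")

    stage("stats", {
        if (nrow(segments)) {
            cs <- summarizeClasses(classifyLength(segments))
            .writeTSV(cs, file.path(out, "class_summary.tsv"))
        } else
            .writeTSV(data.frame(), file.path(out, "class_summary.tsv"))
        froh <- frohPerSample(segments, lAuto, samples = sampleIDs(gm))
        froh$population <- unname(popmap[froh$sample])
        .writeTSV(froh, file.path(out, "froh.tsv"))
        .writeTSV(frohByPopulation(froh, popmap),
                  file.path(out, "froh_population.tsv"))
        say("FROH range: ", paste(signif(range(froh$froh), 4), collapse = " - "))
    })

    stage("islands", {
        iscfg <- config$islands
        topFrac <- if (is.null(iscfg$top_fraction)) 0.001 else iscfg$top_fraction
        minSnps <- if (is.null(iscfg$min_snps)) 2L else iscfg$min_snps
        genes <- config$input$genes
        scan <- islandScan(segments, gm, popmap[sampleIDs(gm)],
                           topFraction = topFrac, minSnps = minSnps,
                           genes = genes)
        for (p in names(scan)) {
            .writeTSV(scan[[p]]$track,
                      file.path(out, paste0("incidence_", p, ".tsv")))
            .writeTSV(scan[[p]]$islands,
                      file.path(out, paste0("islands_", p, ".tsv")))
            if (nrow(scan[[p]]$islands))
                writeBED(scan[[p]]$islands,
                         file.path(out, paste0("islands_", p, ".bed")))
            say("population ", p, ": threshold ",
                signif(scan[[p]]$threshold, 4), ", ",
                nrow(scan[[p]]$islands), " island(s)")
        }
    })

    stage("consensus", {
        cc <- config$consensus
        pops <- if (is.null(cc$populations)) unique(popmap) else cc$populations
        refSamples <- sampleIDs(gm)[popmap[sampleIDs(gm)] %in% pops]
        segs <- segments[segments$sample %in% refSamples, , drop = FALSE]
        pooled <- poolSegments(segs)
        minCon <- if (is.null(cc$min_con_mb)) 0.1 else cc$min_con_mb
        minFrac <- if (is.null(cc$min_frac)) 0.30 else cc$min_frac
        sel <- filterConsensus(pooled$pools, refSamples, minCon, minFrac)
        consensusReport(sel, pooled$members, popmap = popmap,
                        genes = config$input$genes,
                        path = file.path(out, "consensus.tsv"))
        say(nrow(pooled$pools), " pools, ", nrow(sel),
            " selected consensus region(s)")
    })

    cfgOut <- config
    cfgOut$input$genotype_matrix <- NULL   # not serialisable
    yaml::write_yaml(cfgOut, file.path(out, "config.yaml"))
    say("done")
    invisible(out)
}
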