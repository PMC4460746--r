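#' Assemble and validate a pipeline configuration
#'
#' Collects all input paths and tuning parameters of one analysis run.
#' Unknown keys are rejected; required paths are checked before any stage
#' runs. [pipelineConfigFromBundle()] builds the configuration for a
#' directory written by [simulateBundle()].
#'
#' @param ... named configuration entries; see Details.
#' @details Recognized keys: `associations`, `genes_bed`, `pathway`,
#'   `interaction`, `domain`, `tf_target`, `mirna_target` (paths);
#'   `drug_exports` (list of lists with `path`, `dialect`, `source`);
#'   `id_map`, `citations`, `seed_genes`, `phenotype_terms` (paths; the last
#'   two may instead be character vectors); `external_list` (optional path or
#'   vector); `previous_targets` (optional, for run-to-run comparison);
#'   `thresholds`, `tau`, `hub_k`, `citation_thresholds`, `n_perm`, `seed`,
#'   `out_dir`.
#' @return validated configuration list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(...)
    known <- c("associations", "genes_bed", "pathway", "interaction",
               "domain", "tf_target", "mirna_target", "drug_exports",
               "id_map", "citations", "seed_genes", "phenotype_terms",
               "external_list", "previous_targets", "thresholds", "tau",
               "hub_k", "citation_thresholds", "n_perm", "seed", "out_dir")
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    defaults <- list(thresholds = defaultStrataThresholds(), tau = 0.5,
                     hub_k = 5L, citation_thresholds = c(1, 5, 10, 15),
                     n_perm = 1000L, seed = 1L)
    for (k in names(defaults))
        if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    required <- c("associations", "genes_bed", "pathway", "interaction",
                  "domain", "tf_target", "mirna_target", "id_map",
                  "citations", "seed_genes", "phenotype_terms", "out_dir")
    missing <- setdiff(required, names(cfg))
    if (length(missing))
        stop("configuration lacks required key(s): ",
             paste(missing, collapse = ", "))
    class(cfg) <- "pipelineConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param dir directory written by [simulateBundle()].
#' @param outDir output directory for pipeline artifacts.
#' @param seed RNG seed for the benchmark permutation tests.
#' @export
pipelineConfigFromBundle <- function(dir, outDir = file.path(dir, "out"),
                                     seed = 1L) {
    p <- function(f) file.path(dir, f)
    pipelineConfig(
        associations = p("associations.tsv"), genes_bed = p("genes.bed"),
        pathway = p("pathways.tsv"), interaction = p("interactions.tsv"),
        domain = p("domains.tsv"), tf_target = p("tf_targets.tsv"),
        mirna_target = p("mirna_targets.tsv"),
        drug_exports = list(
            list(path = p("drugbank.csv"), dialect = dialectDrugBank(),
                 source = "DrugBank"),
            list(path = p("ttd.tsv"), dialect = dialectTTD(),
                 source = "TTD"),
            list(path = p("pharmgkb.tsv"), dialect = dialectPharmGKB(),
                 source = "PharmGKB")),
        id_map = p("id_map.tsv"), citations = p("citations.tsv"),
        seed_genes = p("seed_genes.txt"),
        phenotype_terms = p("phenotype_terms.txt"),
        out_dir = outDir, seed = seed)
}

readSymbolFile <- function(x) {
    if (length(x) == 1 && file.exists(x)) {
        v <- readLines(x, warn = FALSE)
        v[nzchar(trimws(v))]
    } else as.character(x)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: stratify SNPs, build the search-space grid,
#' predict candidate genes with the five modules, harmonize and pool the drug
#' databases, map and classify therapeutic targets and drugs, run the two
#' validation benchmarks, and (if an external list or previous target set is
#' configured) the set comparisons. Every intermediate artifact is written
#' under `out_dir`; a stage failure aborts with the stage name while earlier
#' outputs are retained. Per-stage record counts are logged to stderr.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return a report list (also serialized as `report.txt` and `report.json`)
#'   with elements `summary`, `venn`, `benchmark_spaces`,
#'   `benchmark_citations`, `comparisons`, `counts`.
#' @export
runPipeline <- function(config) {
    stopIfNot(inherits(config, "pipelineConfig"),
              "config must come from pipelineConfig()")
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, code) {
        tryCatch(code, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    log <- function(...) message("[gwas2drug] ", ...)

    strata <- stage("stratify", {
        snps <- parseAssociationFile(config$associations)
        stratifySnps(snps, config$thresholds)
    })
    log("stratify: ", nrow(strata@snps), " SNPs in ",
        length(strataLabels(strata)), " strata")
    writeTsv(data.frame(stratum = strataLabels(strata),
                        threshold = strataThresholds(strata),
                        n_snps = vapply(strataLabels(strata), function(l)
                            nrow(strataSnps(strata, l)), integer(1))),
             file.path(out, "strata_counts.tsv"))

    spaces <- stage("spaces", {
        genes <- readGeneBed(config$genes_bed)
        buildAllSearchSpaces(strata, genes)
    })
    log("spaces: ", length(spaces), " search spaces")
    writeSearchSpaces(spaces, file.path(out, "search_spaces.tsv"))

    candidates <- stage("predict", {
        annotations <- list(
            pathway = readAnnotationTsv(config$pathway, "pathway"),
            interaction = readAnnotationTsv(config$interaction, "interaction"),
            domain = readAnnotationTsv(config$domain, "domain"),
            tf_target = readAnnotationTsv(config$tf_target, "tf_target"),
            mirna_target = readAnnotationTsv(config$mirna_target,
                                             "mirna_target"))
        seedGenes <- readSymbolFile(config$seed_genes)
        predictCandidates(spaces, annotations, seedGenes,
                          tau = config$tau, hubK = config$hub_k)
    })
    log("predict: ", nrow(candidates), " candidate genes")
    writeTsv(candidates, file.path(out, "candidates.tsv"))

    pooled <- stage("integrate", {
        if (is.null(config$drug_exports))
            stop("no drug databases configured")
        idMap <- read.delim(config$id_map, header = TRUE,
                            stringsAsFactors = FALSE)
        parts <- lapply(config$drug_exports, function(db) {
            rec <- parseDrugExport(db$path, db$dialect, db$source)
            mapToHugo(rec, idMap)$records
        })
        do.call(poolDatabases, parts)
    })
    log("integrate: ", nrow(drugTargetRecords(pooled)), " pooled pairs, ",
        length(uniqueTargets(pooled)), " targets, ",
        length(uniqueDrugs(pooled)), " drugs")
    writeTsv(drugTargetRecords(pooled), file.path(out, "pooled_targets.tsv"))

    phenotypeTerms <- readSymbolFile(config$phenotype_terms)
    reposition <- stage("reposition", {
        targets <- mapTargets(candidates$gene, pooled)
        targets <- classifyTargetNovelty(targets, pooled, phenotypeTerms)
        targets$status_class <- classifyStatusClass(targets$statuses)
        drugs <- buildDrugTable(targets$gene, pooled, phenotypeTerms)
        bySource <- lapply(c("DrugBank", "TTD", "PharmGKB"), function(db)
            targets$gene[vapply(targets$source_dbs, function(s)
                db %in% splitSemi(s), logical(1))])
        venn <- vennRegions(bySource[[1]], bySource[[2]], bySource[[3]],
                            setNames = c("DrugBank", "TTD", "PharmGKB"))
        summary <- summarizeRepositioning(candidates, targets, drugs, venn)
        list(targets = targets, drugs = drugs, venn = venn,
             summary = summary)
    })
    log("reposition: ", reposition$summary$n_targets, " targets (",
        reposition$summary$n_known_targets, " known, ",
        reposition$summary$n_novel_targets, " novel), ",
        reposition$summary$n_drugs, " drugs")
    writeTsv(reposition$targets, file.path(out, "targets.tsv"))
    writeTsv(reposition$drugs, file.path(out, "drugs.tsv"))
    writeTsv(data.frame(region = names(vennCounts(reposition$venn)),
                        count = as.integer(vennCounts(reposition$venn))),
             file.path(out, "venn_targets.tsv"))

    benchmarks <- stage("benchmark", {
        widest <- strataLabels(strata)[length(strataLabels(strata))]
        sixSpaces <- spaces[grep(paste0("^", widest, "\\."), names(spaces))]
        knownTargetGenes <- uniqueTargets(pooled)[vapply(
            uniqueTargets(pooled), function(g)
                any(indicationMatches(recordsForTarget(pooled, g)$indications,
                                      phenotypeTerms)), logical(1))]
        bm1 <- searchSpaceBenchmark(
            sixSpaces, predictedTargets = reposition$targets$gene,
            knownTargets = knownTargetGenes, nPerm = config$n_perm,
            seed = config$seed)
        citations <- readCitationsTsv(config$citations)
        universe <- searchSpaceGeneUniverse(sixSpaces)
        bm2 <- citationBenchmark(
            intersect(reposition$targets$gene, universe), universe,
            citations, thresholds = config$citation_thresholds)
        list(spaces = bm1, citations = bm2, known_targets = knownTargetGenes)
    })
    log("benchmark: search-space AUC ",
        format(rocAuc(benchmarks$spaces$roc), digits = 4),
        ", citation AUC ", format(rocAuc(benchmarks$citations$roc),
                                  digits = 4))
    writeTsv(as.data.frame(rocPoints(benchmarks$spaces$roc)),
             file.path(out, "benchmark_spaces_roc.tsv"))
    writeTsv(as.data.frame(rocPoints(benchmarks$citations$roc)),
             file.path(out, "benchmark_citations_roc.tsv"))

    comparisons <- stage("compare", {
        res <- list()
        if (!is.null(config$previous_targets)) {
            prev <- readSymbolFile(config$previous_targets)
            res$previous <- compareSets(reposition$targets$gene, prev)
        }
        if (!is.null(config$external_list)) {
            ext <- readSymbolFile(config$external_list)
            res$external <- externalListOverlap(ext, pooled,
                                                reposition$targets$gene)
        }
        res
    })

    report <- list(summary = reposition$summary,
                   venn = reposition$venn,
                   benchmark_spaces = list(
                       auc = rocAuc(benchmarks$spaces$roc),
                       perm_auc = benchmarks$spaces$auc,
                       p_value = benchmarks$spaces$p_value,
                       universe_size = length(benchmarks$spaces$universe),
                       tables = lapply(benchmarks$spaces$tables, ctCounts)),
                   benchmark_citations = list(
                       auc = rocAuc(benchmarks$citations$roc),
                       tables = lapply(benchmarks$citations$tables, ctCounts)),
                   comparisons = comparisons,
                   counts = list(n_snps = nrow(strata@snps),
                                 n_spaces = length(spaces),
                                 n_candidates = reposition$summary$n_candidates))
    lines <- renderReport(report)
    writeLines(lines, file.path(out, "report.txt"))
    jsonlite::write_json(reportAsJson(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 12)
    report
}

reportAsJson <- function(report) {
    s <- report$summary
    list(summary = list(
             n_candidates = s$n_candidates, n_targets = s$n_targets,
             n_known_targets = s$n_known_targets,
             n_novel_targets = s$n_novel_targets,
             targetability_index = s$targetability_index,
             novelty_ratio = s$novelty_ratio,
             n_drugs = s$n_drugs, n_known_drugs = s$n_known_drugs,
             n_novel_drugs = s$n_novel_drugs,
             novel_target_status = as.list(s$novel_target_status),
             novel_drug_status = as.list(s$novel_drug_status)),
         venn = as.list(vennCounts(report$venn)),
         benchmark_spaces = report$benchmark_spaces[
             c("auc", "perm_auc", "p_value", "universe_size")],
         benchmark_citations = report$benchmark_citations["auc"],
         counts = report$counts)
}

#' Render a pipeline report as text
#'
#' Emits the run's headline quantities in the field's vocabulary (candidate
#' genes, therapeutic targets, known/novel splits, targetability index,
#' novelty ratio, Venn regions, benchmark AUCs and p-values) as stable
#' `key: value` lines suitable for machine diffing.
#'
#' @param report report list from [runPipeline()].
#' @return character vector of report lines.
#' @export
renderReport <- function(report) {
    s <- report$summary
    fmt <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
    lines <- c(
        "== gwas2drug analysis report ==",
        paste0("candidates: ", s$n_candidates),
        paste0("therapeutic_targets: ", s$n_targets),
        paste0("known_targets: ", s$n_known_targets),
        paste0("novel_targets: ", s$n_novel_targets),
        paste0("targetability_index: ",
               if (is.na(s$targetability_index)) "undefined"
               else renderPercent(s$targetability_index)),
        paste0("novelty_ratio: ",
               if (is.na(s$novelty_ratio)) "undefined"
               else renderRatio(s$novelty_ratio)),
        paste0("drugs: ", s$n_drugs),
        paste0("known_drugs: ", s$n_known_drugs),
        paste0("novel_drugs: ", s$n_novel_drugs),
        paste0("novel_drugs_approved_only: ",
               s$novel_drug_status[["approved_only"]]),
        paste0("novel_drugs_clinical_only: ",
               s$novel_drug_status[["clinical_only"]]),
        paste0("novel_drugs_both: ", s$novel_drug_status[["both"]]))
    if (!is.null(report$venn)) {
        v <- vennCounts(report$venn)
        lines <- c(lines, paste0("venn_", tolower(names(v)), ": ",
                                 as.integer(v)))
    }
    if (!is.null(report$benchmark_spaces) &&
        !is.null(report$benchmark_spaces$auc)) {
        b <- report$benchmark_spaces
        lines <- c(lines,
                   paste0("benchmark_spaces_auc: ", fmt(b$auc)),
                   paste0("benchmark_spaces_p: ", fmt(b$p_value)),
                   paste0("benchmark_universe: ", b$universe_size))
    } else lines <- c(lines, "benchmark_spaces: not-run")
    if (!is.null(report$benchmark_citations) &&
        !is.null(report$benchmark_citations$auc)) {
        lines <- c(lines, paste0("benchmark_citations_auc: ",
                                 fmt(report$benchmark_citations$auc)))
    } else lines <- c(lines, "benchmark_citations: not-run")
    if (!is.null(report$comparisons$previous)) {
        cmp <- report$comparisons$previous
        lines <- c(lines,
                   paste0("previous_common: ", cmp$n_common),
                   paste0("previous_only_new: ", cmp$n_only_a),
                   paste0("previous_only_old: ", cmp$n_only_b))
    }
    if (!is.null(report$comparisons$external)) {
        ext <- report$comparisons$external
        lines <- c(lines,
                   paste0("external_mapped_targets: ",
                          length(ext$mapped_targets)),
                   paste0("external_retrieval_fraction: ",
                          fmt(ext$retrieval_fraction)))
    }
    lines
}
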