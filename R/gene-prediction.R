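#' Build an annotation table
#'
#' Flat two-column knowledge table used by the prediction modules: pathway
#' membership (pathway id, gene), protein-protein interactions (gene, gene),
#' domain content (gene, domain), transcription-factor targets (TF, gene) and
#' microRNA targets (miRNA, gene).
#'
#' @param kind one of "pathway", "interaction", "domain", "tf_target",
#'   "mirna_target".
#' @param subject,object character vectors of equal length.
#' @return data.frame with columns `subject`, `object` and attribute `kind`.
#' @export
annotationTable <- function(kind, subject, object) {
    kind <- match.arg(kind, c("pathway", "interaction", "domain",
                              "tf_target", "mirna_target"))
    stopIfNot(length(subject) == length(object),
              "subject and object must have equal length")
    keep <- nzchar(subject) & nzchar(object) & !is.na(subject) & !is.na(object)
    out <- unique(data.frame(subject = as.character(subject[keep]),
                             object = as.character(object[keep]),
                             stringsAsFactors = FALSE))
    rownames(out) <- NULL
    attr(out, "kind") <- kind
    out
}

#' Read a two-column annotation TSV
#'
#' @param path path to a headered two-column TSV.
#' @param kind annotation kind, see [annotationTable()].
#' @return an annotation table.
#' @export
readAnnotationTsv <- function(path, kind) {
    stopIfNot(file.exists(path), "annotation file not found: ", path)
    raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopIfNot(ncol(raw) >= 2, "annotation file needs two columns")
    annotationTable(kind, raw[[1]], raw[[2]])
}

# unique (gene, locus) membership of a space, genes only
spaceMembership <- function(space) {
    a <- spaceAssignments(space)
    a <- a[!is.na(a$gene), c("gene", "locus_id")]
    unique(a)
}

# Shared-group rule for CPS/CRT/MIR: gene g in locus L is hit iff some group
# (pathway / TF / miRNA) contains g and a *different* gene occupying a
# *different* locus of the same space.
sharedGroupHits <- function(membership, groups) {
    if (nrow(membership) == 0 || nrow(groups) == 0)
        return(membership[0, , drop = FALSE])
    joined <- merge(membership, groups, by.x = "gene", by.y = "object")
    # joined: gene, locus_id, subject (group id)
    hit <- logical(nrow(joined))
    for (grp in split(seq_len(nrow(joined)), joined$subject)) {
        g <- joined$gene[grp]; l <- joined$locus_id[grp]
        for (i in seq_along(grp)) {
            if (any(g != g[i] & l != l[i])) hit[grp[i]] <- TRUE
        }
    }
    unique(joined[hit, c("gene", "locus_id"), drop = FALSE])
}

predictionFrame <- function(hits, space, module) {
    if (nrow(hits) == 0)
        return(data.frame(gene = character(), locus_id = character(),
                          module = character(), stratum = character(),
                          method = character(), stringsAsFactors = FALSE))
    out <- data.frame(gene = hits$gene, locus_id = hits$locus_id,
                      module = module, stratum = stratumLabel(space),
                      method = methodName(space), stringsAsFactors = FALSE)
    out <- out[order(out$gene, out$locus_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Common Pathway Scanning (CPS)
#'
#' Nominates a gene when it shares a pathway with a different gene located in
#' a different locus of the same search space; pathway sharing within a
#' single locus never predicts.
#'
#' @param space a [SearchSpace-class] object.
#' @param pathways annotation table of kind "pathway" (pathway id, gene).
#' @return data.frame with columns `gene`, `locus_id`, `module`, `stratum`,
#'   `method`.
#' @export
predictCps <- function(space, pathways) {
    hits <- sharedGroupHits(spaceMembership(space), pathways)
    predictionFrame(hits, space, "CPS")
}

#' Protein-protein interaction module (PPI)
#'
#' Nominates a gene when it directly interacts with a different gene in a
#' different locus. Interactions are symmetric; self-edges are ignored.
#'
#' @param space a [SearchSpace-class] object.
#' @param interactions annotation table of kind "interaction" (gene, gene).
#' @return prediction data.frame as in [predictCps()].
#' @export
predictPpi <- function(space, interactions) {
    membership <- spaceMembership(space)
    if (nrow(membership) == 0 || nrow(interactions) == 0)
        return(predictionFrame(membership[0, ], space, "PPI"))
    edges <- rbind(interactions[, c("subject", "object")],
                   data.frame(subject = interactions$object,
                              object = interactions$subject))
    edges <- unique(edges[edges$subject != edges$object, , drop = FALSE])
    joined <- merge(membership, edges, by.x = "gene", by.y = "subject")
    # partner (object) must occupy a different locus
    partnerLoci <- split(membership$locus_id, membership$gene)
    hit <- vapply(seq_len(nrow(joined)), function(i) {
        pl <- partnerLoci[[joined$object[i]]]
        !is.null(pl) && any(pl != joined$locus_id[i])
    }, logical(1))
    predictionFrame(unique(joined[hit, c("gene", "locus_id")]), space, "PPI")
}

#' Common Module Profiling (CMP)
#'
#' Nominates a gene when its protein-domain profile is similar to that of a
#' known phenotype (seed) gene: Jaccard similarity of the two domain sets at
#' least `tau`. Genes or seeds without annotated domains never match. No
#' cross-locus requirement applies.
#'
#' @param space a [SearchSpace-class] object.
#' @param domains annotation table of kind "domain" (gene, domain).
#' @param seedGenes character vector of known phenotype genes.
#' @param tau Jaccard similarity threshold in `[0, 1]`, default 0.5.
#' @return prediction data.frame as in [predictCps()].
#' @export
predictCmp <- function(space, domains, seedGenes, tau = 0.5) {
    stopIfNot(tau >= 0 && tau <= 1, "tau must lie in [0, 1]")
    membership <- spaceMembership(space)
    if (nrow(membership) == 0 || length(seedGenes) == 0 || nrow(domains) == 0)
        return(predictionFrame(membership[0, ], space, "CMP"))
    domSets <- lapply(split(domains$object, domains$subject), unique)
    seedSets <- domSets[intersect(unique(seedGenes), names(domSets))]
    seedSets <- seedSets[lengths(seedSets) > 0]
    if (length(seedSets) == 0)
        return(predictionFrame(membership[0, ], space, "CMP"))
    geneOk <- vapply(unique(membership$gene), function(g) {
        dg <- domSets[[g]]
        if (is.null(dg) || length(dg) == 0) return(FALSE)
        any(vapply(seedSets, function(ds)
            length(intersect(dg, ds)) / length(union(dg, ds)) >= tau,
            logical(1)))
    }, logical(1))
    hits <- membership[membership$gene %in%
                       names(geneOk)[geneOk], , drop = FALSE]
    predictionFrame(hits, space, "CMP")
}

#' Common Regulatory Targets (CRT)
#'
#' Nominates a gene when a transcription factor targets both the gene and a
#' different gene in a different locus of the same space.
#'
#' @param space a [SearchSpace-class] object.
#' @param tfTargets annotation table of kind "tf_target" (TF, gene).
#' @return prediction data.frame as in [predictCps()].
#' @export
predictCrt <- function(space, tfTargets) {
    hits <- sharedGroupHits(spaceMembership(space), tfTargets)
    predictionFrame(hits, space, "CRT")
}

#' MicroRNA regulatory module (MIR)
#'
#' Nominates a gene when (a) a microRNA targets both the gene and a different
#' gene in a different locus, and (b) the gene is a regulatory hub, i.e.
#' targeted by at least `hubK` distinct microRNAs.
#'
#' @param space a [SearchSpace-class] object.
#' @param mirnaTargets annotation table of kind "mirna_target" (miRNA, gene).
#' @param hubK minimum number of distinct targeting microRNAs, default 5.
#' @return prediction data.frame as in [predictCps()].
#' @export
predictMir <- function(space, mirnaTargets, hubK = 5L) {
    stopIfNot(hubK >= 1, "hubK must be >= 1")
    hits <- sharedGroupHits(spaceMembership(space), mirnaTargets)
    if (nrow(hits) > 0) {
        indeg <- vapply(split(mirnaTargets$subject, mirnaTargets$object),
                        function(m) length(unique(m)), integer(1))
        ok <- hits$gene %in% names(indeg)[indeg >= hubK]
        hits <- hits[ok, , drop = FALSE]
    }
    predictionFrame(hits, space, "MIR")
}

#' Combine module predictions across search spaces
#'
#' Takes per-module, per-space prediction frames and merges them into one
#' record per unique gene, with supporting modules, loci and
#' (stratum, method) spaces accumulated as semicolon-joined unions.
#'
#' @param predictions a list of prediction data.frames (or a single rbind-ed
#'   data.frame) as produced by the `predict*` functions.
#' @return data.frame with columns `gene`, `modules`, `n_modules`, `loci`,
#'   `n_loci`, `spaces`, one row per gene, sorted by symbol.
#' @export
combinePredictions <- function(predictions) {
    if (is.data.frame(predictions)) predictions <- list(predictions)
    all <- do.call(rbind, predictions)
    if (is.null(all) || nrow(all) == 0)
        return(data.frame(gene = character(), modules = character(),
                          n_modules = integer(), loci = character(),
                          n_loci = integer(), spaces = character(),
                          stringsAsFactors = FALSE))
    all$space <- paste(all$stratum, all$method, sep = "/")
    rows <- lapply(split(all, all$gene), function(d) {
        data.frame(gene = d$gene[1], modules = joinSemi(d$module),
                   n_modules = length(unique(d$module)),
                   loci = joinSemi(d$locus_id),
                   n_loci = length(unique(d$locus_id)),
                   spaces = joinSemi(d$space), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Run all five prediction modules over a list of search spaces
#'
#' Convenience wrapper applying CPS, PPI, CMP, CRT and MIR to every space and
#' combining the results with [combinePredictions()].
#'
#' @param spaces list of [SearchSpace-class] objects (e.g. the 24-space grid
#'   from [buildAllSearchSpaces()]).
#' @param annotations named list with elements `pathway`, `interaction`,
#'   `domain`, `tf_target`, `mirna_target` (annotation tables).
#' @param seedGenes known phenotype genes for CMP.
#' @param tau CMP Jaccard threshold.
#' @param hubK MIR hub threshold.
#' @return combined candidate table from [combinePredictions()].
#' @export
predictCandidates <- function(spaces, annotations, seedGenes,
                              tau = 0.5, hubK = 5L) {
    preds <- list()
    for (sp in spaces) {
        preds[[length(preds) + 1L]] <- predictCps(sp, annotations$pathway)
        preds[[length(preds) + 1L]] <- predictPpi(sp, annotations$interaction)
        preds[[length(preds) + 1L]] <- predictCmp(sp, annotations$domain,
                                                  seedGenes, tau = tau)
        preds[[length(preds) + 1L]] <- predictCrt(sp, annotations$tf_target)
        preds[[length(preds) + 1L]] <- predictMir(sp, annotations$mirna_target,
                                                  hubK = hubK)
    }
    combinePredictions(preds)
}
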