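#' Map candidate genes to therapeutic targets
#'
#' Intersects predicted candidate genes with the targets of a pooled
#' drug-target dataset; each hit carries its drugs, source databases and
#' member-drug statuses.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param pooled a [PooledDrugTargets-class] object.
#' @return data.frame with one row per target gene: `gene`, `n_drugs`,
#'   `drugs` (";"-joined normalized keys), `source_dbs`, `statuses`.
#' @export
mapTargets <- function(candidates, pooled) {
    candidates <- unique(candidates)
    rec <- drugTargetRecords(pooled)
    hit <- rec[rec$target %in% candidates, , drop = FALSE]
    if (nrow(hit) == 0)
        return(data.frame(gene = character(), n_drugs = integer(),
                          drugs = character(), source_dbs = character(),
                          statuses = character(), stringsAsFactors = FALSE))
    rows <- lapply(split(hit, hit$target), function(d) {
        data.frame(gene = d$target[1], n_drugs = length(unique(d$drug)),
                   drugs = joinSemi(d$drug),
                   source_dbs = joinSemi(splitSemi(d$sources)),
                   statuses = joinSemi(splitSemi(d$statuses)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# TRUE where any ";"-joined indication string matches any phenotype term
# (normalized substring match)
indicationMatches <- function(indications, phenotypeTerms) {
    terms <- normalizeText(phenotypeTerms)
    terms <- terms[nzchar(terms)]
    vapply(indications, function(s) {
        parts <- normalizeText(splitSemi(s))
        any(vapply(terms, function(t) any(grepl(t, parts, fixed = TRUE)),
                   logical(1)))
    }, logical(1), USE.NAMES = FALSE)
}

#' Classify targets as known or novel for the phenotype
#'
#' A target is *known* iff at least one of its associated drugs carries an
#' indication matching any phenotype term (normalized substring match);
#' otherwise it is a novel therapeutic target, i.e. a repositioning
#' opportunity.
#'
#' @param targets target table from [mapTargets()].
#' @param pooled the [PooledDrugTargets-class] object the targets came from.
#' @param phenotypeTerms non-empty character vector of phenotype names and
#'   synonyms.
#' @return `targets` with an added logical column `is_known`.
#' @export
classifyTargetNovelty <- function(targets, pooled, phenotypeTerms) {
    stopIfNot(length(phenotypeTerms) >= 1, "phenotypeTerms must be non-empty")
    rec <- drugTargetRecords(pooled)
    known <- vapply(targets$gene, function(g) {
        d <- rec[rec$target == g, , drop = FALSE]
        nrow(d) > 0 && any(indicationMatches(d$indications, phenotypeTerms))
    }, logical(1), USE.NAMES = FALSE)
    targets$is_known <- known
    targets
}

#' Status class of a set of drug statuses
#'
#' Splits items into `approved_only`, `clinical_only` and `both`. The
#' approved class is the "approved" status; the clinical class comprises
#' clinical, experimental and unknown statuses (experimental/unknown-only
#' drugs are binned with the clinical class).
#'
#' @param statuses character vector of ";"-joined normalized statuses, one
#'   element per item (target or drug).
#' @return character vector over {approved_only, clinical_only, both}.
#' @export
classifyStatusClass <- function(statuses) {
    vapply(statuses, function(s) {
        v <- splitSemi(s)
        hasAppr <- "approved" %in% v
        hasClin <- any(c("clinical", "experimental", "unknown") %in% v)
        if (hasAppr && hasClin) "both"
        else if (hasAppr) "approved_only"
        else "clinical_only"
    }, character(1), USE.NAMES = FALSE)
}

#' Status breakdown counts
#'
#' @param classes vector from [classifyStatusClass()].
#' @return named integer vector c(approved_only, clinical_only, both); sums
#'   to `length(classes)`.
#' @export
statusBreakdown <- function(classes) {
    c(approved_only = sum(classes == "approved_only"),
      clinical_only = sum(classes == "clinical_only"),
      both = sum(classes == "both"))
}

#' Build the drug-level table for a set of targets
#'
#' One row per unique drug associated with any of the given target genes,
#' with its aggregate status class and novelty (a drug is novel iff none of
#' its records carries a phenotype-matching indication).
#'
#' @param targetGenes character vector of target gene symbols.
#' @param pooled a [PooledDrugTargets-class] object.
#' @param phenotypeTerms phenotype names and synonyms.
#' @return data.frame with columns `drug`, `targets`, `statuses`,
#'   `status_class`, `is_known`.
#' @export
buildDrugTable <- function(targetGenes, pooled, phenotypeTerms) {
    rec <- drugTargetRecords(pooled)
    hit <- rec[rec$target %in% targetGenes, , drop = FALSE]
    if (nrow(hit) == 0)
        return(data.frame(drug = character(), targets = character(),
                          statuses = character(), status_class = character(),
                          is_known = logical(), stringsAsFactors = FALSE))
    rows <- lapply(split(hit, hit$drug), function(d) {
        data.frame(drug = d$drug[1], targets = joinSemi(d$target),
                   statuses = joinSemi(splitSemi(d$statuses)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$status_class <- classifyStatusClass(out$statuses)
    knownByDrug <- vapply(split(hit, hit$drug), function(d)
        any(indicationMatches(d$indications, phenotypeTerms)),
        logical(1))
    out$is_known <- knownByDrug[out$drug]
    out <- out[order(out$drug), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Targetability Index
#'
#' Ratio of predicted therapeutic targets to predicted candidate genes.
#'
#' @param nTargets number of predicted therapeutic targets.
#' @param nCandidates number of predicted candidate genes (> 0).
#' @return the ratio, in `[0, 1]`.
#' @examples
#' renderPercent(targetabilityIndex(192, 647))  # "30%"
#' @export
targetabilityIndex <- function(nTargets, nCandidates) {
    stopIfNot(nCandidates > 0, "nCandidates must be > 0")
    stopIfNot(nTargets <= nCandidates, "nTargets must be <= nCandidates")
    nTargets / nCandidates
}

#' Novelty ratio
#'
#' Ratio of novel therapeutic targets to all predicted therapeutic targets.
#'
#' @param nNovel number of novel targets.
#' @param nTargets number of predicted targets (> 0).
#' @return the ratio, in `[0, 1]`.
#' @examples
#' renderRatio(noveltyRatio(184, 192))  # "0.95"
#' @export
noveltyRatio <- function(nNovel, nTargets) {
    stopIfNot(nTargets > 0, "nTargets must be > 0")
    stopIfNot(nNovel <= nTargets, "nNovel must be <= nTargets")
    nNovel / nTargets
}

#' Reporting conventions for ratios
#'
#' `renderPercent` renders a proportion as a whole percent (nearest integer);
#' `renderRatio` truncates at two decimals. These are the conventions used
#' throughout the textual report.
#'
#' @param x a proportion in `[0, 1]`.
#' @return character scalar.
#' @export
renderPercent <- function(x) paste0(round(x * 100), "%")

#' @rdname renderPercent
#' @export
renderRatio <- function(x) sprintf("%.2f", floor(x * 100 + 1e-9) / 100)

#' Summarize a repositioning run
#'
#' Aggregates candidate, target and drug statistics into one summary list and
#' asserts the partition identities (known + novel = total for targets and
#' drugs; status breakdowns sum to their class totals). Violations raise an
#' error naming the identity.
#'
#' @param candidates candidate table from [combinePredictions()] (or a
#'   character vector of candidate genes).
#' @param targets classified target table (with `is_known` and
#'   `status_class` columns).
#' @param drugs drug table from [buildDrugTable()].
#' @param venn optional [VennCounts3-class] of targets by source database.
#' @return a list of class `repositioningSummary`.
#' @export
summarizeRepositioning <- function(candidates, targets, drugs, venn = NULL) {
    candGenes <- if (is.data.frame(candidates)) candidates$gene else candidates
    nCand <- length(unique(candGenes))
    nTargets <- nrow(targets)
    nKnown <- sum(targets$is_known)
    nNovel <- sum(!targets$is_known)
    if (nKnown + nNovel != nTargets)
        stop("integrity error: n_known + n_novel != n_targets")
    nDrugs <- nrow(drugs)
    nKnownDrugs <- sum(drugs$is_known)
    nNovelDrugs <- sum(!drugs$is_known)
    if (nKnownDrugs + nNovelDrugs != nDrugs)
        stop("integrity error: n_known_drugs + n_novel_drugs != n_drugs")
    novelTargetBreakdown <- statusBreakdown(
        targets$status_class[!targets$is_known])
    if (sum(novelTargetBreakdown) != nNovel)
        stop("integrity error: novel-target status breakdown != n_novel_targets")
    novelDrugBreakdown <- statusBreakdown(
        drugs$status_class[!drugs$is_known])
    if (sum(novelDrugBreakdown) != nNovelDrugs)
        stop("integrity error: novel-drug status breakdown != n_novel_drugs")
    perDb <- if (nTargets > 0) {
        dbs <- splitSemi(targets$source_dbs)
        table(unlist(lapply(seq_len(nTargets), function(i)
            unique(splitSemi(targets$source_dbs[i])))))
    } else table(character())
    out <- list(
        n_candidates = nCand,
        n_targets = nTargets,
        n_known_targets = nKnown,
        n_novel_targets = nNovel,
        targetability_index = if (nCand > 0) nTargets / nCand else NA_real_,
        novelty_ratio = if (nTargets > 0) nNovel / nTargets else NA_real_,
        n_drugs = nDrugs,
        n_known_drugs = nKnownDrugs,
        n_novel_drugs = nNovelDrugs,
        novel_target_status = novelTargetBreakdown,
        novel_drug_status = novelDrugBreakdown,
        per_db_targets = perDb,
        venn = venn)
    class(out) <- "repositioningSummary"
    out
}

#' @export
print.repositioningSummary <- function(x, ...) {
    cat("Repositioning summary\n")
    cat("  candidates:      ", x$n_candidates, "\n")
    cat("  targets:         ", x$n_targets,
        if (!is.na(x$targetability_index))
            paste0(" (TI ", renderPercent(x$targetability_index), ")") else "",
        "\n", sep = "")
    cat("  known / novel:   ", x$n_known_targets, "/", x$n_novel_targets,
        if (!is.na(x$novelty_ratio))
            paste0(" (novelty ratio ", renderRatio(x$novelty_ratio), ")")
        else "", "\n", sep = " ")
    cat("  drugs (known/novel):", x$n_known_drugs, "/", x$n_novel_drugs, "\n")
    invisible(x)
}
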