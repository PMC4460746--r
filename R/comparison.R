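#' Compare two gene sets
#'
#' Exact partition of two symbol sets into the common part and the two
#' exclusive parts, with memberships.
#'
#' @param a,b character vectors (converted to sets).
#' @return list with counts `n_common`, `n_only_a`, `n_only_b` and membership
#'   vectors `common`, `only_a`, `only_b`.
#' @examples
#' cmp <- compareSets(c("a", "b", "c"), c("b", "c", "d"))
#' cmp$n_common  # 2
#' @export
compareSets <- function(a, b) {
    a <- unique(a); b <- unique(b)
    common <- sort(intersect(a, b))
    onlyA <- sort(setdiff(a, b))
    onlyB <- sort(setdiff(b, a))
    list(n_common = length(common), n_only_a = length(onlyA),
         n_only_b = length(onlyB), common = common, only_a = onlyA,
         only_b = onlyB)
}

#' Overlap of an external gene list with predicted targets
#'
#' Maps an externally derived gene list (e.g. from a larger meta-analysis)
#' onto the pooled drug-target dataset, then compares the druggable subset
#' with the predicted therapeutic targets. The retrieval fraction is the
#' share of the external list's druggable genes that the pipeline also
#' predicted.
#'
#' @param geneList character vector of external gene symbols.
#' @param pooled a [PooledDrugTargets-class] object.
#' @param predictedTargets character vector of predicted therapeutic targets.
#' @return list with `mapped_targets` (external genes that are drug targets),
#'   `comparison` (from [compareSets()], A = mapped targets, B = predicted),
#'   and `retrieval_fraction` (NA when no external gene is druggable).
#' @export
externalListOverlap <- function(geneList, pooled, predictedTargets) {
    mapped <- sort(intersect(unique(geneList), uniqueTargets(pooled)))
    cmp <- compareSets(mapped, predictedTargets)
    frac <- if (length(mapped) > 0) cmp$n_common / length(mapped) else NA_real_
    list(mapped_targets = mapped, comparison = cmp,
         retrieval_fraction = frac)
}
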