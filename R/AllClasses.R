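#' @import methods
#' @importFrom stats runif rexp rpois
#' @importFrom utils read.delim write.table head
NULL

#' SnpStrata: nested SNP significance sets
#'
#' Holds a table of SNP association results together with a named, strictly
#' increasing vector of p-value thresholds. Stratum membership is cumulative:
#' the stratum at threshold `t` contains every SNP with `p_value <= t`, so the
#' strata are nested from the most stringent to the most permissive set.
#'
#' @slot snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `p_value`.
#' @slot thresholds named numeric vector of strictly increasing thresholds;
#'   default labels are HS, MHS, MWS, WS.
#' @export
setClass("SnpStrata",
    representation(snps = "data.frame", thresholds = "numeric"))

setValidity("SnpStrata", function(object) {
    msgs <- character()
    req <- c("snp_id", "chrom", "pos", "p_value")
    if (!all(req %in% names(object@snps)))
        msgs <- c(msgs, paste("snps must have columns:", paste(req, collapse = ", ")))
    th <- object@thresholds
    if (length(th) < 1L || is.null(names(th)) || any(!nzchar(names(th))))
        msgs <- c(msgs, "thresholds must be a non-empty named numeric vector")
    if (length(th) > 1L && any(diff(th) <= 0))
        msgs <- c(msgs, "thresholds must be strictly increasing")
    if (nrow(object@snps) > 0) {
        p <- object@snps$p_value
        if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
            msgs <- c(msgs, "p_value must lie in (0, 1]")
        if (anyDuplicated(object@snps$snp_id))
            msgs <- c(msgs, "snp_id must be unique")
        if (any(p > max(th)))
            msgs <- c(msgs, "all retained SNPs must pass the widest threshold")
    }
    if (length(msgs)) msgs else TRUE
})

#' SearchSpace: genes assigned to SNP loci
#'
#' One search space is the gene assignment produced by applying a single
#' construction method (fixed-width window or k-nearest genes) to every SNP of
#' one significance stratum. Each SNP anchors its own locus; loci are never
#' merged, so a gene near two SNPs appears once per locus.
#'
#' @slot stratum stratum label (e.g. "WS").
#' @slot method construction method name (see [searchSpaceMethods()]).
#' @slot params list with `type` ("fixed" or "nearest") and `width` or `k`.
#' @slot assignments data.frame with one row per (locus, gene):
#'   `locus_id`, `snp_id`, `chrom`, `pos`, `gene`. Loci on chromosomes without
#'   genes are kept with `gene = NA`.
#' @export
setClass("SearchSpace",
    representation(stratum = "character", method = "character",
                   params = "list", assignments = "data.frame"))

setValidity("SearchSpace", function(object) {
    msgs <- character()
    req <- c("locus_id", "snp_id", "chrom", "pos", "gene")
    if (!all(req %in% names(object@assignments)))
        msgs <- c(msgs, paste("assignments must have columns:", paste(req, collapse = ", ")))
    if (length(object@stratum) != 1L || length(object@method) != 1L)
        msgs <- c(msgs, "stratum and method must be length-1 character")
    if (!is.null(object@params$type) &&
        !object@params$type %in% c("fixed", "nearest"))
        msgs <- c(msgs, "params$type must be 'fixed' or 'nearest'")
    if (length(msgs)) msgs else TRUE
})

#' PooledDrugTargets: harmonized drug-target associations
#'
#' Drug-target records pooled across source databases. Drug identity is the
#' case-folded, whitespace-normalized drug name; each (drug, target) pair is
#' stored once, with source databases, development statuses, indications and
#' actions merged as semicolon-joined unions.
#'
#' @slot records data.frame with columns `drug` (normalized key), `drug_name`
#'   (representative original spelling), `target` (HUGO symbol), `sources`,
#'   `statuses`, `indications`, `actions` (each ";"-joined, sorted, unique).
#' @export
setClass("PooledDrugTargets", representation(records = "data.frame"))

setValidity("PooledDrugTargets", function(object) {
    msgs <- character()
    req <- c("drug", "drug_name", "target", "sources", "statuses",
             "indications", "actions")
    if (!all(req %in% names(object@records)))
        msgs <- c(msgs, paste("records must have columns:", paste(req, collapse = ", ")))
    else {
        if (nrow(object@records) > 0 &&
            anyDuplicated(object@records[, c("drug", "target")]))
            msgs <- c(msgs, "(drug, target) pairs must be unique")
        if (any(!nzchar(object@records$target)))
            msgs <- c(msgs, "target symbols must be non-empty")
    }
    if (length(msgs)) msgs else TRUE
})

#' VennCounts3: exclusive regions of a 3-set Venn diagram
#'
#' @slot counts named numeric vector of the seven exclusive region counts, in
#'   order A, B, C, AB, AC, BC, ABC (pairwise regions exclude the triple).
#' @slot setNames names of the three sets.
#' @export
setClass("VennCounts3",
    representation(counts = "numeric", setNames = "character"))

setValidity("VennCounts3", function(object) {
    msgs <- character()
    reg <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
    if (length(object@counts) != 7L || !identical(names(object@counts), reg))
        msgs <- c(msgs, "counts must be the seven regions A,B,C,AB,AC,BC,ABC")
    else if (any(object@counts < 0))
        msgs <- c(msgs, "region counts must be non-negative")
    if (length(object@setNames) != 3L)
        msgs <- c(msgs, "setNames must have length 3")
    if (length(msgs)) msgs else TRUE
})

#' ContingencyTable: TP/FP/FN/TN counts for one ROC point
#'
#' @slot tp,fp,fn,tn non-negative counts; their sum is the benchmark universe
#'   size.
#' @slot excludedKnown number of known-positive genes that fell outside the
#'   universe and were excluded from the classification.
#' @export
setClass("ContingencyTable",
    representation(tp = "numeric", fp = "numeric", fn = "numeric",
                   tn = "numeric", excludedKnown = "numeric"))

setValidity("ContingencyTable", function(object) {
    v <- c(object@tp, object@fp, object@fn, object@tn, object@excludedKnown)
    if (length(v) != 5L || any(!is.finite(v)) || any(v < 0) ||
        any(v != round(v)))
        "tp, fp, fn, tn, excludedKnown must be non-negative integers"
    else TRUE
})

#' RocCurve: an ROC curve with trapezoidal AUC
#'
#' @slot points two-column matrix (`fpr`, `tpr`), sorted by fpr then tpr,
#'   anchored at (0,0) and (1,1).
#' @slot auc area under the curve by the trapezoid rule.
#' @export
setClass("RocCurve", representation(points = "matrix", auc = "numeric"))

setValidity("RocCurve", function(object) {
    msgs <- character()
    p <- object@points
    if (ncol(p) != 2L || !identical(colnames(p), c("fpr", "tpr")))
        msgs <- c(msgs, "points must be a two-column matrix (fpr, tpr)")
    else {
        if (any(p < -1e-12) || any(p > 1 + 1e-12))
            msgs <- c(msgs, "fpr and tpr must lie in [0, 1]")
        if (is.unsorted(p[, "fpr"]))
            msgs <- c(msgs, "points must be sorted by fpr")
    }
    if (length(object@auc) != 1L || object@auc < -1e-12 || object@auc > 1 + 1e-12)
        msgs <- c(msgs, "auc must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})
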