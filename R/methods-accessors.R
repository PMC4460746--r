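#' @describeIn SnpStrata-class stratum labels, most stringent first.
#' @export
setMethod("strataLabels", "SnpStrata", function(x) names(x@thresholds))

#' @describeIn SnpStrata-class named threshold vector.
#' @export
setMethod("strataThresholds", "SnpStrata", function(x) x@thresholds)

#' @describeIn SnpStrata-class SNP table of one stratum (cumulative: all SNPs
#'   at or below the stratum's threshold).
#' @export
setMethod("strataSnps", "SnpStrata", function(x, label) {
    if (!label %in% names(x@thresholds))
        stop("unknown stratum label: ", label)
    x@snps[x@snps$p_value <= x@thresholds[[label]], , drop = FALSE]
})

setMethod("show", "SnpStrata", function(object) {
    sizes <- vapply(names(object@thresholds),
                    function(l) nrow(strataSnps(object, l)), integer(1))
    cat("SnpStrata with", length(object@thresholds), "nested strata,",
        nrow(object@snps), "SNPs\n")
    for (l in names(object@thresholds))
        cat(sprintf("  %-4s p <= %-8g n = %d\n", l,
                    object@thresholds[[l]], sizes[[l]]))
})

#' @describeIn SearchSpace-class stratum label.
#' @export
setMethod("stratumLabel", "SearchSpace", function(x) x@stratum)

#' @describeIn SearchSpace-class construction-method name.
#' @export
setMethod("methodName", "SearchSpace", function(x) x@method)

#' @describeIn SearchSpace-class one row per (locus, gene) assignment.
#' @export
setMethod("spaceAssignments", "SearchSpace", function(x) x@assignments)

#' @describeIn SearchSpace-class unique gene symbols in the space.
#' @export
setMethod("spaceGenes", "SearchSpace", function(x) {
    g <- x@assignments$gene
    sort(unique(g[!is.na(g)]))
})

#' @describeIn SearchSpace-class unique locus identifiers.
#' @export
setMethod("spaceLoci", "SearchSpace", function(x) unique(x@assignments$locus_id))

setMethod("show", "SearchSpace", function(object) {
    cat("SearchSpace", paste0(object@stratum, "/", object@method), "-",
        length(spaceLoci(object)), "loci,",
        length(spaceGenes(object)), "genes\n")
})

#' @describeIn PooledDrugTargets-class pooled (drug, target) record table.
#' @export
setMethod("drugTargetRecords", "PooledDrugTargets", function(x) x@records)

#' @describeIn PooledDrugTargets-class sorted unique target symbols.
#' @export
setMethod("uniqueTargets", "PooledDrugTargets",
          function(x) sort(unique(x@records$target)))

#' @describeIn PooledDrugTargets-class sorted unique normalized drug keys.
#' @export
setMethod("uniqueDrugs", "PooledDrugTargets",
          function(x) sort(unique(x@records$drug)))

setMethod("show", "PooledDrugTargets", function(object) {
    cat("PooledDrugTargets:", nrow(object@records), "(drug, target) pairs,",
        length(uniqueDrugs(object)), "drugs,",
        length(uniqueTargets(object)), "targets\n")
})

#' @describeIn VennCounts3-class named counts of the seven exclusive regions.
#' @export
setMethod("vennCounts", "VennCounts3", function(x) x@counts)

#' @describeIn VennCounts3-class size of the three-set union.
#' @export
setMethod("vennUnion", "VennCounts3", function(x) sum(x@counts))

#' @describeIn VennCounts3-class per-set totals (sum of each set's four
#'   regions), named by `setNames`.
#' @export
setMethod("vennSetTotals", "VennCounts3", function(x) {
    k <- x@counts
    tot <- c(k[["A"]] + k[["AB"]] + k[["AC"]] + k[["ABC"]],
             k[["B"]] + k[["AB"]] + k[["BC"]] + k[["ABC"]],
             k[["C"]] + k[["AC"]] + k[["BC"]] + k[["ABC"]])
    names(tot) <- x@setNames
    tot
})

setMethod("show", "VennCounts3", function(object) {
    cat("VennCounts3 (", paste(object@setNames, collapse = ", "), ")\n", sep = "")
    print(object@counts)
})

#' @describeIn ContingencyTable-class named vector c(tp, fp, fn, tn).
#' @export
setMethod("ctCounts", "ContingencyTable", function(x)
    c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))

#' @describeIn ContingencyTable-class sensitivity tp/(tp+fn); NA if undefined.
#' @export
setMethod("truePositiveRate", "ContingencyTable", function(x) {
    if (x@tp + x@fn == 0) NA_real_ else x@tp / (x@tp + x@fn)
})

#' @describeIn ContingencyTable-class fall-out fp/(fp+tn); NA if undefined.
#' @export
setMethod("falsePositiveRate", "ContingencyTable", function(x) {
    if (x@fp + x@tn == 0) NA_real_ else x@fp / (x@fp + x@tn)
})

setMethod("show", "ContingencyTable", function(object) {
    cat(sprintf("ContingencyTable tp=%d fp=%d fn=%d tn=%d (total %d)\n",
                object@tp, object@fp, object@fn, object@tn,
                object@tp + object@fp + object@fn + object@tn))
    if (object@excludedKnown > 0)
        cat("  known positives outside universe, excluded:",
            object@excludedKnown, "\n")
})

#' @describeIn RocCurve-class (fpr, tpr) point matrix including anchors.
#' @export
setMethod("rocPoints", "RocCurve", function(x) x@points)

#' @describeIn RocCurve-class trapezoidal area under the curve.
#' @export
setMethod("rocAuc", "RocCurve", function(x) x@auc)

setMethod("show", "RocCurve", function(object) {
    cat("RocCurve with", nrow(object@points), "points, AUC =",
        format(object@auc, digits = 4), "\n")
})
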