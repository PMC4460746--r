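#' @rdname SnpStrata-class
#' @param x object.
#' @export
setGeneric("strataLabels", function(x) standardGeneric("strataLabels"))

#' @rdname SnpStrata-class
#' @export
setGeneric("strataThresholds", function(x) standardGeneric("strataThresholds"))

#' @rdname SnpStrata-class
#' @param label stratum label.
#' @export
setGeneric("strataSnps", function(x, label) standardGeneric("strataSnps"))

#' @rdname SearchSpace-class
#' @param x object.
#' @export
setGeneric("stratumLabel", function(x) standardGeneric("stratumLabel"))

#' @rdname SearchSpace-class
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname SearchSpace-class
#' @export
setGeneric("spaceAssignments", function(x) standardGeneric("spaceAssignments"))

#' @rdname SearchSpace-class
#' @export
setGeneric("spaceGenes", function(x) standardGeneric("spaceGenes"))

#' @rdname SearchSpace-class
#' @export
setGeneric("spaceLoci", function(x) standardGeneric("spaceLoci"))

#' @rdname PooledDrugTargets-class
#' @param x object.
#' @export
setGeneric("drugTargetRecords", function(x) standardGeneric("drugTargetRecords"))

#' @rdname PooledDrugTargets-class
#' @export
setGeneric("uniqueTargets", function(x) standardGeneric("uniqueTargets"))

#' @rdname PooledDrugTargets-class
#' @export
setGeneric("uniqueDrugs", function(x) standardGeneric("uniqueDrugs"))

#' @rdname VennCounts3-class
#' @param x object.
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' @rdname VennCounts3-class
#' @export
setGeneric("vennUnion", function(x) standardGeneric("vennUnion"))

#' @rdname VennCounts3-class
#' @export
setGeneric("vennSetTotals", function(x) standardGeneric("vennSetTotals"))

#' @rdname ContingencyTable-class
#' @param x object.
#' @export
setGeneric("ctCounts", function(x) standardGeneric("ctCounts"))

#' @rdname ContingencyTable-class
#' @export
setGeneric("truePositiveRate", function(x) standardGeneric("truePositiveRate"))

#' @rdname ContingencyTable-class
#' @export
setGeneric("falsePositiveRate", function(x) standardGeneric("falsePositiveRate"))

#' @rdname RocCurve-class
#' @param x object.
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname RocCurve-class
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))
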