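#' Contingency table of predicted vs known targets over a universe
#'
#' Classifies every gene of the benchmark universe: true positives are
#' predicted and known, false negatives known but not predicted, false
#' positives predicted but not known, true negatives the remainder. Known
#' genes outside the universe are excluded from the classification and
#' reported via the `excludedKnown` slot.
#'
#' @param universe character vector of genes (non-empty).
#' @param predicted predicted genes; must be a subset of `universe`.
#' @param known known-positive genes (may extend beyond the universe).
#' @return a [ContingencyTable-class] object; tp+fp+fn+tn = |universe|.
#' @examples
#' ct <- contingencyTable(paste0("g", 1:10), paste0("g", 1:3),
#'                        c("g1", "g4"))
#' ctCounts(ct)  # tp 1, fp 2, fn 1, tn 6
#' @export
contingencyTable <- function(universe, predicted, known) {
    universe <- unique(universe)
    predicted <- unique(predicted)
    known <- unique(known)
    stopIfNot(length(universe) > 0, "universe must be non-empty")
    if (!all(predicted %in% universe))
        stop("predicted targets must be a subset of the universe")
    knownIn <- intersect(known, universe)
    tp <- length(intersect(predicted, knownIn))
    fn <- length(setdiff(knownIn, predicted))
    fp <- length(setdiff(predicted, knownIn))
    tn <- length(universe) - tp - fn - fp
    new("ContingencyTable", tp = tp, fp = fp, fn = fn, tn = tn,
        excludedKnown = length(known) - length(knownIn))
}

# trapezoid area under sorted (x, y) points
trapezoidArea <- function(x, y) {
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Assemble an ROC curve from a series of contingency tables
#'
#' Produces one (fpr, tpr) point per table, adds the (0,0) and (1,1)
#' anchors, sorts by fpr (ties by tpr) and computes the trapezoidal AUC.
#' Tables with undefined rates are skipped with a warning.
#'
#' @param tables list of [ContingencyTable-class] objects (at least one).
#' @return a [RocCurve-class] object.
#' @export
rocFromThresholds <- function(tables) {
    stopIfNot(length(tables) >= 1, "need at least one contingency table")
    pts <- lapply(tables, function(ct) {
        t <- truePositiveRate(ct); f <- falsePositiveRate(ct)
        if (is.na(t) || is.na(f)) {
            warning("contingency table with undefined tpr/fpr skipped")
            return(NULL)
        }
        c(fpr = f, tpr = t)
    })
    pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
    pts <- rbind(c(fpr = 0, tpr = 0), pts, c(fpr = 1, tpr = 1))
    ord <- order(pts[, "fpr"], pts[, "tpr"])
    pts <- pts[ord, , drop = FALSE]
    rownames(pts) <- NULL
    new("RocCurve", points = pts,
        auc = trapezoidArea(pts[, "fpr"], pts[, "tpr"]))
}

#' Mann-Whitney AUC with a permutation test
#'
#' The AUC is the pairwise probability that a positive score exceeds a
#' negative score, counting ties as 1/2 (the Mann-Whitney statistic divided
#' by n1*n2). Significance against the chance value 0.5 is assessed with a
#' one-sided label-permutation test under a fixed seed.
#'
#' @param posScores,negScores numeric score vectors (both non-empty).
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed for the permutation draw.
#' @return list with elements `auc` and `p_value`.
#' @export
aucSignificance <- function(posScores, negScores, nPerm = 1000L, seed = 1L) {
    stopIfNot(length(posScores) > 0 && length(negScores) > 0,
              "both score collections must be non-empty")
    stopIfNot(nPerm >= 100, "nPerm must be >= 100")
    n1 <- length(posScores); n2 <- length(negScores)
    mwAuc <- function(labels, scores) {
        r <- rank(scores)
        (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    }
    scores <- c(posScores, negScores)
    labels <- c(rep(TRUE, n1), rep(FALSE, n2))
    obs <- mwAuc(labels, scores)
    perm <- withSeed(seed, {
        vapply(seq_len(nPerm), function(b)
            mwAuc(sample(labels), scores), numeric(1))
    })
    p <- (1 + sum(perm >= obs - 1e-12)) / (nPerm + 1)
    list(auc = obs, p_value = p)
}

#' Search-space benchmark (known-target replication)
#'
#' Benchmark over the union of the six search spaces of one stratum. Each
#' gene is scored by the number of the six spaces in which it appears as a
#' predicted therapeutic target; thresholding the score at 6, 5, ..., 1
#' yields six contingency tables (known targets inside the universe are the
#' positives) and the resulting ROC curve. Significance is assessed by a
#' permutation test on the scores of known vs other universe genes.
#'
#' @param spaces the six [SearchSpace-class] objects of one stratum.
#' @param predictedTargets character vector of predicted therapeutic
#'   targets.
#' @param knownTargets character vector of known phenotype drug targets.
#' @param nPerm,seed permutation-test parameters, see [aucSignificance()].
#' @return list with `tables` (one per threshold, decreasing), `roc`, `auc`,
#'   `p_value`, `universe`, `scores`.
#' @export
searchSpaceBenchmark <- function(spaces, predictedTargets, knownTargets,
                                 nPerm = 1000L, seed = 1L) {
    universe <- searchSpaceGeneUniverse(spaces)
    score <- stats::setNames(integer(length(universe)), universe)
    for (sp in spaces) {
        hit <- intersect(intersect(spaceGenes(sp), predictedTargets), universe)
        score[hit] <- score[hit] + 1L
    }
    nSpaces <- length(spaces)
    tables <- lapply(seq(nSpaces, 1L), function(t)
        contingencyTable(universe, names(score)[score >= t], knownTargets))
    roc <- rocFromThresholds(tables)
    knownIn <- intersect(knownTargets, universe)
    sig <- if (length(knownIn) > 0 && length(knownIn) < length(universe)) {
        aucSignificance(score[knownIn], score[setdiff(universe, knownIn)],
                        nPerm = nPerm, seed = seed)
    } else list(auc = NA_real_, p_value = NA_real_)
    list(tables = tables, roc = roc, auc = sig$auc, p_value = sig$p_value,
         universe = universe, scores = score)
}

#' Literature-citation benchmark
#'
#' For each citation threshold `t`, a universe gene is literature-positive
#' iff it has at least `t` phenotype-linked citations; predicted targets are
#' classified against these positives, giving one contingency table per
#' threshold and an ROC curve. Genes without a citation record count as zero
#' citations (their number is reported).
#'
#' @param targets predicted therapeutic targets (subset of `universe`).
#' @param universe benchmark gene universe.
#' @param citations data.frame with columns `gene`, `n_citations`.
#' @param thresholds strictly increasing citation cutoffs; default
#'   c(1, 5, 10, 15).
#' @return list with `tables`, `roc`, `n_missing` (genes lacking citation
#'   records).
#' @export
citationBenchmark <- function(targets, universe, citations,
                              thresholds = c(1, 5, 10, 15)) {
    stopIfNot(length(thresholds) >= 1 && all(diff(thresholds) > 0) ||
              length(thresholds) == 1, "thresholds must be strictly increasing")
    universe <- unique(universe)
    counts <- stats::setNames(rep(0, length(universe)), universe)
    hit <- citations$gene %in% universe
    counts[citations$gene[hit]] <- citations$n_citations[hit]
    nMissing <- sum(!universe %in% citations$gene)
    tables <- lapply(rev(thresholds), function(t)
        contingencyTable(universe, intersect(targets, universe),
                         names(counts)[counts >= t]))
    list(tables = tables, roc = rocFromThresholds(tables),
         n_missing = nMissing)
}

#' Citation counts from gene-publication pairs
#'
#' Emulates the join of a gene-to-publication table with a set of
#' phenotype-linked publication ids: a gene's count is the number of its
#' publication ids that fall in the phenotype set.
#'
#' @param genePmids data.frame with columns `gene`, `pmid`.
#' @param phenotypePmids character or numeric vector of phenotype-linked
#'   publication ids.
#' @return data.frame with columns `gene`, `n_citations`.
#' @export
citationCountsFromPairs <- function(genePmids, phenotypePmids) {
    keep <- genePmids[genePmids$pmid %in% phenotypePmids, , drop = FALSE]
    tab <- table(keep$gene)
    data.frame(gene = names(tab), n_citations = as.integer(tab),
               stringsAsFactors = FALSE)
}

#' Read a citation TSV
#'
#' @param path headered TSV with columns `gene`, `n_citations`.
#' @return data.frame with those columns.
#' @export
readCitationsTsv <- function(path) {
    stopIfNot(file.exists(path), "citation file not found: ", path)
    raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopIfNot(all(c("gene", "n_citations") %in% names(raw)),
              "citation file needs columns gene, n_citations")
    raw[, c("gene", "n_citations")]
}
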