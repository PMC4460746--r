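#' Drug-export column dialects
#'
#' A dialect declares where to find the drug, target, status, indication and
#' action columns in one database export, plus the field separator and the
#' delimiter used inside the indication column. Three defaults mirror the
#' shapes of common public exports.
#'
#' @param drug,target,status,indication,action column names (`action` and
#'   `status` may be NA when the export lacks them).
#' @param sep field separator of the file.
#' @param indicationSep delimiter splitting multiple indications in one cell.
#' @return named list usable as the `dialect` argument of
#'   [parseDrugExport()].
#' @export
drugDialect <- function(drug, target, status, indication, action = NA,
                        sep = "\t", indicationSep = "|") {
    list(drug = drug, target = target, status = status,
         indication = indication, action = action, sep = sep,
         indicationSep = indicationSep)
}

#' @rdname drugDialect
#' @export
dialectDrugBank <- function() {
    drugDialect(drug = "name", target = "gene_name", status = "groups",
                indication = "indication", action = "actions", sep = ",")
}

#' @rdname drugDialect
#' @export
dialectTTD <- function() {
    drugDialect(drug = "DRUGNAME", target = "TARGETID", status = "HIGHEST_STATUS",
                indication = "INDICATION", action = "ACTION", sep = "\t")
}

#' @rdname drugDialect
#' @export
dialectPharmGKB <- function() {
    drugDialect(drug = "Chemical", target = "Gene", status = "Status",
                indication = "Indication", action = NA, sep = "\t")
}

#' Normalize development-status tokens
#'
#' Maps free-text status strings to the closed vocabulary `approved`,
#' `clinical`, `experimental`, `unknown`: "approved"/"launched" tokens map to
#' approved; phase, trial and investigational tokens to clinical;
#' "experimental"/"preclinical" to experimental; everything else to unknown.
#'
#' @param x character vector of raw status tokens.
#' @return character vector over the closed vocabulary, with attribute
#'   `n_unknown` counting unrecognized non-empty tokens.
#' @export
normalizeStatus <- function(x) {
    lx <- normalizeText(ifelse(is.na(x), "", x))
    out <- rep("unknown", length(lx))
    out[grepl("approved|launched", lx)] <- "approved"
    isClin <- out == "unknown" &
        grepl("phase|trial|clinical|investigational", lx)
    out[isClin] <- "clinical"
    isExp <- out == "unknown" & grepl("experimental|preclinical", lx)
    out[isExp] <- "experimental"
    unknownTok <- out == "unknown" & nzchar(lx) & lx != "unknown"
    attr(out, "n_unknown") <- sum(unknownTok)
    out
}

#' Parse one drug-database export
#'
#' Reads a delimited export under a column dialect, yielding one record per
#' (drug, target) row. Statuses are normalized to the closed vocabulary (a
#' count of unrecognized tokens is attached as a warning attribute);
#' indications are lower-cased and split on the dialect's delimiter.
#'
#' @param path path to the export file.
#' @param dialect a dialect from [drugDialect()].
#' @param sourceDb source database name, e.g. "DrugBank", "TTD", "PharmGKB".
#' @return data.frame with columns `drug_name`, `target`, `source_db`,
#'   `status`, `indications` (";"-joined, normalized), `action`; attribute
#'   `n_unknown_status`.
#' @export
parseDrugExport <- function(path, dialect, sourceDb) {
    stopIfNot(file.exists(path), "drug export not found: ", path)
    stopIfNot(all(c("drug", "target", "status", "indication") %in%
                  names(dialect)), "dialect must declare drug, target, status, indication")
    raw <- read.delim(path, sep = dialect$sep, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(raw) == 0) {
        out <- data.frame(drug_name = character(), target = character(),
                          source_db = character(), status = character(),
                          indications = character(), action = character(),
                          stringsAsFactors = FALSE)
        attr(out, "n_unknown_status") <- 0L
        return(out)
    }
    need <- c(dialect$drug, dialect$target)
    missing <- setdiff(need, names(raw))
    if (length(missing))
        stop("drug export lacks column(s): ", paste(missing, collapse = ", "))
    getCol <- function(colName) {
        if (is.na(colName) || !colName %in% names(raw))
            rep("", nrow(raw)) else as.character(raw[[colName]])
    }
    status <- normalizeStatus(getCol(dialect$status))
    nUnknown <- attr(status, "n_unknown")
    if (nUnknown > 0)
        warning(nUnknown, " unrecognized status token(s) in ", basename(path),
                " mapped to 'unknown'")
    indRaw <- getCol(dialect$indication)
    indications <- vapply(strsplit(indRaw, dialect$indicationSep, fixed = TRUE),
                          function(v) joinSemi(normalizeText(v)), character(1))
    out <- data.frame(drug_name = getCol(dialect$drug),
                      target = getCol(dialect$target),
                      source_db = sourceDb,
                      status = as.character(status),
                      indications = indications,
                      action = getCol(dialect$action),
                      stringsAsFactors = FALSE)
    out <- out[nzchar(out$drug_name) & nzchar(out$target), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_unknown_status") <- nUnknown
    out
}

#' Harmonize drug-target records to HUGO symbols
#'
#' Targets already present in the map's symbol column pass through unchanged;
#' accessions are translated via the map (an accession mapping to several
#' symbols duplicates the record, flagged in the count); untranslatable
#' targets are dropped and counted. Conservation:
#' `nrow(output) = nrow(input) - n_dropped + n_duplicated`.
#'
#' @param records parsed drug-target records, see [parseDrugExport()].
#' @param idMap data.frame with columns `accession`, `symbol`.
#' @return list with elements `records` (harmonized), `n_dropped`,
#'   `n_duplicated`.
#' @export
mapToHugo <- function(records, idMap) {
    stopIfNot(all(c("accession", "symbol") %in% names(idMap)),
              "idMap needs columns accession, symbol")
    symbols <- unique(idMap$symbol)
    isSym <- records$target %in% symbols
    keep <- records[isSym, , drop = FALSE]
    rest <- records[!isSym, , drop = FALSE]
    translated <- merge(rest, idMap, by.x = "target", by.y = "accession")
    nDropped <- sum(!rest$target %in% idMap$accession)
    nDuplicated <- nrow(translated) - sum(rest$target %in% idMap$accession)
    if (nrow(translated) > 0) {
        translated$target <- translated$symbol
        translated$symbol <- NULL
        translated <- translated[, names(records), drop = FALSE]
    } else {
        translated <- records[0, , drop = FALSE]
    }
    out <- rbind(keep, translated)
    rownames(out) <- NULL
    list(records = out, n_dropped = nDropped, n_duplicated = nDuplicated)
}

#' Pool drug-target records across databases
#'
#' Drug identity across databases is the case-folded, whitespace-normalized
#' drug name. Each (drug, target) pair is kept once; source databases,
#' statuses, indications and actions are merged as sorted unions. Pooling a
#' pooled object is a no-op.
#'
#' @param ... any number of harmonized record data.frames and/or
#'   [PooledDrugTargets-class] objects.
#' @return a [PooledDrugTargets-class] object.
#' @export
poolDatabases <- function(...) {
    parts <- lapply(list(...), function(x) {
        if (is(x, "PooledDrugTargets")) {
            r <- drugTargetRecords(x)
            data.frame(drug_name = r$drug_name, target = r$target,
                       source_db = r$sources, status = r$statuses,
                       indications = r$indications, action = r$actions,
                       stringsAsFactors = FALSE)
        } else x
    })
    all <- do.call(rbind, parts)
    if (is.null(all) || nrow(all) == 0) {
        empty <- data.frame(drug = character(), drug_name = character(),
                            target = character(), sources = character(),
                            statuses = character(), indications = character(),
                            actions = character(), stringsAsFactors = FALSE)
        return(new("PooledDrugTargets", records = empty))
    }
    all$drug <- normalizeText(all$drug_name)
    key <- paste(all$drug, all$target, sep = "\r")
    rows <- lapply(split(all, key), function(d) {
        data.frame(drug = d$drug[1], drug_name = d$drug_name[1],
                   target = d$target[1],
                   sources = joinSemi(splitSemi(d$source_db)),
                   statuses = joinSemi(splitSemi(d$status)),
                   indications = joinSemi(splitSemi(d$indications)),
                   actions = joinSemi(splitSemi(d$action)),
                   stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rows)
    rec <- rec[order(rec$drug, rec$target), , drop = FALSE]
    rownames(rec) <- NULL
    new("PooledDrugTargets", records = rec)
}

#' Records associated with one target
#'
#' @param pooled a [PooledDrugTargets-class] object.
#' @param gene target symbol.
#' @return data.frame of the target's pooled records.
#' @export
recordsForTarget <- function(pooled, gene) {
    r <- drugTargetRecords(pooled)
    r[r$target %in% gene, , drop = FALSE]
}

#' Exclusive region counts of three sets
#'
#' @param a,b,c character vectors (converted to sets).
#' @param setNames names of the three sets.
#' @return a [VennCounts3-class] object.
#' @examples
#' v <- vennRegions(c("1", "2", "3"), c("2", "3", "4"), "3")
#' vennCounts(v)   # A=1 B=1 C=0 AB=1 AC=0 BC=0 ABC=1
#' vennUnion(v)    # 4
#' @export
vennRegions <- function(a, b, c, setNames = c("A", "B", "C")) {
    a <- unique(a); b <- unique(b); c <- unique(c)
    u <- unique(c(a, b, c))
    inA <- u %in% a; inB <- u %in% b; inC <- u %in% c
    counts <- c(A = sum(inA & !inB & !inC),
                B = sum(!inA & inB & !inC),
                C = sum(!inA & !inB & inC),
                AB = sum(inA & inB & !inC),
                AC = sum(inA & !inB & inC),
                BC = sum(!inA & inB & inC),
                ABC = sum(inA & inB & inC))
    new("VennCounts3", counts = as.numeric(counts) |>
            stats::setNames(names(counts)), setNames = setNames)
}

#' Reconstruct Venn regions from per-set totals and exclusive overlaps
#'
#' Given the three set totals, the three pairwise-exclusive overlap counts
#' (pair regions excluding the triple) and the triple count, recovers the
#' exclusive singles and the full seven-region object.
#'
#' @param totals numeric(3): |A|, |B|, |C|.
#' @param pairExclusive numeric(3): AB-only, AC-only, BC-only counts.
#' @param triple count of the triple region.
#' @param setNames names of the three sets.
#' @return a [VennCounts3-class] object.
#' @export
vennFromMargins <- function(totals, pairExclusive, triple,
                            setNames = c("A", "B", "C")) {
    stopIfNot(length(totals) == 3 && length(pairExclusive) == 3,
              "totals and pairExclusive must have length 3")
    singles <- c(totals[1] - pairExclusive[1] - pairExclusive[2] - triple,
                 totals[2] - pairExclusive[1] - pairExclusive[3] - triple,
                 totals[3] - pairExclusive[2] - pairExclusive[3] - triple)
    if (any(singles < 0))
        stop("inconsistent margins: negative exclusive single count")
    counts <- c(A = singles[1], B = singles[2], C = singles[3],
                AB = pairExclusive[1], AC = pairExclusive[2],
                BC = pairExclusive[3], ABC = triple)
    new("VennCounts3", counts = as.numeric(counts) |>
            stats::setNames(names(counts)), setNames = setNames)
}
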