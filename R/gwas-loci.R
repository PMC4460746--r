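#' Column dialect for association-result files
#'
#' Describes how to find the SNP id, chromosome, position and p-value columns
#' in a PLINK-style association table. The default matches PLINK `.assoc`
#' headers (CHR, SNP, BP, P).
#'
#' @param chrom,snp,pos,p column names in the input file.
#' @param sep field separator.
#' @return a named list usable as the `dialect` argument of
#'   [parseAssociationFile()].
#' @export
assocDialect <- function(chrom = "CHR", snp = "SNP", pos = "BP", p = "P",
                         sep = "\t") {
    list(chrom = chrom, snp = snp, pos = pos, p = p, sep = sep)
}

#' Parse a GWAS association-result file
#'
#' Reads a delimited association table and returns one record per well-formed
#' row. Rows whose p-value is missing, non-numeric, or outside (0, 1] are
#' rejected and counted; positions must be positive integers (1-based).
#'
#' @param path path to the association file.
#' @param dialect column mapping from [assocDialect()].
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `p_value`, with
#'   attribute `n_rejected` giving the number of dropped rows.
#' @export
parseAssociationFile <- function(path, dialect = assocDialect()) {
    stopIfNot(file.exists(path), "association file not found: ", path)
    raw <- tryCatch(
        read.delim(path, sep = dialect$sep, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   strip.white = TRUE),
        error = function(e) NULL)
    emptyResult <- function() {
        warning("association file is empty: ", path)
        out <- data.frame(snp_id = character(), chrom = character(),
                          pos = integer(), p_value = numeric())
        attr(out, "n_rejected") <- 0L
        out
    }
    if (is.null(raw)) return(emptyResult())
    need <- unlist(dialect[c("chrom", "snp", "pos", "p")])
    missing <- setdiff(need, names(raw))
    if (length(missing))
        stop("association file lacks mapped column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(raw) == 0) return(emptyResult())
    p <- suppressWarnings(as.numeric(raw[[dialect$p]]))
    pos <- suppressWarnings(as.integer(raw[[dialect$pos]]))
    ok <- is.finite(p) & p > 0 & p <= 1 & !is.na(pos) & pos >= 1
    out <- data.frame(snp_id = as.character(raw[[dialect$snp]][ok]),
                      chrom = as.character(raw[[dialect$chrom]][ok]),
                      pos = pos[ok], p_value = p[ok],
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out$snp_id))
        stop("duplicate snp_id in ", path)
    attr(out, "n_rejected") <- sum(!ok)
    out
}

#' Default significance thresholds
#'
#' The four nested significance strata: highly significant (HS, p <= 5e-7),
#' medium-highly significant (MHS, p <= 1e-5), medium-weakly significant
#' (MWS, p <= 1e-4) and weakly significant (WS, p <= 1e-3).
#' @return named numeric vector of thresholds.
#' @export
defaultStrataThresholds <- function() {
    c(HS = 5e-7, MHS = 1e-5, MWS = 1e-4, WS = 1e-3)
}

#' Stratify SNPs into nested significance sets
#'
#' Assigns SNPs to cumulative strata: the stratum at threshold `t` contains
#' every SNP with `p_value <= t` (the bound is inclusive), so strata are
#' nested from most to least stringent. SNPs above the widest threshold are
#' discarded.
#'
#' @param snps data.frame as returned by [parseAssociationFile()].
#' @param thresholds named, strictly increasing numeric vector.
#' @return a [SnpStrata-class] object.
#' @examples
#' snps <- data.frame(snp_id = paste0("rs", 1:5), chrom = "1",
#'                    pos = 1:5 * 1000L,
#'                    p_value = c(4e-8, 5e-6, 5e-5, 5e-4, 1e-2))
#' st <- stratifySnps(snps)
#' nrow(strataSnps(st, "MHS"))  # 2
#' @export
stratifySnps <- function(snps, thresholds = defaultStrataThresholds()) {
    stopIfNot(length(thresholds) >= 1 && !is.null(names(thresholds)),
              "thresholds must be named")
    stopIfNot(all(diff(thresholds) > 0) || length(thresholds) == 1,
              "thresholds must be strictly increasing")
    keep <- snps$p_value <= max(thresholds)
    new("SnpStrata", snps = snps[keep, , drop = FALSE],
        thresholds = thresholds)
}

#' Read a gene annotation in BED format
#'
#' Expects at least four columns (chrom, start, end, name); score and strand
#' are optional. Coordinates stay in BED convention: 0-based, half-open.
#'
#' @param path path to the BED file (plain text, no header).
#' @return data.frame with columns `symbol`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
readGeneBed <- function(path) {
    stopIfNot(file.exists(path), "BED file not found: ", path)
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    stopIfNot(ncol(raw) >= 4, "BED file needs >= 4 columns (chrom start end name)")
    out <- data.frame(symbol = as.character(raw[[4]]),
                      chrom = as.character(raw[[1]]),
                      start = as.integer(raw[[2]]),
                      end = as.integer(raw[[3]]),
                      strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else ".",
                      stringsAsFactors = FALSE)
    stopIfNot(all(out$start < out$end), "BED intervals must satisfy start < end")
    stopIfNot(!anyDuplicated(out$symbol), "gene symbols must be unique")
    out
}

#' The six default search-space construction methods
#'
#' Three fixed half-width windows (100 kb, 500 kb, 1 Mb) and three
#' k-nearest-gene rules (k = 1, 3, 5). Each entry has `type` ("fixed" or
#' "nearest") and the corresponding `width` (half-width, bp) or `k`.
#'
#' @return named list of method descriptors.
#' @export
searchSpaceMethods <- function() {
    list(fixed_100kb = list(type = "fixed", width = 1e5),
         fixed_500kb = list(type = "fixed", width = 5e5),
         fixed_1mb   = list(type = "fixed", width = 1e6),
         nearest_1   = list(type = "nearest", k = 1L),
         nearest_3   = list(type = "nearest", k = 3L),
         nearest_5   = list(type = "nearest", k = 5L))
}

# genes (BED, 0-based half-open) -> GRanges (1-based closed)
genesAsGRanges <- function(genes) {
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(start = genes$start + 1L,
                                            end = genes$end))
}

#' Construct a SearchSpace from explicit assignments
#'
#' Low-level constructor; most users should call [buildSearchSpace()].
#'
#' @param stratum stratum label.
#' @param method method name.
#' @param assignments data.frame with columns `locus_id`, `snp_id`, `chrom`,
#'   `pos`, `gene` (NA gene marks an empty locus).
#' @param params optional parameter list.
#' @return a [SearchSpace-class] object.
#' @export
searchSpace <- function(stratum, method, assignments, params = list()) {
    new("SearchSpace", stratum = stratum, method = method, params = params,
        assignments = assignments)
}

#' Build one gene search space around the SNPs of a stratum
#'
#' Every SNP anchors one locus. For fixed-width methods a gene enters the
#' locus iff its interval (0-based half-open) intersects
#' `[pos - width, pos + width)` around the 0-based SNP position. For
#' proximity methods the `k` genes on the SNP's chromosome with the smallest
#' base-pair distance to the gene interval are taken (distance 0 when the SNP
#' lies inside the gene); ties are broken by lexicographic symbol order.
#' SNPs on chromosomes without annotated genes yield loci with empty gene
#' sets.
#'
#' @param snps data.frame of the stratum's SNPs (`snp_id`, `chrom`, `pos`,
#'   `p_value`), e.g. from [strataSnps()].
#' @param genes gene annotation data.frame from [readGeneBed()].
#' @param method a method name from [searchSpaceMethods()], or "fixed" /
#'   "nearest" with an explicit `width` / `k`.
#' @param stratum stratum label recorded on the space.
#' @param width half-width in bp (fixed methods).
#' @param k number of nearest genes (proximity methods).
#' @return a [SearchSpace-class] object.
#' @export
buildSearchSpace <- function(snps, genes, method = "fixed_500kb",
                             stratum = "WS", width = NULL, k = NULL) {
    registry <- searchSpaceMethods()
    if (method %in% names(registry)) {
        par <- registry[[method]]
        if (!is.null(width)) par$width <- width
        if (!is.null(k)) par$k <- k
    } else if (method %in% c("fixed", "nearest")) {
        par <- list(type = method, width = width, k = k)
    } else {
        stop("unknown search-space method: ", method)
    }
    if (par$type == "fixed")
        stopIfNot(is.numeric(par$width) && par$width > 0, "width must be > 0")
    else
        stopIfNot(is.numeric(par$k) && par$k >= 1, "k must be >= 1")

    rows <- vector("list", nrow(snps))
    if (nrow(snps) > 0 && nrow(genes) > 0 && par$type == "fixed") {
        # window [pos0 - w, pos0 + w) in 0-based coords -> 1-based closed
        w <- par$width
        winGR <- GenomicRanges::GRanges(snps$chrom,
                    IRanges::IRanges(start = pmax(1L, snps$pos - w),
                                     end = snps$pos + w - 1L))
        # disjoint seqlevels (SNP on a gene-free chromosome) are a valid
        # empty-locus case, not a user warning
        hits <- suppressWarnings(
            GenomicRanges::findOverlaps(winGR, genesAsGRanges(genes)))
        hitQ <- S4Vectors::queryHits(hits)
        hitS <- S4Vectors::subjectHits(hits)
        for (i in seq_len(nrow(snps))) {
            gs <- sort(genes$symbol[hitS[hitQ == i]])
            rows[[i]] <- data.frame(
                locus_id = paste0("L_", snps$snp_id[i]),
                snp_id = snps$snp_id[i], chrom = snps$chrom[i],
                pos = snps$pos[i],
                gene = if (length(gs)) gs else NA_character_,
                stringsAsFactors = FALSE)
        }
    } else if (nrow(snps) > 0 && par$type == "nearest") {
        byChrom <- split(seq_len(nrow(genes)), genes$chrom)
        for (i in seq_len(nrow(snps))) {
            idx <- byChrom[[snps$chrom[i]]]
            gs <- character()
            if (length(idx)) {
                # gene 1-based closed [start+1, end]; point distance to interval
                d <- pmax(0L, genes$start[idx] + 1L - snps$pos[i],
                          snps$pos[i] - genes$end[idx])
                ord <- order(d, genes$symbol[idx])
                take <- head(ord, par$k)
                gs <- genes$symbol[idx][take]
            }
            rows[[i]] <- data.frame(
                locus_id = paste0("L_", snps$snp_id[i]),
                snp_id = snps$snp_id[i], chrom = snps$chrom[i],
                pos = snps$pos[i],
                gene = if (length(gs)) gs else NA_character_,
                stringsAsFactors = FALSE)
        }
    } else {
        for (i in seq_len(nrow(snps)))
            rows[[i]] <- data.frame(
                locus_id = paste0("L_", snps$snp_id[i]),
                snp_id = snps$snp_id[i], chrom = snps$chrom[i],
                pos = snps$pos[i], gene = NA_character_,
                stringsAsFactors = FALSE)
    }
    assignments <- if (length(rows)) do.call(rbind, rows) else
        data.frame(locus_id = character(), snp_id = character(),
                   chrom = character(), pos = integer(),
                   gene = character(), stringsAsFactors = FALSE)
    rownames(assignments) <- NULL
    searchSpace(stratum = stratum, method = method,
                assignments = assignments, params = par)
}

#' Build all search spaces of a stratified SNP set
#'
#' Applies every construction method to every stratum; with the default four
#' strata and six methods this yields the full grid of 24 search spaces.
#'
#' @param strata a [SnpStrata-class] object.
#' @param genes gene annotation from [readGeneBed()].
#' @param methods named list of method descriptors, default
#'   [searchSpaceMethods()].
#' @return named list of [SearchSpace-class] objects, names
#'   `"<stratum>.<method>"`.
#' @export
buildAllSearchSpaces <- function(strata, genes,
                                 methods = searchSpaceMethods()) {
    out <- list()
    for (lab in strataLabels(strata)) {
        snps <- strataSnps(strata, lab)
        for (m in names(methods)) {
            par <- methods[[m]]
            out[[paste(lab, m, sep = ".")]] <-
                buildSearchSpace(snps, genes, method = m, stratum = lab,
                                 width = par$width, k = par$k)
        }
    }
    out
}

#' Gene universe of the six search spaces of one stratum
#'
#' The union of gene symbols across the spaces; used as the benchmark
#' universe. All spaces must come from the same stratum.
#'
#' @param spaces list of [SearchSpace-class] objects.
#' @return sorted character vector of gene symbols.
#' @export
searchSpaceGeneUniverse <- function(spaces) {
    stopIfNot(length(spaces) >= 1, "need at least one search space")
    labs <- unique(vapply(spaces, stratumLabel, character(1)))
    if (length(labs) != 1L)
        stop("search spaces come from mixed strata: ",
             paste(labs, collapse = ", "))
    sort(unique(unlist(lapply(spaces, spaceGenes), use.names = FALSE)))
}

#' Write search spaces to a TSV file
#'
#' One row per (stratum, method, locus, gene).
#'
#' @param spaces list of [SearchSpace-class] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSearchSpaces <- function(spaces, path) {
    tabs <- lapply(spaces, function(sp) {
        a <- spaceAssignments(sp)
        if (nrow(a) == 0) return(NULL)
        cbind(stratum = stratumLabel(sp), method = methodName(sp), a)
    })
    writeTsv(do.call(rbind, tabs), path)
}
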