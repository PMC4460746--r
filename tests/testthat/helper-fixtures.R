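# small in-code fixtures shared across test files

tinyGenes <- function() {
    data.frame(
        symbol = c("ABC", "DEF", "GHI", "JKL", "XYZ"),
        chrom  = c("chr1", "chr1", "chr1", "chr2", "chr1"),
        start  = c(1400000L, 1600000L, 100000L, 5000L, 600000L),
        end    = c(1450000L, 1700000L, 150000L, 9000L, 650000L),
        strand = c("+", "-", "+", "+", "-"),
        stringsAsFactors = FALSE)
}

# a two-locus search space with explicit gene placement
twoLocusSpace <- function(l1 = c("a1", "a2"), l2 = c("b1", "b2"),
                          stratum = "WS", method = "fixed_500kb") {
    assignments <- data.frame(
        locus_id = c(rep("L1", length(l1)), rep("L2", length(l2))),
        snp_id = c(rep("rs1", length(l1)), rep("rs2", length(l2))),
        chrom = "chr1",
        pos = c(rep(1000L, length(l1)), rep(900000L, length(l2))),
        gene = c(l1, l2), stringsAsFactors = FALSE)
    searchSpace(stratum, method, assignments)
}

# random search space over nLoci loci and a gene alphabet; genes can recur
# across loci
randomSpace <- function(nLoci, genes, maxPerLocus = 4) {
    rows <- lapply(seq_len(nLoci), function(i) {
        g <- sample(genes, sample.int(maxPerLocus, 1))
        data.frame(locus_id = paste0("L", i), snp_id = paste0("rs", i),
                   chrom = "chr1", pos = i * 1000L, gene = unique(g),
                   stringsAsFactors = FALSE)
    })
    searchSpace("WS", "fixed_500kb", do.call(rbind, rows))
}

# brute-force oracle for the shared-group modules (CPS/CRT and MIR clause a):
# gene g in locus L is hit iff some group holds g and a different gene in a
# different locus
oracleSharedGroup <- function(space, groups) {
    m <- unique(spaceAssignments(space)[, c("gene", "locus_id")])
    m <- m[!is.na(m$gene), ]
    hits <- character()
    for (i in seq_len(nrow(m))) {
        g <- m$gene[i]; l <- m$locus_id[i]
        for (grp in unique(groups$subject)) {
            members <- groups$object[groups$subject == grp]
            if (!g %in% members) next
            for (j in seq_len(nrow(m))) {
                if (m$gene[j] != g && m$locus_id[j] != l &&
                    m$gene[j] %in% members) {
                    hits <- c(hits, paste(g, l))
                }
            }
        }
    }
    unique(hits)
}

# brute-force oracle for PPI: direct edge to a different gene in another locus
oraclePpi <- function(space, edges) {
    m <- unique(spaceAssignments(space)[, c("gene", "locus_id")])
    m <- m[!is.na(m$gene), ]
    hits <- character()
    for (i in seq_len(nrow(m))) {
        g <- m$gene[i]; l <- m$locus_id[i]
        for (e in seq_len(nrow(edges))) {
            pair <- c(edges$subject[e], edges$object[e])
            if (!g %in% pair) next
            partner <- setdiff(pair, g)
            if (length(partner) != 1) next  # self-edge
            ok <- any(m$gene == partner & m$locus_id != l)
            if (ok) hits <- c(hits, paste(g, l))
        }
    }
    unique(hits)
}

predHitKeys <- function(pred) unique(paste(pred$gene, pred$locus_id))

# brute-force contingency classification by per-gene enumeration
oracleContingency <- function(universe, predicted, known) {
    tp <- fp <- fn <- tn <- 0L
    for (g in unique(universe)) {
        p <- g %in% predicted; k <- g %in% known
        if (p && k) tp <- tp + 1L
        else if (p) fp <- fp + 1L
        else if (k) fn <- fn + 1L
        else tn <- tn + 1L
    }
    c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# small pooled drug-target object built from raw record rows
makePooled <- function(...) {
    rows <- list(...)
    df <- do.call(rbind, lapply(rows, function(r)
        data.frame(drug_name = r[[1]], target = r[[2]],
                   source_db = if (length(r) > 2) r[[3]] else "DrugBank",
                   status = if (length(r) > 3) r[[4]] else "approved",
                   indications = if (length(r) > 4) r[[5]] else "",
                   action = "", stringsAsFactors = FALSE)))
    poolDatabases(df)
}
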