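test_that("association parsing maps PLINK-style columns and rejects bad rows", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("CHR\tSNP\tBP\tP",
                 "1\trs1\t1000\t0.5",
                 "1\trs2\t2000\t1e-6",
                 "2\trs3\t3000\t0.01"), f)
    snps <- parseAssociationFile(f)
    expect_equal(nrow(snps), 3)
    expect_equal(snps$snp_id, c("rs1", "rs2", "rs3"))
    expect_equal(snps$pos, c(1000L, 2000L, 3000L))
    expect_equal(attr(snps, "n_rejected"), 0L)

    writeLines(c("CHR\tSNP\tBP\tP",
                 "1\trs1\t1000\tNA",
                 "1\trs2\t2000\t0.2"), f)
    snps <- parseAssociationFile(f)
    expect_equal(nrow(snps), 1)
    expect_equal(attr(snps, "n_rejected"), 1L)

    # round trip: write records back out in PLINK layout and reparse
    orig <- data.frame(snp_id = paste0("rs", 1:4), chrom = c("1", "2", "2", "X"),
                       pos = c(10L, 20L, 30L, 40L),
                       p_value = c(0.5, 1e-6, 0.9, 1e-3))
    write.table(data.frame(CHR = orig$chrom, SNP = orig$snp_id,
                           BP = orig$pos, P = orig$p_value),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    back <- parseAssociationFile(f)
    expect_equal(back$snp_id, orig$snp_id)
    expect_equal(back$chrom, orig$chrom)
    expect_equal(back$pos, orig$pos)
    expect_equal(back$p_value, orig$p_value)

    writeLines("CHR\tSNP\tBP", f)
    expect_error(parseAssociationFile(f), "lacks mapped column")
})

test_that("stratification is cumulative with inclusive bounds", {
    snps <- data.frame(snp_id = paste0("rs", 1:5), chrom = "1",
                       pos = 1:5 * 1000L,
                       p_value = c(4e-8, 5e-6, 5e-5, 5e-4, 1e-2))
    st <- stratifySnps(snps)
    sizes <- vapply(strataLabels(st), function(l) nrow(strataSnps(st, l)),
                    integer(1))
    expect_equal(unname(sizes), c(1L, 2L, 3L, 4L))

    # boundary p exactly 5e-7 belongs to the most stringent set
    boundary <- data.frame(snp_id = "rsB", chrom = "1", pos = 1L,
                           p_value = 5e-7)
    expect_equal(nrow(strataSnps(stratifySnps(boundary), "HS")), 1)

    empty <- snps[0, ]
    stE <- stratifySnps(empty)
    expect_true(all(vapply(strataLabels(stE), function(l)
        nrow(strataSnps(stE, l)) == 0, logical(1))))

    expect_error(stratifySnps(snps, c(A = 1e-3, B = 1e-5)),
                 "strictly increasing")
})

test_that("fixed-width inclusion follows the half-open window rule", {
    snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 1000000L,
                       p_value = 1e-4)
    sp <- buildSearchSpace(snps, tinyGenes(), method = "fixed",
                           width = 5e5, stratum = "WS")
    g <- spaceGenes(sp)
    expect_true("ABC" %in% g)    # [1.40, 1.45) Mb intersects window
    expect_false("DEF" %in% g)   # [1.60, 1.70) Mb beyond pos + w
    expect_true("XYZ" %in% g)

    # SNP on a chromosome with no annotated genes keeps an empty locus
    lonely <- data.frame(snp_id = "rs9", chrom = "chr9", pos = 500L,
                         p_value = 1e-4)
    spE <- buildSearchSpace(lonely, tinyGenes(), method = "fixed_100kb")
    expect_equal(spaceLoci(spE), "L_rs9")
    expect_length(spaceGenes(spE), 0)

    expect_error(buildSearchSpace(snps, tinyGenes(), method = "bogus"),
                 "unknown search-space method")
})

test_that("fixed-width assignment agrees with brute-force interval overlap", {
    set.seed(71)
    for (trial in 1:20) {
        nG <- sample(100, 1); nS <- sample(20, 1)
        start <- sample.int(2e6, nG)
        genes <- data.frame(symbol = sprintf("g%03d", seq_len(nG)),
                            chrom = sample(c("c1", "c2"), nG, replace = TRUE),
                            start = start, end = start + sample.int(5e4, nG),
                            strand = "+")
        snps <- data.frame(snp_id = sprintf("rs%02d", seq_len(nS)),
                           chrom = sample(c("c1", "c2"), nS, replace = TRUE),
                           pos = sample.int(2e6, nS), p_value = 1e-4)
        w <- sample(c(1e4, 1e5, 5e5), 1)
        sp <- buildSearchSpace(snps, genes, method = "fixed", width = w)
        a <- spaceAssignments(sp)
        for (i in seq_len(nS)) {
            # brute force over all genes: 0-based [pos-1-w, pos-1+w) window
            lo <- snps$pos[i] - 1 - w; hi <- snps$pos[i] - 1 + w
            expected <- sort(genes$symbol[genes$chrom == snps$chrom[i] &
                                          genes$start < hi & genes$end > lo])
            got <- a$gene[a$snp_id == snps$snp_id[i]]
            got <- sort(got[!is.na(got)])
            expect_equal(got, expected)
        }
    }
})

test_that("nearest-k picks minimal-distance genes with lexicographic ties", {
    # two genes equidistant from the SNP: symbol order decides
    genes <- data.frame(symbol = c("XYZ", "ABC"), chrom = "chr1",
                        start = c(2000L, 5999L), end = c(3000L, 7000L),
                        strand = "+")
    snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 4500L,
                       p_value = 1e-4)   # 1500 bp from both intervals
    sp1 <- buildSearchSpace(snps, genes, method = "nearest", k = 1)
    expect_equal(spaceGenes(sp1), "ABC")

    # SNP inside a gene has distance zero to it
    inside <- data.frame(snp_id = "rs2", chrom = "chr1", pos = 2500L,
                         p_value = 1e-4)
    expect_equal(spaceGenes(buildSearchSpace(inside, genes,
                                             method = "nearest_1")), "XYZ")
})

test_that("search spaces grow monotonically in width and k", {
    set.seed(72)
    nG <- 60
    start <- sample.int(3e6, nG)
    genes <- data.frame(symbol = sprintf("g%02d", seq_len(nG)), chrom = "c1",
                        start = start, end = start + 2e4, strand = "+")
    snps <- data.frame(snp_id = paste0("rs", 1:8), chrom = "c1",
                       pos = sample.int(3e6, 8), p_value = 1e-4)
    widths <- c(5e4, 2e5, 1e6)
    ks <- c(1, 3, 5)
    for (i in seq_len(2)) {
        spW1 <- buildSearchSpace(snps, genes, "fixed", width = widths[i])
        spW2 <- buildSearchSpace(snps, genes, "fixed", width = widths[i + 1])
        spK1 <- buildSearchSpace(snps, genes, "nearest", k = ks[i])
        spK2 <- buildSearchSpace(snps, genes, "nearest", k = ks[i + 1])
        for (l in spaceLoci(spW1)) {
            a1 <- spaceAssignments(spW1); a2 <- spaceAssignments(spW2)
            expect_true(all(stats::na.omit(a1$gene[a1$locus_id == l]) %in%
                            a2$gene[a2$locus_id == l]))
            k1 <- spaceAssignments(spK1); k2 <- spaceAssignments(spK2)
            expect_true(all(stats::na.omit(k1$gene[k1$locus_id == l]) %in%
                            k2$gene[k2$locus_id == l]))
        }
    }
})

test_that("search-space construction is deterministic", {
    snps <- data.frame(snp_id = paste0("rs", 1:3), chrom = "chr1",
                       pos = c(1e5, 5e5, 1.2e6), p_value = 1e-4)
    s1 <- buildSearchSpace(snps, tinyGenes(), "fixed_500kb")
    s2 <- buildSearchSpace(snps, tinyGenes(), "fixed_500kb")
    expect_identical(spaceAssignments(s1), spaceAssignments(s2))
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeSearchSpaces(list(s1), f1); writeSearchSpaces(list(s2), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("gene universe is the union over same-stratum spaces", {
    mk <- function(genes) {
        searchSpace("WS", "m", data.frame(
            locus_id = "L1", snp_id = "rs1", chrom = "c", pos = 1L,
            gene = if (length(genes)) genes else NA_character_))
    }
    spaces <- lapply(list(c("a", "b"), c("b", "c"), character(), "d", "a",
                          "c"), mk)
    expect_equal(searchSpaceGeneUniverse(spaces), c("a", "b", "c", "d"))
    expect_equal(searchSpaceGeneUniverse(lapply(rep(list("z"), 6), mk)), "z")
    expect_length(searchSpaceGeneUniverse(lapply(rep(list(character()), 6),
                                                 mk)), 0)
    mixed <- c(lapply(list(c("a")), mk),
               list(searchSpace("HS", "m", data.frame(
                   locus_id = "L1", snp_id = "rs1", chrom = "c", pos = 1L,
                   gene = "a"))))
    expect_error(searchSpaceGeneUniverse(mixed), "mixed strata")
})

test_that("the default grid yields 24 spaces and BED parsing keeps 0-based coords", {
    f <- withr::local_tempfile(fileext = ".bed")
    g <- tinyGenes()
    write.table(data.frame(g$chrom, g$start, g$end, g$symbol, 0L, g$strand),
                f, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    genes <- readGeneBed(f)
    expect_equal(genes$start, g$start)
    expect_equal(genes$symbol, g$symbol)
    snps <- data.frame(snp_id = paste0("rs", 1:4), chrom = "chr1",
                       pos = c(1e5, 5e5, 1e6, 1.5e6),
                       p_value = c(4e-8, 5e-6, 5e-5, 5e-4))
    grid <- buildAllSearchSpaces(stratifySnps(snps), genes)
    expect_length(grid, 24)
    expect_equal(sum(grepl("^WS\\.", names(grid))), 6)
})
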