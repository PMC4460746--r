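test_that("genome generation packs the requested genes deterministically", {
    g <- generateGenome(nChrom = 2, nGenes = 100, meanGeneLen = 1e4,
                        meanGap = 5e4, seed = 7)
    expect_equal(nrow(g), 100)
    expect_length(unique(g$chrom), 2)
    expect_true(all(g$start < g$end))
    # non-overlapping within each chromosome
    for (d in split(g, g$chrom)) {
        d <- d[order(d$start), ]
        expect_true(all(head(d$end, -1) <= d$start[-1]))
    }
    expect_identical(g, generateGenome(2, 100, 1e4, 5e4, seed = 7))
    expect_false(identical(g, generateGenome(2, 100, 1e4, 5e4, seed = 8)))
    expect_equal(nrow(generateGenome(2, 0, 1e4, 5e4, seed = 7)), 0)
})

test_that("planted SNPs recover their strata exactly", {
    genome <- generateGenome(2, 200, 1e4, 5e4, seed = 1)
    gw <- generateGwas(genome, strataMix = c(HS = 1L, MHS = 1L, MWS = 1L,
                                             WS = 1L),
                       nNullSnps = 50, seed = 2)
    st <- stratifySnps(gw$snps)
    sizes <- vapply(strataLabels(st), function(l) nrow(strataSnps(st, l)),
                    integer(1))
    expect_equal(unname(sizes), c(1L, 2L, 3L, 4L))
    # every planted SNP obeys its stratum bound, disjoint intervals
    iv <- list(HS = c(0, 5e-7), MHS = c(5e-7, 1e-5), MWS = c(1e-5, 1e-4),
               WS = c(1e-4, 1e-3))
    m <- merge(gw$manifest, gw$snps, by = "snp_id")
    for (i in seq_len(nrow(m))) {
        b <- iv[[m$stratum[i]]]
        expect_gt(m$p_value[i], b[1])
        expect_lte(m$p_value[i], b[2])
    }
    # no planted loci: the widest stratum is empty
    gw0 <- generateGwas(genome, strataMix = c(WS = 0L), nNullSnps = 30,
                        seed = 3)
    expect_equal(nrow(stratifySnps(gw0$snps)@snps), 0)
    expect_error(generateGwas(genome[1:3, ],
                              strataMix = c(WS = 10L), seed = 1),
                 "more planted loci")
})

test_that("annotation wiring makes every planted gene recoverable", {
    genome <- generateGenome(2, 300, 1e4, 1e5, seed = 11)
    gw <- generateGwas(genome, strataMix = c(HS = 2L, MHS = 3L, MWS = 3L,
                                             WS = 4L),
                       nNullSnps = 0, seed = 12)
    planted <- gw$manifest$gene
    ann <- generateAnnotations(genome, planted, decoyDensity = 0,
                               hubK = 5, seed = 13)
    spaces <- buildAllSearchSpaces(stratifySnps(gw$snps), genome)
    ws <- spaces[grep("^WS\\.", names(spaces))]
    got <- predictCandidates(ws, ann$tables, ann$seedGenes, tau = 0.5,
                             hubK = 5)
    # with no decoys the predictions are exactly the designated subsets
    expect_setequal(got$gene, unique(unlist(ann$moduleGenes)))
    perModule <- do.call(rbind, lapply(ws, function(sp) rbind(
        predictCps(sp, ann$tables$pathway),
        predictPpi(sp, ann$tables$interaction),
        predictCmp(sp, ann$tables$domain, ann$seedGenes, 0.5),
        predictCrt(sp, ann$tables$tf_target),
        predictMir(sp, ann$tables$mirna_target, 5))))
    for (m in names(ann$moduleGenes))
        expect_setequal(unique(perModule$gene[perModule$module == m]),
                        ann$moduleGenes[[m]])

    # decoys are strictly additive: doubling the density loses nothing
    annD <- generateAnnotations(genome, planted, decoyDensity = 0.1,
                                hubK = 5, seed = 13)
    gotD <- predictCandidates(ws, annD$tables, annD$seedGenes, tau = 0.5,
                              hubK = 5)
    expect_true(all(got$gene %in% gotD$gene))

    # no planted genes: all modules return empty
    ann0 <- generateAnnotations(genome, character(), decoyDensity = 0,
                                hubK = 5, seed = 13)
    got0 <- predictCandidates(ws, ann0$tables, ann0$seedGenes)
    expect_equal(nrow(got0), 0)
})

test_that("drug-database generation honors the overlap profile and fractions", {
    genome <- generateGenome(2, 500, 1e4, 1e5, seed = 21)
    gw <- generateGwas(genome, strataMix = c(WS = 10L), nNullSnps = 0,
                       seed = 22)
    snpPos <- merge(gw$manifest, gw$snps, by = "snp_id")[, c("chrom", "pos")]
    dd <- generateDrugDatabases(genome, gw$manifest$gene, snpPos,
                                targetFraction = 0.08, seed = 23)
    m <- dd$manifest
    expect_equal(length(m$targets), round(0.08 * 500))
    # realized region counts are reproduced exactly by the generated sets
    v <- vennRegions(m$db_targets$A, m$db_targets$B, m$db_targets$C)
    expect_equal(as.list(vennCounts(v)), lapply(m$region_counts, as.numeric))
    # planted split is a partition
    expect_length(intersect(m$planted_known_targets,
                            m$planted_novel_targets), 0)
    expect_setequal(c(m$planted_known_targets, m$planted_novel_targets),
                    m$planted_targets)
    # known and novel drug keys never overlap
    expect_length(intersect(m$known_drugs, m$novel_drugs), 0)

    # no known targets: everything downstream is novel
    dd0 <- generateDrugDatabases(genome, gw$manifest$gene, snpPos,
                                 nKnownTargets = 0L, seed = 24)
    expect_length(dd0$manifest$known_drugs, 0)
    expect_equal(noveltyRatio(length(dd0$manifest$planted_novel_targets),
                              length(dd0$manifest$planted_targets)), 1.0)

    # exact integer profiles must sum to the target total
    expect_error(generateDrugDatabases(genome, gw$manifest$gene, snpPos,
        vennProfile = c(A = 5, B = 5, C = 5, AB = 0, AC = 0, BC = 0,
                        ABC = 0), seed = 25), "inconsistent")
})

test_that("generated exports survive parsing, mapping and pooling", {
    genome <- generateGenome(2, 400, 1e4, 1e5, seed = 31)
    gw <- generateGwas(genome, strataMix = c(WS = 8L), nNullSnps = 0,
                       seed = 32)
    snpPos <- merge(gw$manifest, gw$snps, by = "snp_id")[, c("chrom", "pos")]
    dd <- generateDrugDatabases(genome, gw$manifest$gene, snpPos, seed = 33)
    d <- withr::local_tempdir()
    write.table(dd$exports$drugbank, file.path(d, "db.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write.table(dd$exports$ttd, file.path(d, "ttd.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(dd$exports$pharmgkb, file.path(d, "pgkb.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rec <- list(
        mapToHugo(parseDrugExport(file.path(d, "db.csv"),
                                  dialectDrugBank(), "DrugBank"),
                  dd$idMap)$records,
        mapToHugo(parseDrugExport(file.path(d, "ttd.tsv"),
                                  dialectTTD(), "TTD"), dd$idMap)$records,
        mapToHugo(parseDrugExport(file.path(d, "pgkb.tsv"),
                                  dialectPharmGKB(), "PharmGKB"),
                  dd$idMap)$records)
    pooled <- do.call(poolDatabases, rec)
    # harmonized targets per database reproduce the planted sets
    expect_setequal(unique(rec[[1]]$target), dd$manifest$db_targets$A)
    expect_setequal(unique(rec[[2]]$target), dd$manifest$db_targets$B)
    expect_setequal(unique(rec[[3]]$target), dd$manifest$db_targets$C)
    expect_setequal(uniqueTargets(pooled), dd$manifest$targets)
})

test_that("citation counts separate planted targets when rates differ", {
    genes <- sprintf("g%03d", 1:200)
    hot <- genes[1:15]
    cites <- generateCitations(genes, hot, highRate = 20, lowRate = 0.1,
                               seed = 41)
    expect_identical(cites, generateCitations(genes, hot, 20, 0.1, seed = 41))
    bm <- citationBenchmark(hot, genes, cites)
    expect_gte(rocAuc(bm$roc), 0.9)
    # equal rates carry no signal
    flat <- generateCitations(genes, hot, highRate = 2, lowRate = 2,
                              seed = 42)
    bmF <- suppressWarnings(citationBenchmark(hot, genes, flat))
    expect_lt(abs(rocAuc(bmF$roc) - 0.5), 0.2)
})

test_that("bundle simulation is reproducible file by file", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    p <- syntheticParams(n_genes = 300L, n_null_snps = 40L,
                         strata_mix = c(HS = 1L, MHS = 2L, MWS = 2L,
                                        WS = 3L),
                         n_known_targets = 2L,
                         n_offspace_known_targets = 1L)
    simulateBundle(d1, p, seed = 5)
    simulateBundle(d2, p, seed = 5)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f), warn = FALSE),
                         readLines(file.path(d2, f), warn = FALSE),
                         info = f)
    }
    expect_error(syntheticParams(bogus_key = 1), "unknown synthetic")
})
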