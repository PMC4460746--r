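test_that("CPS requires pathway sharing across distinct loci", {
    sp <- twoLocusSpace(l1 = c("geneA", "geneC", "geneD"), l2 = "geneB")
    pw <- annotationTable("pathway", c("P1", "P1"), c("geneA", "geneB"))
    pred <- predictCps(sp, pw)
    expect_setequal(pred$gene, c("geneA", "geneB"))

    # all genes of a single locus share a pathway: nothing predicted
    single <- searchSpace("WS", "m", data.frame(
        locus_id = "L1", snp_id = "rs1", chrom = "c", pos = 1L,
        gene = c("geneA", "geneB", "geneC")))
    pwAll <- annotationTable("pathway", rep("P1", 3),
                             c("geneA", "geneB", "geneC"))
    expect_equal(nrow(predictCps(single, pwAll)), 0)

    # pathway containing only L1 genes never predicts an L1 gene
    pwL1 <- annotationTable("pathway", c("P2", "P2"), c("geneC", "geneD"))
    expect_equal(nrow(predictCps(sp, pwL1)), 0)

    expect_equal(nrow(predictCps(sp, annotationTable("pathway",
        character(), character()))), 0)
})

test_that("PPI predicts both partners of a cross-locus edge only", {
    sp <- twoLocusSpace(l1 = c("a", "c"), l2 = c("b"))
    cross <- annotationTable("interaction", "a", "b")
    expect_setequal(predictPpi(sp, cross)$gene, c("a", "b"))
    # symmetric: reversed edge gives the same result
    expect_setequal(predictPpi(sp, annotationTable("interaction", "b",
                                                   "a"))$gene, c("a", "b"))
    within <- annotationTable("interaction", "a", "c")
    expect_equal(nrow(predictPpi(sp, within)), 0)
    selfEdge <- annotationTable("interaction", "a", "a")
    expect_equal(nrow(predictPpi(sp, selfEdge)), 0)
})

test_that("CMP applies the Jaccard threshold against seed domain profiles", {
    sp <- twoLocusSpace(l1 = "g", l2 = "other")
    dom <- function(...) {
        pairs <- list(...)
        annotationTable("domain",
                        unlist(lapply(pairs, `[[`, 1)),
                        unlist(lapply(pairs, `[[`, 2)))
    }
    # identical profiles: Jaccard 1
    d1 <- dom(list("g", "D1"), list("g", "D2"), list("s", "D1"),
              list("s", "D2"))
    expect_equal(predictCmp(sp, d1, "s", tau = 0.5)$gene, "g")
    # disjoint profiles: Jaccard 0
    d2 <- dom(list("g", "D1"), list("s", "D2"), list("s", "D3"))
    expect_equal(nrow(predictCmp(sp, d2, "s", tau = 0.5)), 0)
    # 1/5 overlap below tau = 0.5
    d3 <- dom(list("g", "D1"), list("g", "D2"), list("g", "D3"),
              list("g", "D4"), list("g", "D5"), list("s", "D1"))
    expect_equal(nrow(predictCmp(sp, d3, "s", tau = 0.5)), 0)
    expect_equal(predictCmp(sp, d3, "s", tau = 0.2)$gene, "g")
    # empty seed set is an empty result, not an error
    expect_equal(nrow(predictCmp(sp, d1, character(), tau = 0.5)), 0)
    # seeds without domain records never match
    expect_equal(nrow(predictCmp(sp, d1, "unseen", tau = 0.5)), 0)
})

test_that("CRT requires a TF targeting distinct loci", {
    sp <- twoLocusSpace(l1 = c("a", "c"), l2 = "b")
    both <- annotationTable("tf_target", c("t", "t"), c("a", "b"))
    expect_setequal(predictCrt(sp, both)$gene, c("a", "b"))
    same <- annotationTable("tf_target", c("t", "t"), c("a", "c"))
    expect_equal(nrow(predictCrt(sp, same)), 0)
    expect_equal(nrow(predictCrt(sp, annotationTable("tf_target",
        character(), character()))), 0)
})

test_that("MIR requires both cross-locus sharing and hub membership", {
    sp <- twoLocusSpace(l1 = "g", l2 = "h")
    mirs <- function(n, shared = TRUE) {
        subj <- c(paste0("m", seq_len(n)), if (shared) "m1")
        obj <- c(rep("g", n), if (shared) "h")
        annotationTable("mirna_target", subj, obj)
    }
    # 6 targeting miRNAs, one shared cross-locus, hub threshold 5
    expect_true("g" %in% predictMir(sp, mirs(6), hubK = 5)$gene)
    # only 2 targeting miRNAs: hub clause fails
    expect_false("g" %in% predictMir(sp, mirs(2), hubK = 5)$gene)
    # no cross-locus sharing: clause (a) fails even at hubK = 1
    expect_equal(nrow(predictMir(sp, mirs(6, shared = FALSE), hubK = 1)), 0)
})

test_that("each predictor agrees with an exhaustive brute-force oracle", {
    set.seed(301)
    genes <- sprintf("g%02d", 1:12)
    for (trial in 1:40) {
        sp <- randomSpace(nLoci = sample(2:5, 1), genes = genes)
        n <- sample(20, 1)
        groups <- annotationTable("pathway",
                                  sample(paste0("P", 1:4), n, replace = TRUE),
                                  sample(genes, n, replace = TRUE))
        expect_setequal(predHitKeys(predictCps(sp, groups)),
                        oracleSharedGroup(sp, groups))
        expect_setequal(predHitKeys(predictCrt(sp, groups)),
                        oracleSharedGroup(sp, groups))
        edges <- annotationTable("interaction",
                                 sample(genes, n, replace = TRUE),
                                 sample(genes, n, replace = TRUE))
        expect_setequal(predHitKeys(predictPpi(sp, edges)),
                        oraclePpi(sp, edges))
        # MIR at hubK = 1 reduces to the shared-group rule
        mir <- annotationTable("mirna_target",
                               sample(paste0("m", 1:5), n, replace = TRUE),
                               sample(genes, n, replace = TRUE))
        expect_setequal(predHitKeys(predictMir(sp, mir, hubK = 1)),
                        oracleSharedGroup(sp, mir))
    }
})

test_that("predictions never leave the search space and respect monotonicity", {
    set.seed(302)
    genes <- sprintf("g%02d", 1:10)
    for (trial in 1:20) {
        sp <- randomSpace(nLoci = 3, genes = genes)
        n <- 10
        base <- annotationTable("pathway",
                                sample(paste0("P", 1:3), n, replace = TRUE),
                                sample(genes, n, replace = TRUE))
        more <- annotationTable("pathway",
                                c(base$subject, "P9", "P9"),
                                c(base$object, sample(genes, 2)))
        p1 <- predictCps(sp, base); p2 <- predictCps(sp, more)
        expect_true(all(p1$gene %in% spaceGenes(sp)))
        # adding annotation never removes a prediction
        expect_true(all(predHitKeys(p1) %in% predHitKeys(p2)))
        # raising tau never adds a CMP prediction
        dom <- annotationTable("domain",
                               sample(genes, 12, replace = TRUE),
                               sample(paste0("D", 1:4), 12, replace = TRUE))
        seeds <- sample(genes, 2)
        lo <- predictCmp(sp, dom, seeds, tau = 0.3)
        hi <- predictCmp(sp, dom, seeds, tau = 0.7)
        expect_true(all(predHitKeys(hi) %in% predHitKeys(lo)))
        # raising hubK never adds an MIR prediction
        mir <- annotationTable("mirna_target",
                               sample(paste0("m", 1:6), 15, replace = TRUE),
                               sample(genes, 15, replace = TRUE))
        m1 <- predictMir(sp, mir, hubK = 1)
        m3 <- predictMir(sp, mir, hubK = 3)
        expect_true(all(predHitKeys(m3) %in% predHitKeys(m1)))
    }
})

test_that("combinePredictions merges provenance per gene", {
    sp1 <- twoLocusSpace(l1 = "a", l2 = "b")
    sp2 <- searchSpace("HS", "nearest_1", data.frame(
        locus_id = c("L9", "L10"), snp_id = c("rs9", "rs10"), chrom = "c",
        pos = c(1L, 2L), gene = c("a", "b")))
    cps <- predictCps(sp1, annotationTable("pathway", c("P", "P"),
                                           c("a", "b")))
    ppi <- predictPpi(sp2, annotationTable("interaction", "a", "b"))
    comb <- combinePredictions(list(cps, ppi))
    expect_equal(nrow(comb), 2)
    aRow <- comb[comb$gene == "a", ]
    expect_equal(aRow$modules, "CPS;PPI")
    expect_equal(aRow$n_modules, 2L)
    expect_true(grepl("HS/nearest_1", aRow$spaces) &&
                grepl("WS/fixed_500kb", aRow$spaces))

    expect_equal(nrow(combinePredictions(list())), 0)

    # disjoint single-gene outputs from five modules stay five records
    mk <- function(g, m) data.frame(gene = g, locus_id = "L1", module = m,
                                    stratum = "WS", method = "x")
    five <- combinePredictions(Map(mk, paste0("g", 1:5),
                                   c("CPS", "PPI", "CMP", "CRT", "MIR")))
    expect_equal(nrow(five), 5)
    expect_true(all(five$n_modules == 1L))
})
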