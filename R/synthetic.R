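#' Default parameters of the synthetic study
#'
#' The generator emulates, at roughly 1/30 scale, the statistical structure
#' the analysis assumes: four nested significance strata feeding six search
#' spaces, a genome in which about 8% of genes are drug targets, three
#' partially overlapping drug databases, and a small subset of drugs already
#' indicated for the phenotype. Override individual entries via `...`;
#' unknown names are rejected.
#'
#' @param ... named overrides of individual defaults.
#' @return named list of generator parameters.
#' @export
syntheticParams <- function(...) {
    p <- list(
        n_chrom = 4L,
        n_genes = 1200L,
        mean_gene_len = 1e4,
        mean_gap = 2e5,
        strata_mix = c(HS = 3L, MHS = 5L, MWS = 7L, WS = 10L),
        n_null_snps = 200L,
        decoy_density = 0.05,
        tau = 0.5,
        hub_k = 5L,
        target_fraction = 0.08,
        planted_target_fraction = 0.6,
        n_known_targets = 4L,
        n_offspace_known_targets = 3L,
        venn_profile = c(A = 0.55, B = 0.06, C = 0.12, AB = 0.17,
                         AC = 0.02, BC = 0.04, ABC = 0.04),
        accession_share = 0.3,
        untranslatable_share = 0.05,
        phenotype_terms = c("coronary artery disease", "cad"),
        citation_high_rate = 20,
        citation_low_rate = 0.1,
        citation_thresholds = c(1, 5, 10, 15),
        n_perm = 1000L,
        max_locus_width = 1e6)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
        stop("unknown synthetic parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
    p
}

#' Generate a synthetic gene annotation
#'
#' Lays out non-overlapping genes along `nChrom` chromosomes, with
#' exponentially distributed gene lengths and intergenic gaps. Deterministic
#' under the seed.
#'
#' @param nChrom number of chromosomes (>= 1 when `nGenes` > 0).
#' @param nGenes total number of genes.
#' @param meanGeneLen,meanGap mean gene length and intergenic gap in bp.
#' @param seed RNG seed.
#' @return data.frame with columns `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
generateGenome <- function(nChrom = 4L, nGenes = 1200L, meanGeneLen = 1e4,
                           meanGap = 2e5, seed = 1L) {
    stopIfNot(meanGeneLen > 0 && meanGap > 0, "lengths must be positive")
    if (nGenes == 0)
        return(data.frame(symbol = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), stringsAsFactors = FALSE))
    stopIfNot(nChrom >= 1, "need at least one chromosome")
    withSeed(seed, {
        perChrom <- rep(nGenes %/% nChrom, nChrom) +
            c(rep(1L, nGenes %% nChrom), rep(0L, nChrom - nGenes %% nChrom))
        rows <- list()
        idx <- 0L
        for (ci in seq_len(nChrom)) {
            n <- perChrom[ci]
            if (n == 0) next
            gaps <- round(rexp(n, 1 / meanGap)) + 1000L
            lens <- round(rexp(n, 1 / meanGeneLen)) + 200L
            pos <- 0L
            for (i in seq_len(n)) {
                idx <- idx + 1L
                start <- pos + gaps[i]
                end <- start + lens[i]
                rows[[idx]] <- data.frame(
                    symbol = sprintf("G%04d", idx),
                    chrom = paste0("chr", ci),
                    start = as.integer(start), end = as.integer(end),
                    strand = sample(c("+", "-"), 1L),
                    stringsAsFactors = FALSE)
                pos <- end
            }
        }
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    })
}

# p-value sampling intervals of the disjoint stratum labels
strataIntervals <- function() {
    list(HS = c(1e-12, 5e-7), MHS = c(5e-7, 1e-5),
         MWS = c(1e-5, 1e-4), WS = c(1e-4, 1e-3))
}

#' Generate synthetic GWAS association results with planted loci
#'
#' Plants one SNP inside each of `sum(strataMix)` distinct disease genes and
#' draws its p-value log-uniformly inside the disjoint interval of its
#' assigned stratum (e.g. an MHS-labelled SNP has p in (5e-7, 1e-5]), so
#' stratifying the output recovers the planted strata exactly. Null SNPs are
#' placed uniformly on the genome with p-values above the weakest threshold.
#'
#' @param genome gene annotation from [generateGenome()].
#' @param strataMix named integer vector giving the number of planted loci
#'   per disjoint stratum label (HS, MHS, MWS, WS).
#' @param nNullSnps number of non-associated SNPs.
#' @param seed RNG seed.
#' @return list with `snps` (association data.frame: `snp_id`, `chrom`,
#'   `pos`, `p_value`) and `manifest` (data.frame `snp_id`, `gene`,
#'   `stratum`, plus attribute-free planted gene order).
#' @export
generateGwas <- function(genome, strataMix = c(HS = 3L, MHS = 5L, MWS = 7L,
                                               WS = 10L),
                         nNullSnps = 200L, seed = 1L) {
    iv <- strataIntervals()
    stopIfNot(all(names(strataMix) %in% names(iv)),
              "strataMix labels must be HS, MHS, MWS, WS")
    nLoci <- sum(strataMix)
    stopIfNot(nLoci <= nrow(genome), "more planted loci than genes")
    withSeed(seed, {
        plantedIdx <- sample(nrow(genome), nLoci)
        labels <- rep(names(strataMix), strataMix)
        pvals <- vapply(labels, function(l) {
            b <- iv[[l]]
            p <- 10^runif(1, log10(b[1]), log10(b[2]))
            min(b[2], max(b[1] * 1.000001, p))
        }, numeric(1))
        planted <- data.frame(
            snp_id = sprintf("rsP%03d", seq_len(nLoci)),
            chrom = genome$chrom[plantedIdx],
            pos = as.integer(floor((genome$start[plantedIdx] + 1L +
                                    genome$end[plantedIdx]) / 2)),
            p_value = pvals, stringsAsFactors = FALSE)
        manifest <- data.frame(snp_id = planted$snp_id,
                               gene = genome$symbol[plantedIdx],
                               stratum = labels, stringsAsFactors = FALSE)
        nulls <- NULL
        if (nNullSnps > 0) {
            chromEnds <- tapply(genome$end, genome$chrom, max)
            nc <- sample(names(chromEnds), nNullSnps, replace = TRUE)
            nulls <- data.frame(
                snp_id = sprintf("rsN%04d", seq_len(nNullSnps)),
                chrom = nc,
                pos = as.integer(ceiling(runif(nNullSnps) *
                                         chromEnds[nc])),
                p_value = 10^runif(nNullSnps, log10(2e-3), 0),
                stringsAsFactors = FALSE)
        }
        snps <- rbind(planted, nulls)
        rownames(snps) <- NULL
        list(snps = snps, manifest = manifest)
    })
}

#' Generate the five annotation tables around planted disease genes
#'
#' Wires the planted genes so that each prediction module can recover a
#' designated subset: a shared pathway (CPS), pairwise interaction edges
#' (PPI), domain profiles identical to generated seed genes (CMP), a shared
#' transcription factor (CRT), and a shared microRNA plus `hubK`-fold
#' targeting (MIR). Modules are assigned round-robin over the planted genes;
#' a singleton group borrows one partner from the largest group so its
#' cross-locus rule can fire, and the borrowed gene joins that module's
#' expected set. Decoy pairs link random genome genes to off-genome symbols
#' at `decoyDensity` per table, so they can never create cross-locus sharing
#' among genome genes.
#'
#' @param genome gene annotation.
#' @param plantedGenes character vector of planted disease genes.
#' @param decoyDensity decoy pairs per genome gene, per table.
#' @param hubK MIR hub threshold used for the wiring.
#' @param seed RNG seed.
#' @return list with `tables` (named list of the five annotation tables),
#'   `seedGenes` (CMP seeds), and `moduleGenes` (named list of the per-module
#'   expected planted subsets).
#' @export
generateAnnotations <- function(genome, plantedGenes, decoyDensity = 0.05,
                                hubK = 5L, seed = 1L) {
    stopIfNot(all(plantedGenes %in% genome$symbol),
              "planted genes must be in the genome")
    mods <- c("CPS", "PPI", "CMP", "CRT", "MIR")
    assign <- if (length(plantedGenes))
        split(plantedGenes, rep(mods, length.out = length(plantedGenes)))
        else stats::setNames(rep(list(character()), 5), mods)
    for (m in mods) if (is.null(assign[[m]])) assign[[m]] <- character()
    # borrow a partner for singleton cross-locus groups
    expected <- assign
    biggest <- mods[which.max(lengths(assign))]
    for (m in c("CPS", "PPI", "CRT", "MIR")) {
        if (length(assign[[m]]) == 1L && length(plantedGenes) > 1L) {
            partner <- setdiff(assign[[biggest]], assign[[m]])[1]
            expected[[m]] <- sort(c(assign[[m]], partner))
        }
    }
    withSeed(seed, {
        pw <- data.frame(subject = character(), object = character())
        if (length(expected$CPS) >= 2L)
            pw <- data.frame(subject = "PW_PLANTED", object = expected$CPS)
        ppiGenes <- expected$PPI
        ppi <- data.frame(subject = character(), object = character())
        if (length(ppiGenes) >= 2L) {
            nxt <- c(ppiGenes[-1], ppiGenes[1])
            keep <- ppiGenes != nxt
            ppi <- data.frame(subject = ppiGenes[keep], object = nxt[keep])
        }
        seedGenes <- character()
        dom <- data.frame(subject = character(), object = character())
        if (length(expected$CMP) >= 1L) {
            seedGenes <- paste0("SEED", seq_along(expected$CMP))
            dom <- do.call(rbind, lapply(seq_along(expected$CMP), function(i) {
                d <- paste0("DOM_", expected$CMP[i], "_", 1:2)
                data.frame(subject = c(rep(expected$CMP[i], 2),
                                       rep(seedGenes[i], 2)),
                           object = c(d, d), stringsAsFactors = FALSE)
            }))
        }
        tf <- data.frame(subject = character(), object = character())
        if (length(expected$CRT) >= 2L)
            tf <- data.frame(subject = "TF_PLANTED", object = expected$CRT)
        mir <- data.frame(subject = character(), object = character())
        if (length(expected$MIR) >= 2L) {
            shared <- data.frame(subject = "mir_shared", object = expected$MIR)
            hubs <- do.call(rbind, lapply(expected$MIR, function(g)
                data.frame(subject = paste0("mir_", g, "_", seq_len(hubK - 1L)),
                           object = g, stringsAsFactors = FALSE)))
            mir <- rbind(shared, hubs)
        }
        # additive decoys: genome gene paired with an off-genome symbol
        nDecoy <- max(0L, round(decoyDensity * nrow(genome)))
        decoyPair <- function(prefix) {
            if (nDecoy == 0 || nrow(genome) == 0)
                return(data.frame(subject = character(), object = character()))
            g <- sample(genome$symbol, nDecoy, replace = TRUE)
            data.frame(subject = paste0(prefix, "_", seq_len(nDecoy)),
                       object = g, stringsAsFactors = FALSE)
        }
        pw <- rbind(pw, decoyPair("DPW"))
        tf <- rbind(tf, decoyPair("DTF"))
        mir <- rbind(mir, decoyPair("dmir"))
        if (nDecoy > 0) {
            gI <- sample(genome$symbol, nDecoy, replace = TRUE)
            ppi <- rbind(ppi, data.frame(subject = gI,
                                         object = paste0("XG_PPI_",
                                                         seq_len(nDecoy))))
            eligible <- setdiff(genome$symbol, expected$CMP)
            gD <- sample(eligible, min(nDecoy, length(eligible)))
            dom <- rbind(dom, data.frame(
                subject = rep(gD, each = 2),
                object = paste0("DDOM_", rep(seq_along(gD), each = 2),
                                "_", 1:2)))
        }
        tables <- list(
            pathway = annotationTable("pathway", pw$subject, pw$object),
            interaction = annotationTable("interaction", ppi$subject,
                                          ppi$object),
            domain = annotationTable("domain", dom$subject, dom$object),
            tf_target = annotationTable("tf_target", tf$subject, tf$object),
            mirna_target = annotationTable("mirna_target", mir$subject,
                                           mir$object))
        list(tables = tables, seedGenes = seedGenes,
             moduleGenes = lapply(expected, sort))
    })
}

# integer allocation of n items to the 7 regions by largest remainder
allocateRegions <- function(profile, n) {
    reg <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
    stopIfNot(identical(sort(names(profile)), sort(reg)),
              "venn profile must name the seven regions A,B,C,AB,AC,BC,ABC")
    profile <- profile[reg]
    if (all(profile == round(profile)) && sum(profile) > 1.5) {
        if (sum(profile) != n)
            stop("venn profile counts inconsistent with total targets (",
                 sum(profile), " vs ", n, ")")
        return(stats::setNames(as.integer(profile), reg))
    }
    raw <- profile / sum(profile) * n
    base <- floor(raw)
    rem <- n - sum(base)
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
    stats::setNames(as.integer(base), reg)
}

#' Generate three synthetic drug-database exports with planted truth
#'
#' Marks about `targetFraction` of genome genes as drug targets, including a
#' `plantedTargetFraction` share of the planted disease genes. Targets are
#' distributed over the seven exclusive regions of the three databases
#' according to `vennProfile` (proportions, or exact counts summing to the
#' target total). `nKnownTargets` planted druggable genes receive a dedicated
#' drug indicated for the phenotype; `nOffspaceKnownTargets` additional known
#' targets are placed on genes farther than `minOffspaceDistance` from every
#' planted SNP, mirroring known drug targets that fall outside the search
#' spaces. A share of the second database's targets are emitted as accessions
#' requiring translation, and a few untranslatable accession rows are added.
#'
#' @param genome gene annotation.
#' @param plantedGenes planted disease genes.
#' @param plantedSnps data.frame with `chrom`, `pos` of the planted SNPs
#'   (used for the off-space distance rule).
#' @param targetFraction fraction of genes that are drug targets.
#' @param plantedTargetFraction fraction of planted genes that are druggable.
#' @param nKnownTargets planted druggable genes with a phenotype-indicated
#'   drug.
#' @param nOffspaceKnownTargets known targets outside all search spaces.
#' @param vennProfile 7-region overlap profile (see above).
#' @param accessionShare share of second-database rows written as accessions.
#' @param untranslatableShare share of extra untranslatable rows.
#' @param phenotypeTerms phenotype names; the first is used as the known
#'   indication.
#' @param minOffspaceDistance minimum distance (bp) of off-space known
#'   targets from any planted SNP.
#' @param seed RNG seed.
#' @return list with `exports` (named list of raw data.frames: `drugbank`,
#'   `ttd`, `pharmgkb`, in their dialect shapes), `idMap`, and `manifest`
#'   (planted/known/novel targets and drugs, per-database target sets,
#'   realized region counts).
#' @export
generateDrugDatabases <- function(genome, plantedGenes, plantedSnps,
                                  targetFraction = 0.08,
                                  plantedTargetFraction = 0.6,
                                  nKnownTargets = 4L,
                                  nOffspaceKnownTargets = 3L,
                                  vennProfile = syntheticParams()$venn_profile,
                                  accessionShare = 0.3,
                                  untranslatableShare = 0.05,
                                  phenotypeTerms = c("coronary artery disease"),
                                  minOffspaceDistance = 1e6,
                                  seed = 1L) {
    stopIfNot(targetFraction >= 0 && targetFraction <= 1 &&
              plantedTargetFraction >= 0 && plantedTargetFraction <= 1,
              "fractions must lie in [0, 1]")
    withSeed(seed, {
        nTargets <- round(targetFraction * nrow(genome))
        plantedTargets <- sort(sample(plantedGenes,
            round(plantedTargetFraction * length(plantedGenes))))
        stopIfNot(nKnownTargets <= length(plantedTargets),
                  "nKnownTargets exceeds planted druggable genes")
        knownTargets <- sort(sample(plantedTargets, nKnownTargets))
        novelTargets <- setdiff(plantedTargets, knownTargets)
        # genes far from every planted SNP (outside any search space)
        farGene <- vapply(seq_len(nrow(genome)), function(i) {
            on <- plantedSnps$chrom == genome$chrom[i]
            if (!any(on)) return(TRUE)
            d <- pmax(0, genome$start[i] + 1L - plantedSnps$pos[on],
                      plantedSnps$pos[on] - genome$end[i])
            all(d > minOffspaceDistance)
        }, logical(1))
        farPool <- setdiff(genome$symbol[farGene], plantedGenes)
        stopIfNot(length(farPool) >= nOffspaceKnownTargets,
                  "not enough off-space genes for known decoy targets")
        offspaceKnown <- sort(sample(farPool, nOffspaceKnownTargets))
        mustHave <- unique(c(plantedTargets, offspaceKnown))
        stopIfNot(nTargets >= length(mustHave),
                  "targetFraction too small for planted targets")
        others <- sample(setdiff(genome$symbol,
                                 union(plantedGenes, mustHave)),
                         nTargets - length(mustHave))
        targets <- sample(c(mustHave, others))  # shuffled
        regionCounts <- allocateRegions(vennProfile, nTargets)
        regionOf <- rep(names(regionCounts), regionCounts)
        names(regionOf) <- targets
        dbOf <- list(A = c("A", "AB", "AC", "ABC"),
                     B = c("B", "AB", "BC", "ABC"),
                     C = c("C", "AC", "BC", "ABC"))
        inDb <- lapply(dbOf, function(regs) targets[regionOf %in% regs])

        # drug pool shared across targets; dedicated known drugs per known target
        poolSize <- max(1L, ceiling(nTargets * 1.2))
        pool <- sprintf("drug%04d", seq_len(poolSize))
        novelIndications <- c("epilepsy", "depressive disorder",
                              "renal cell carcinoma", "skin ulcers",
                              "asthma", "type 2 diabetes mellitus",
                              "rheumatoid arthritis")
        recs <- list()
        for (g in targets) {
            nd <- sample(1:3, 1L)
            for (d in sample(pool, nd)) {
                recs[[length(recs) + 1L]] <- data.frame(
                    drug = d, target = g,
                    class = sample(c("approved", "clinical", "experimental",
                                     "unknown"), 1L,
                                   prob = c(0.45, 0.35, 0.1, 0.1)),
                    indication = sample(novelIndications, 1L),
                    stringsAsFactors = FALSE)
            }
        }
        knownAll <- c(knownTargets, offspaceKnown)
        for (i in seq_along(knownAll)) {
            nkd <- sample(1:2, 1L)
            for (j in seq_len(nkd)) {
                recs[[length(recs) + 1L]] <- data.frame(
                    drug = sprintf("ctrldrug%02d_%d", i, j),
                    target = knownAll[i],
                    class = sample(c("approved", "clinical"), 1L),
                    indication = phenotypeTerms[1],
                    stringsAsFactors = FALSE)
            }
        }
        recs <- do.call(rbind, recs)

        statusToken <- function(class, db) {
            switch(db,
                drugbank = c(approved = "approved",
                             clinical = "investigational",
                             experimental = "experimental",
                             unknown = "")[class],
                ttd = c(approved = "Launched", clinical = "Phase III",
                        experimental = "Experimental",
                        unknown = "Unknown")[class],
                pharmgkb = c(approved = "Approved",
                             clinical = "Clinical Trial",
                             experimental = "Experimental",
                             unknown = "")[class])
        }
        idMap <- data.frame(accession = sprintf("UP%05d",
                                                seq_along(sort(targets))),
                            symbol = sort(targets),
                            stringsAsFactors = FALSE)
        accOf <- stats::setNames(idMap$accession, idMap$symbol)

        mkExport <- function(db, dbTargets) {
            d <- recs[recs$target %in% dbTargets, , drop = FALSE]
            tok <- unname(statusToken(d$class, db))
            if (db == "drugbank")
                data.frame(name = d$drug, gene_name = d$target,
                           groups = tok, indication = d$indication,
                           actions = "unknown", stringsAsFactors = FALSE)
            else if (db == "ttd") {
                useAcc <- runif(nrow(d)) < accessionShare
                data.frame(DRUGNAME = d$drug,
                           TARGETID = ifelse(useAcc, accOf[d$target],
                                             d$target),
                           HIGHEST_STATUS = tok, INDICATION = d$indication,
                           ACTION = "unknown", stringsAsFactors = FALSE)
            } else
                data.frame(Chemical = d$drug, Gene = d$target,
                           Status = tok, Indication = d$indication,
                           stringsAsFactors = FALSE)
        }
        exports <- list(drugbank = mkExport("drugbank", inDb$A),
                        ttd = mkExport("ttd", inDb$B),
                        pharmgkb = mkExport("pharmgkb", inDb$C))
        nBad <- round(untranslatableShare * nrow(exports$ttd))
        if (nBad > 0) {
            bad <- data.frame(DRUGNAME = sample(pool, nBad, replace = TRUE),
                              TARGETID = sprintf("UPX9%03d", seq_len(nBad)),
                              HIGHEST_STATUS = "Experimental",
                              INDICATION = sample(novelIndications, nBad,
                                                  replace = TRUE),
                              ACTION = "unknown", stringsAsFactors = FALSE)
            exports$ttd <- rbind(exports$ttd, bad)
        }
        onPlanted <- recs[recs$target %in% plantedTargets, , drop = FALSE]
        knownDrugs <- sort(unique(
            onPlanted$drug[onPlanted$indication == phenotypeTerms[1]]))
        novelDrugs <- sort(setdiff(unique(onPlanted$drug), knownDrugs))
        manifest <- list(
            targets = sort(targets),
            planted_targets = plantedTargets,
            planted_known_targets = knownTargets,
            planted_novel_targets = novelTargets,
            offspace_known_targets = offspaceKnown,
            known_drugs = knownDrugs,
            novel_drugs = novelDrugs,
            db_targets = lapply(inDb, sort),
            region_counts = as.list(regionCounts))
        list(exports = exports, idMap = idMap, manifest = manifest)
    })
}

#' Generate synthetic gene-citation counts
#'
#' Genes in the high group draw Poisson counts at `highRate`, all others at
#' `lowRate`; deterministic under the seed.
#'
#' @param genes character vector of all genes.
#' @param highGenes genes with phenotype literature support.
#' @param highRate,lowRate Poisson means (>= 0).
#' @param seed RNG seed.
#' @return data.frame with columns `gene`, `n_citations`.
#' @export
generateCitations <- function(genes, highGenes, highRate = 20,
                              lowRate = 0.1, seed = 1L) {
    stopIfNot(highRate >= 0 && lowRate >= 0, "rates must be >= 0")
    withSeed(seed, {
        hi <- genes %in% highGenes
        n <- integer(length(genes))
        n[hi] <- rpois(sum(hi), highRate)
        n[!hi] <- rpois(sum(!hi), lowRate)
        data.frame(gene = genes, n_citations = n, stringsAsFactors = FALSE)
    })
}

#' Simulate a full input bundle with a planted-truth manifest
#'
#' Runs all generators with sub-seeds derived from one master seed and writes
#' every pipeline input into `dir`: association results, gene BED, the five
#' annotation tables, the three drug-database exports, the identifier map,
#' citation counts, CMP seed genes, phenotype terms, and `manifest.json`
#' recording the planted truth and generator parameters.
#'
#' @param dir output directory (created if missing).
#' @param params parameter list from [syntheticParams()].
#' @param seed master RNG seed.
#' @return invisibly, a list with `paths` (named file paths), `manifest` and
#'   `params`.
#' @export
simulateBundle <- function(dir, params = syntheticParams(), seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sub <- withSeed(seed, sample.int(1e7, 5))
    genome <- generateGenome(params$n_chrom, params$n_genes,
                             params$mean_gene_len, params$mean_gap,
                             seed = sub[1])
    gwas <- generateGwas(genome, strataMix = params$strata_mix,
                         nNullSnps = params$n_null_snps, seed = sub[2])
    ann <- generateAnnotations(genome, gwas$manifest$gene,
                               decoyDensity = params$decoy_density,
                               hubK = params$hub_k, seed = sub[3])
    plantedSnps <- merge(gwas$manifest, gwas$snps, by = "snp_id")
    drugs <- generateDrugDatabases(
        genome, gwas$manifest$gene,
        plantedSnps[, c("chrom", "pos")],
        targetFraction = params$target_fraction,
        plantedTargetFraction = params$planted_target_fraction,
        nKnownTargets = params$n_known_targets,
        nOffspaceKnownTargets = params$n_offspace_known_targets,
        vennProfile = params$venn_profile,
        accessionShare = params$accession_share,
        untranslatableShare = params$untranslatable_share,
        phenotypeTerms = params$phenotype_terms,
        minOffspaceDistance = params$max_locus_width,
        seed = sub[4])
    citations <- generateCitations(genome$symbol,
                                   drugs$manifest$planted_targets,
                                   highRate = params$citation_high_rate,
                                   lowRate = params$citation_low_rate,
                                   seed = sub[5])
    p <- function(f) file.path(dir, f)
    paths <- list(
        associations = p("associations.tsv"), genes_bed = p("genes.bed"),
        pathway = p("pathways.tsv"), interaction = p("interactions.tsv"),
        domain = p("domains.tsv"), tf_target = p("tf_targets.tsv"),
        mirna_target = p("mirna_targets.tsv"),
        drugbank = p("drugbank.csv"), ttd = p("ttd.tsv"),
        pharmgkb = p("pharmgkb.tsv"), id_map = p("id_map.tsv"),
        citations = p("citations.tsv"), seed_genes = p("seed_genes.txt"),
        phenotype_terms = p("phenotype_terms.txt"),
        manifest = p("manifest.json"))
    writeTsv(stats::setNames(gwas$snps, c("SNP", "CHR", "BP", "P")),
             paths$associations)
    write.table(genome[, c("chrom", "start", "end", "symbol")],
                paths$genes_bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    for (k in names(ann$tables))
        writeTsv(ann$tables[[k]], paths[[k]])
    write.table(drugs$exports$drugbank, paths$drugbank, sep = ",",
                quote = FALSE, row.names = FALSE)
    writeTsv(drugs$exports$ttd, paths$ttd)
    writeTsv(drugs$exports$pharmgkb, paths$pharmgkb)
    writeTsv(drugs$idMap, paths$id_map)
    writeTsv(citations, paths$citations)
    writeLines(ann$seedGenes, paths$seed_genes)
    writeLines(params$phenotype_terms, paths$phenotype_terms)
    manifest <- c(list(seed = seed,
                       params = params[setdiff(names(params),
                                               "venn_profile")],
                       venn_profile = as.list(params$venn_profile),
                       planted_disease_genes = sort(gwas$manifest$gene),
                       planted_snps = gwas$manifest,
                       module_genes = ann$moduleGenes,
                       seed_genes = ann$seedGenes),
                  drugs$manifest)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(paths = paths, manifest = manifest, params = params))
}
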