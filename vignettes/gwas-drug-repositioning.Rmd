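---
title: "From GWAS loci to repositionable drugs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS loci to repositionable drugs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwas2drug)
```

## The problem and the model

Genome-wide association studies of complex diseases such as coronary artery
disease leave most of the genetic signal below the genome-wide significance
threshold. The pipeline in this package rescues that weaker signal by
combining three independent sources of evidence: (1) graded statistical
association, (2) biological knowledge linking genes across implicated loci,
and (3) existing pharmacology. A gene supported by all three is a candidate
therapeutic target, and any of its drugs not already indicated for the
phenotype is a repositioning hypothesis.

The statistical association enters through four *nested* significance
strata — HS (p ≤ 5×10⁻⁷), MHS (p ≤ 10⁻⁵), MWS (p ≤ 10⁻⁴) and WS
(p ≤ 10⁻³). Nesting is cumulative by construction (`stratifySnps()`):
lowering the threshold only adds SNPs, and the thresholds are inclusive, so
a SNP at exactly 5×10⁻⁷ belongs to HS. Because the causal variant may be
regulatory and distal, gene assignment is deliberately redundant: around
each SNP locus, six search spaces are built (`buildSearchSpace()`) — three
fixed half-width windows (100 kb, 500 kb, 1 Mb) and three k-nearest-gene
rules (k = 1, 3, 5). With four strata this yields the full 24-space grid.
The specific widths and k values are tunable; the defaults span the locus
sizes typical of GWAS follow-up work.

Coordinates are handled with one convention each: SNP positions are 1-based
(GWAS convention), gene intervals 0-based half-open (BED convention), and
conversion happens exactly once at parse time. A fixed-width space includes
a gene iff its interval intersects `[pos − w, pos + w)`; a proximity space
takes the k genes with minimal base-pair distance to the gene interval
(zero when the SNP lies inside the gene), breaking ties lexicographically
by symbol so results are deterministic. Strand is parsed but ignored —
distance is to the interval, not to the transcription start site, since no
TSS rule is part of the method. Overlapping loci are never merged: sharing
of annotation *between* loci is the evidence the prediction modules use, so
locus identity must be preserved; a gene near two SNPs appears once per
locus but only once in any gene universe.

## The five prediction modules

All five modules are principle-level binary rules; no ranking scores are
emitted, because everything downstream consumes set membership only.

* **CPS** (`predictCps()`): gene g in locus L is nominated iff some pathway
  contains g and a *different* gene in a *different* locus. Intra-locus
  sharing never predicts — genes under one association peak are expected to
  share annotation for reasons of genomic proximity alone.
* **PPI** (`predictPpi()`): as CPS, but with a direct interaction edge;
  edges are symmetric and self-edges are ignored.
* **CMP** (`predictCmp()`): domain-profile similarity to a known phenotype
  gene — Jaccard of domain sets ≥ τ (default 0.5, i.e. the profiles agree
  on at least as many domains as they disagree). Seed genes are a required
  input; genes or seeds without domain annotation never match. This is the
  one module without a cross-locus requirement, since its evidence is
  external (the seed list).
* **CRT** (`predictCrt()`): a transcription factor targeting the gene and a
  different-locus gene.
* **MIR** (`predictMir()`): a shared microRNA across loci *and* hub
  membership — at least `hubK` (default 5) distinct miRNAs targeting the
  gene. The hub clause encodes the assumption that regulatory hubs are the
  functionally consequential miRNA targets.

A design point worth making explicit: a gene that itself occupies two loci
does not satisfy a cross-locus rule — the partner must be a different gene.
The alternative reading (self-partnering across loci) would nominate genes
purely for spanning two windows, which carries no biological information.

`combinePredictions()` unions per-space, per-module results into one record
per gene with full provenance (modules, loci, spaces). Monotonicity holds
throughout: adding annotation never removes a prediction; raising τ or
`hubK` never adds one. The test suite asserts both, plus agreement with
exhaustive brute-force oracles on small instances.

## Drug-database integration

Three export dialects (DrugBank-, TTD- and PharmGKB-like) are parsed into a
common record shape. Development statuses collapse to a closed vocabulary:
approved/launched → `approved`; phase, trial, investigational →
`clinical`; experimental/preclinical → `experimental`; anything else →
`unknown` (counted and warned). Targets are harmonized to HUGO symbols via
an accession map; untranslatable records are dropped and counted — this
doubles as the human-target filter. Drug identity across databases is the
case-folded, whitespace-normalized drug name (no structure matching; a
synonym table can be layered on by pre-normalizing the exports).
`poolDatabases()` deduplicates (drug, target) pairs with union provenance
and is idempotent.

A target is *known* for the phenotype iff at least one associated drug has
an indication matching any phenotype term by normalized substring match;
otherwise it is novel. Matching is deliberately simple and term-driven —
the phenotype synonym list is the user's contract, and the bundled default
uses the full phenotype name plus its abbreviation. For status breakdowns,
experimental- or unknown-only drugs are binned with the clinical class:
they are unapproved compounds, which is the operationally relevant
distinction for repositioning priority.

Reporting conventions: the targetability index (targets / candidates) is
rendered as a whole percent (`renderPercent()`), the novelty ratio
(novel / targets) truncated at two decimals (`renderRatio()`). These are
the only conventions simultaneously consistent with rendering 192/647 as
30%, 102/264 as 39%, 184/192 as 0.95 and 98/102 as 0.96.

## Validation benchmarks

**Search-space benchmark** (`searchSpaceBenchmark()`). The universe is the
union of the six search spaces of the widest stratum. Each universe gene is
scored by the number of those spaces in which it appears as a predicted
therapeutic target (0–6); thresholding at ≥6 … ≥1 yields six contingency
tables (known phenotype drug targets are the positives) and an ROC curve.
The published description ("six thresholds based on the number of targets
present in the six search spaces") does not pin down the ordering; this
per-gene score is the reading that reproduces the published table structure
at the widest threshold and uses all six spaces as graded evidence. Known
targets outside the universe are excluded and reported — most known
therapy targets of a phenotype are expected to lie outside the implicated
loci.

**Citation benchmark** (`citationBenchmark()`). A gene is
literature-positive at threshold t iff it has ≥ t phenotype-linked
citations (defaults 1, 5, 10, 15); genes without citation records count as
zero. The counts can come directly from a TSV or from a gene↔publication
pair table joined against a phenotype publication set
(`citationCountsFromPairs()`).

AUC is trapezoidal over points anchored at (0,0) and (1,1); degenerate
tables (undefined rate) are skipped with a warning, and duplicate points do
not change the area. Curve fitting by non-linear regression is not
reproducible from its published description, so significance is instead
assessed with a standard, assertable substitute: the Mann–Whitney AUC
(pairwise P(pos > neg), ties ½ — exactly equal to the trapezoid AUC over
all score thresholds, which the tests verify) with a seeded one-sided
permutation test of H₀: AUC = 0.5, p = (1 + #{perm ≥ obs}) / (B + 1).

## The synthetic study and what it does (not) show

`simulateBundle()` generates every input with a planted-truth manifest, at
roughly 1/30 the scale of a WTCCC-era analysis so a full run takes seconds:
4 chromosomes carrying 1200 genes (mean length 10 kb, mean gap 200 kb —
sparse enough that the 1 Mb windows of 25 loci cover only part of the
genome, leaving room for genes outside all search spaces); 25 planted
disease loci in a 3/5/7/10 HS/MHS/MWS/WS mix (≈ 757/30 SNPs) plus 200 null
SNPs with p > 10⁻³; p-values drawn log-uniformly inside each stratum's
disjoint interval so stratification recovers the planted strata exactly;
8% of genes druggable; 60% of planted genes druggable (15 targets), 4 of
them with a dedicated phenotype-indicated drug; 3 further known targets
placed > 1 Mb from every planted SNP, mimicking known therapy targets that
genetics does not reach; three databases overlapping per a DrugBank-heavy
7-region profile; 30% of second-database rows emitted as accessions and a
5% untranslatable share; citation rates 20 vs 0.1 for planted targets vs
background.

Annotation wiring makes each planted gene recoverable by its designated
module (round-robin assignment; singleton groups borrow one partner so the
cross-locus rule can fire). Decoy annotation connects genome genes to
off-genome symbols only, so decoys are strictly additive and cannot create
cross-locus structure among genome genes: with the default generator the
false-positive candidate rate is zero by construction. That is a deliberate
property — it makes recovery tests exact — and an equally deliberate
limitation: real annotation databases produce correlated, locus-clustered
false positives, real LD smears association across neighbouring genes, and
real drug nomenclature is far messier than case-folding. Passing the
planted-recovery suite therefore demonstrates correctness of the machinery
under the assumed generative structure, not performance on real data.

Every generator takes an explicit seed and restores the caller's RNG state;
`simulateBundle()` derives per-generator sub-seeds from one master seed, so
bundles, pipeline reports and permutation p-values are byte-reproducible.

## Numerical and degenerate-input choices

* Thresholds are inclusive (≤) everywhere: strata, CMP's τ, MIR's hub
  count, citation cutoffs.
* Ties in nearest-gene selection break lexicographically; ROC points sort
  by (fpr, tpr); all joined text fields are sorted unique — every output is
  deterministic given inputs.
* Empty inputs degrade to empty results (empty stratum, gene-free
  chromosome, empty annotation table, empty seed list), never to errors;
  errors are reserved for contract violations (non-increasing thresholds,
  unknown method or configuration key, predicted ⊄ universe, empty
  universe, zero denominators).
* `summarizeRepositioning()` re-asserts the partition identities
  (known + novel = total, breakdowns sum to class totals) on every run and
  fails loudly naming the violated identity.

## Interface

The exported functions are the interface; `runPipeline()` orchestrates the
stages (stratify → spaces → predict → integrate → reposition → benchmark →
compare) from a validated `pipelineConfig()`, writes every intermediate
table plus `report.txt`/`report.json` under `out_dir`, and logs per-stage
counts to stderr. `scripts/acceptance.R` is a thin wrapper that recomputes
the headline statistics and a full synthetic run; `simulateBundle()` plays
the role of a `simulate` subcommand. Figure generation is out of scope
beyond ROC point export.

## Known limitations

The five modules are principle-level re-creations, not the published
implementations of the original prediction system (which score and
prioritize); external gene lists bundled for comparison are synthetic
stand-ins; indication matching is substring-based and will miss synonymous
disease vocabulary unless the term list covers it; and the benchmark
ordering choice described above, while faithful to the published table, is
one of several defensible readings.
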