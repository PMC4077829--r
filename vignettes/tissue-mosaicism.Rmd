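---
title: "Multi-tissue SNV mosaicism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue SNV mosaicism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicsnv)
```

## The biological model

A multicellular body is a clone with history. Every mutation acquired
after fertilisation is inherited by the cellular descendants of the cell
in which it arose, so the set of tissues carrying a somatic SNV encodes
*when* it arose:

- **germline / zygotic** variants are carried by every cell of the body;
- **germ-layer** variants, acquired around gastrulation, are carried by
  all tissues derived from one layer (ectoderm, mesoderm or endoderm);
- **tissue-founder** variants are clonal within one tissue and absent
  elsewhere;
- **late-somatic** variants, acquired during later development or adult
  life, are confined to a fraction of one tissue's cells.

The package's analyses all exploit this scoping. The *common-to-all core*
(`common_to_all`) isolates the germline/zygotic stratum; pairwise
differences (`pairwise_unique`, `pairwise_matrix`) surface tissue-specific
variation; within- versus cross-layer sharing (`layer_sharing_summary`)
tests for the germ-layer stratum.

Variant identity throughout is the **variant key** (chromosome, 1-based
position, reference allele, alternate allele). Zygosity is deliberately
excluded from identity: the comparisons concern presence/absence of a
variation, not genotype concordance, and exact-site matching mirrors how
standard VCF comparison tools operate. Chromosome labels are normalized by
stripping a leading `chr` internally and re-attached on output, so both
hg19 dialects interoperate.

## Hard filtering

`apply_hard_filters` re-implements classic record-local hard filtering: a
call passes iff

```
dp >= min_dp  AND  QD >= 2.0  AND  FS <= 60.0  AND  MQ >= 35.0  AND
HaplotypeScore <= 13.0  AND  MQRankSum >= -12.5  AND  ReadPosRankSum >= -8.0
```

Three choices deserve comment:

1. **Inclusive depth.** Depth tiers are read inclusively (`dp >= 20` at
   DP20): "covered by at least N reads" is the unambiguous convention,
   and it makes stratum counts at rising tiers a nested, non-increasing
   family — the property `stratify_by_depth` relies on.
2. **Missing annotations pass.** Rank-sum statistics are undefined at
   e.g. homozygous-alt sites; an absent annotation is represented as `NA`
   (never 0) and treated as passing its criterion, matching standard
   hard-filter semantics. Missing counts are tallied in the filter report.
3. **All criteria at every tier.** The six annotation criteria are applied
   at every depth tier by default; `apply_annotation_filters = FALSE`
   restricts filtering to depth alone for sensitivity analyses, since
   published descriptions of depth-stratified workflows do not always
   state whether annotation filters were re-applied per tier.

For reporting, the first failing criterion of each rejected record is
tallied in the fixed order DP, QD, FS, MQ, HaplotypeScore, MQRankSum,
ReadPosRankSum; the decision itself is order-independent, and the
exclusive first-failure counts plus passes always sum to the input count.

## From read fractions to cell fractions

With `ploidy` copies of a locus per cell and `mutant_copies` mutant
alleles per carrier cell, a carrier fraction *f* yields an expected
variant allele fraction `f · mutant_copies / ploidy`; inverting,

```
f̂ = min(1, VAF · ploidy / mutant_copies)
```

(`estimate_cell_fraction`; defaults 2 and 1, diploid heterozygous). The
cap at 1 absorbs sampling noise above the clonal ceiling. The companion
arithmetic `cells_from_dna_mass` converts input DNA mass to cell
equivalents (6.4×10⁻¹² g per diploid male G1 cell by default; 3 µg of DNA
is 468,750 ≈ 5×10⁵ cells, reported exactly and at one significant figure,
the conventional order-of-magnitude display).

`timing_class` deliberately separates two signals that are easy to
conflate: read depth (a property of capture and coverage) and estimated
carrier fraction (the actual lineage signal). A variant is labelled
`early-candidate` only when **both** the depth tier (default 100) and a
carrier-fraction floor (default 0.25) are met, and outputs are labelled
candidates because the classifier is a heuristic, not a validated
inference. The 0.25 floor is a package default with no empirical
derivation; it marks variants carried by at least a quarter of sampled
cells as plausibly early.

## The synthetic generator

`simulate_mosaicism` draws a full study: a truth set on the
zygote → germ-layer → tissue tree, then per-tissue observed callsets.

**Truth stage** (`simulate_truth`). Stage counts are Poisson with means
`n_germline = 12000` (split between germline and zygotic labels, which
are identical in scope and kept separate only for reporting),
`n_per_layer = 300`, `n_founder_per_tissue = 100`,
`n_late_per_tissue = 200`. No published per-stage somatic mutation counts
exist at this resolution; these defaults are sized so that a 16-tissue
run yields a common core in the five figures and pairwise
tissue-specific counts in the hundreds — non-degenerate for every
downstream statistic. Chromosome placement is multinomial with weights
proportional to per-chromosome protein-coding gene counts (the empirical
association for exonic SNVs), positions uniform along the chromosome, and
collided `chrom:pos` draws are redrawn so keys are unique. Late-somatic
cell fractions default to Uniform(0, 0.5): subclonal by construction,
since a late variant confined to part of one tissue cannot be clonal.

Positions are uniform over whole chromosomes rather than over a real exon
map. Distribution statistics depend only on the chromosome assignment, so
this costs nothing for the package's tests; analyses of *within*-
chromosome position would need a real interval map.

**Observation stage** (`sample_observed_callsets`). Per (variant, tissue
in scope): depth ~ Poisson(`coverage_mean` = 50, a typical exome run);
alt reads ~ Binomial(depth, `cell_fraction · mutant_copies / ploidy`);
called iff `alt_depth >= min_alt_reads` (3) and VAF ≥ `min_vaf` (0.05) —
minimal evidence thresholds in the range used by somatic callers. Called
records receive filter annotations drawn from comfortably passing ranges;
`fail_inject_rate` optionally replaces one annotation with a failing
value, a stress-test hook for the hard filter that is off by default.

**What the generator does not emulate.** No sequencing-error false
positives by default (so a called variant never escapes its truth scope —
the set-algebra tests exercise exact lineage structure, not error
tolerance); no mappability or capture-efficiency variation; no
trinucleotide mutational signatures; no copy-number events or indels; no
read-level artefacts. Passing tests therefore demonstrate correctness of
the pipeline's logic under the lineage model, not robustness to the
artefacts of real exome data.

**Determinism.** `simulate_truth` seeds from `config$seed`;
`simulate_mosaicism` seeds the observation stage with `config$seed + 1`.
Identical seeds give byte-identical `truth.tsv` files from
`write_simulation`.

## Chromosomal distribution statistics

`count_per_chromosome` reports counts, percentages and per-Mb densities
(Mb = 10⁶ bp) over a fixed chromosome universe — zero-count chromosomes
are reported, never dropped, so cross-tissue comparisons always align.
`correlate_with_feature` computes Pearson and Spearman coefficients of
counts against length, exon count, or coding-gene count, replacing visual
judgement with numbers. Chromosome Y is excluded from correlations by
default (negligible exome content); X is included but easily excluded via
`exclude = c("X", "Y")`, appropriate when X's lower variant diversity
distorts the fit. Constant inputs yield an explicit `defined = FALSE`
flag rather than a silent `NaN`, and fewer than three chromosomes after
exclusion is an error.

The shipped `chrom_features.tsv` is an hg19-era reference table (lengths
in Mb, exon and protein-coding gene counts per chromosome) frozen in the
package; any table with the same columns can replace it.

## Germ-layer sharing

The sharing statistic is the pairwise **Jaccard index**
`|A ∩ B| / |A ∪ B|` — size-invariant, unlike raw shared counts, so
tissues with different callset sizes compare fairly. Pairs are grouped
within-layer versus cross-layer and group means compared. A pair of empty
callsets has an undefined index (`NA`) and is excluded from means. The
shipped tissue→layer map follows the published 16-tissue assignment
verbatim (including adipose tissue under ectoderm); the two colliding
short labels are disambiguated as `SpC` (spinal cord) and `SuC`
(suprarrenal cortex).

## Enrichment

`enrich` is a deliberately plain over-representation test: upper-tail
hypergeometric `P(X ≥ k)` for a query of size *n* overlapping a term of
size *K* in *k* genes within a universe of *N*, with Benjamini–Hochberg
q-values and a deterministic (p, term-name) ordering. Web-service
enrichment tools do not document their exact statistic; an auditable
hypergeometric with a user-supplied annotation map is the reproducible
equivalent. Gene identifiers are opaque strings; no ontology propagation
is performed.

## Verification strategy and problem sizes

Every operation is tested against an independent oracle: a straight-line
per-record re-check for the hard filter, membership and nested-loop
recomputation for the set algebra, tally loops for counting, combinatorial
enumeration (closed-form sums and, for a small universe, literal
enumeration of all draws) for the hypergeometric tail. Simulation-level
guarantees are checked over 100 replicate runs at the generator defaults:
depth-stratum monotonicity, ≥95% recovery of germline/zygotic truth by
the common core with zero leakage of subset-scoped variants, and — with
50,000 gene-weighted placements per replicate — per-chromosome proportions
within 0.02 of the weights and a higher Spearman correlation with
coding-gene counts than with length in ≥95 replicates. The timing
classifier's discrimination (founder versus late variants) is checked at
`early_tier = 50`, the tier matched to the simulated mean coverage, since
at 50× depth the default 100-read tier is essentially never reached and
the discriminating signal is the carrier-fraction floor.

## Known limitations

- Headline counts from any real study (total SNVs per tissue, the size of
  the common core) depend on the subjects' unpublished exomes and are not
  reproducible from synthetic data; the package validates properties and
  mechanisms, not those counts.
- The carrier-fraction estimator assumes a copy-neutral locus; CNVs bias
  VAF and are out of scope.
- `timing_class` is a screening heuristic. Deep coverage reflects capture
  efficiency as much as lineage; only the VAF component carries timing
  information, and validation would require orthogonal sequencing.
- The simulator's lineage tree has fixed depth 3; finer-grained lineages
  (e.g. organ sub-compartments) would need a deeper tree.
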