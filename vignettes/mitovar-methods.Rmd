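---
title: "Methods: contamination-aware mitochondrial variant calling and mitotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contamination-aware mitochondrial variant calling and mitotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The calling model

mitovar starts from per-site nucleotide-composition tables: for each
accession and each position of a shared mitochondrial reference, the read
depth and the counts of A/C/G/T and indel-supporting reads. This is the
natural summary of a short-read pileup after mapping, and it is the only
sequencing-derived input the package consumes — mapping itself, base-quality
recalibration and assembly are out of scope.

The central assumption is that read depth identifies the origin of the
mapped reads. In plant whole-genome sequencing, plastid DNA is present at
far higher copy number than mitochondrial DNA, and nuclear genomes carry
insertions of mitochondrial sequence (NUMTs) whose mitochondrial counterpart
may be absent from a given accession. Reads from both sources mis-map onto
mitochondrial homologies, producing three depth classes at roughly ~3000x
(plastid), ~100x (genuine mtDNA) and ~5x (NUMT-only). The filter is a depth
window with *exclusive* boundaries:

* retained iff `20 < depth < 900` — depth exactly 20 is dropped as NUMT
  class, depth exactly 900 as plastid class. The boundary semantics are
  deliberate and tested at 20/21 and 899/900.

At retained-depth sites, the consensus is the most frequent base, with
frequency computed over the total depth (indel reads count toward depth but
never toward consensus identity). A site is missing for an accession when

* the consensus frequency is ≤ 0.80 (exactly 80 % is dropped — mixed
  mapping, NUMT alleles, or real heteroplasmy, none of which are usable for
  phylogeny), or
* indel-supporting reads are the plurality call.

Ties between bases can never satisfy a threshold above 0.5, so no special
tie-breaking is needed; they fall out as low-consensus. Each missing call
carries a provenance flag (`depth_low`, `depth_high`, `low_consensus`,
`indel_majority`), and for every accession retained + missing = reference
length.

A site enters the cross-accession SNP matrix only when *no* accession is
missing there and at least two distinct bases occur. Missingness is
evaluated before polymorphism, so a site that is variant only through an
accession that failed the filters is dropped as missing data rather than
counted as a SNP. This ordering makes the call set conservative: every
retained column is complete and indel-free.

Reference refinement uses the same machinery on a single deep pileup: at
sites that pass depth and consensus rules, the consensus base replaces the
reference base; everywhere else (including the very high-depth
plastid-homology class) the original base is kept, so cpDNA alleles never
enter the refined reference. The depth window is configurable because the
appropriate plastid bound depends on sequencing depth; `filter_config()`
defaults to the 20/900 window and can be loosened (e.g. a 10000 plastid
bound for a very deep single-accession run).

SNP density is summarised in non-overlapping windows anchored at position 1,
1-based inclusive (1–1000, 1001–2000, ...), the convention in which windows
such as 50001–51000 are reported in organellar genome scans.

## Structure analyses

The SNP matrix is exported as a concatenated-SNP multi-FASTA (one record per
accession) and as VCF v4.2 with haploid GT fields, both of which round-trip
losslessly and are readable by standard tools.

For distances and PCA the matrix is encoded as binary non-reference-allele
indicators: one 0/1 column per (site, non-reference allele) pair, ordered by
position then allele. The encoding is the simplest defensible choice for
haploid SNP data fed to Bray–Curtis distances and is documented precisely so
results are reproducible; other encodings (allele-frequency weighting,
genotype dosages) would change numeric results on real data and are out of
scope.

* **Bray–Curtis / UPGMA.** `bray_curtis(u, v) = Σ|uᵢ−vᵢ| / Σ(uᵢ+vᵢ)`; a
  pair of all-zero vectors (two accessions identical to the reference at
  every encoded allele) is defined as distance 0 with a warning. UPGMA uses
  the size-weighted average-linkage update; exact ties in the minimum
  inter-cluster distance are broken by the first pair in scan order
  (smallest cluster index, which for leaves is the smallest leaf index), so
  merges are fully deterministic. Dendrogram node heights follow the
  ultrametric convention — half the merge distance — with the raw merge
  distances retained alongside; the hand-worked three-taxon example
  (d(A,B)=0.2, d(A,C)=d(B,C)=0.8 → heights 0.1 and 0.4) pins the convention
  in the tests. Flat clusters cut the k−1 highest merges and are renumbered
  so cluster 1 contains the smallest leaf index.
* **PCA** is performed on mean-centred (not scaled) indicators via the
  singular value decomposition; component signs are fixed by making the
  largest-magnitude loading positive. Zero-variance input is an error since
  explained proportions are undefined.

## The phylogenetic tree

Distance-based neighbor joining with Jukes–Cantor-corrected distances
replaces heuristic maximum-likelihood search. This is a deliberate design
decision: ML tree search is an external-tool capability with many
implementation-specific heuristics, whereas Saitou–Nei neighbor joining is a
fully specified algorithm that can be tested exactly — it provably recovers
additive distance matrices, which the test suite exercises against both a
naive re-implementation and exhaustive topology enumeration at five taxa.
The cost of this substitution is that clade topology among weakly separated
groups may differ from an ML tree on real data; bootstrap supports are the
guard against over-reading such branches.

Details fixed by the implementation contract:

* Q-criterion ties are broken by the first pair in scan order, making the
  agglomeration deterministic.
* Negative branch lengths are clamped to zero with the deficit moved to the
  sibling edge, preserving the path length between the joined nodes.
* JC69 distances `−(3/4)·ln(1 − 4p/3)` saturate at p ≥ 0.75; such pairs are
  clamped to 5.0 substitutions/site with a warning. On short alignments a
  resampled between-group distance can cross the saturation point even when
  the point estimate does not, which depresses bootstrap supports; the
  p-distance model is available for such regimes.
* Bootstrap resamples alignment columns with replacement; support is the
  percentage of replicate trees containing each internal bipartition of the
  point-estimate tree (classic Felsenstein style, reported on the point
  topology rather than a majority-rule consensus). Replicates are a pure
  function of the seed.
* Rooting is on a user-named outgroup; clade membership expands named
  exemplar sets to the smallest monophyletic group containing them, flagging
  exemplar sets that swallow exemplars of competing definitions.

## CMS gene screening

Queries are CMS-associated gene sequences (for Owen-type beet CMS, the
1161-bp *preSatp6* extension of *atp6*; *orf129* for E-type; the *cox1*
extension for G-type); the tool accepts any A/C/G/T FASTA query, and all
bundled test queries are synthetic. The search is seed-and-extend local
alignment on both strands: exact 15-mer seeds select candidate diagonals,
the maximal-scoring ungapped segment (match +1, mismatch −2) is found per
diagonal, and a banded affine-gap dynamic program (open −5, extend −2, band
16) refines the hit when the ungapped alignment leaves room for an indel to
pay off — with substitution-only divergence the ungapped segment is already
optimal because a gap pair costs more than the mismatches it could save.
The best hit maximises alignment length (aligned query span), then minimises
mismatches; gap columns are excluded from the mismatch count. The suite
checks exact agreement with a Smith–Waterman oracle (Biostrings) under the
same scoring on every synthetic carrier.

Classification follows the printed two-regime rule: **present** iff the
alignment spans the full query length with ≤ 3 mismatches; **-like** iff it
is shorter with ≥ 8 mismatches; no reportable hit is **absent**. Hits with
4–7 mismatches, or full-length hits with ≥ 8, fall in neither regime; the
package emits a fourth label, **ambiguous**, rather than forcing a side,
since the two rules were stated on disjoint observed regimes. Accessions
without assembled contigs are recorded as `no_contigs` and excluded from
per-gene denominators.

## Geographic association

Clades map onto two large mitochondrial groups (GroupA = clades 1, 2,
4A–4D; GroupB = clades 3, 4E–4H); accessions with unknown coast or unmapped
clade are excluded and counted. The two-sided Fisher exact p-value sums the
hypergeometric probabilities of all margin-preserving tables whose
probability does not exceed the observed table's — the minimum-likelihood
rule used by mainstream statistics tools; sidedness is an assumption
validated by reproducing the published p-value of 2.97 × 10⁻¹⁹ on the
bundled survey counts. Probabilities are computed in log space via `lgamma`,
and float ties are resolved with a relative tolerance of 10⁻⁷, which the
exact-rational oracle in the test suite applies identically. The tolerance
avoids platform-dependent inclusion of knife-edge tables; a zero margin
returns p = 1 with a warning.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions the pipeline targets:
depth means 3000/100/5 for the plastid, mitochondrial and NUMT classes, with
Poisson-distributed per-site depths (the simplest count model with the right
mean–variance behaviour for "~" depth classes). Haplotypes follow an
infinite-sites substitution model — each SNP position used once, uniform
random alternative base — with clade-diagnostic SNPs shared by all clade
members and optional accession-private SNPs. Plastid and NUMT regions carry
fixed divergent alleles so that misclassification of contamination is
detectable. Heteroplasmic sites split reads between the haplotype base and a
minor allele at a configurable fraction (default minor frequency 0.25, which
yields a 75 % consensus — below the 80 % rule, so such sites are filtered;
the default heteroplasmy rate of 0.01 is a free parameter, chosen as a
plausible per-site artifact rate rather than taken from any measured value).

Defaults chosen by the package where no external value exists: a 20-kbp
reference (a scaled-down organellar genome; real beet mtDNA is ~369 kbp, but
recovery behaviour does not depend on genome length once the depth classes
and SNP counts are fixed), one 1000-bp plastid region, one 500-bp NUMT
region, and true SNP positions drawn outside contaminated regions so that
ground-truth recovery is well defined. Coordinates are 0-based half-open
internally and 1-based inclusive in all file output.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: read-level errors and quality structure,
mapping ambiguity in repeats, structural variation and genome rearrangement,
recombination between mitotypes, true biological heteroplasmy dynamics, and
depth covariation along the genome. The generator validates the *logic* of
the pipeline (filters, recovery, classification rules), not the adequacy of
the 20/900/80 % thresholds for any particular sequencing design.

## Problem sizes and numerical tolerances

The test suite runs entirely on simulated data at sizes chosen to exercise
each property while staying quick: a 12-accession, 5-kbp cohort shared
across modules; a 40-accession, 20-kbp cohort with 200 diagnostic SNPs for
the end-to-end recovery checks (exact SNP-set recovery, adjusted Rand index
1.0 at k = 4, all clade bipartitions ≥ 95 % over 100 bootstrap replicates);
200 random 8-taxon matrices for the UPGMA/NJ oracle-equivalence suites; 500
random tables with total ≤ 40 for the Fisher oracle (agreement to 10
significant digits); and 50 randomized CMS carriers (zero classification
errors, exact Smith–Waterman agreement). Oracles are independent of the
implementations they check: naive O(n³) re-scans for the clustering and
joining algorithms, exhaustive topology enumeration with least-squares fits
at five taxa, exact rational arithmetic for the Fisher test, and a
library Smith–Waterman for the gene search. Floating-point comparisons use
1e-12 for algebraic identities and 1e-10 for round-tripped branch lengths.

## Known limitations

* The consensus caller reports at most one base per site; within-accession
  allele fractions are summarised only through the consensus frequency, so
  true heteroplasmy is (intentionally) treated as missingness, never
  quantified.
* The indicator encoding and distance/PCA conventions are one defensible
  choice among several; absolute coordinates of scores or dendrogram shapes
  on real cohorts depend on that choice.
* Neighbor joining is not maximum likelihood; weakly supported branches are
  method-sensitive.
* The gene search assumes substitution-dominant divergence; homologues with
  many indels inside the banded width are refined, but rearranged or
  fragmented copies across multiple contigs are reported only via the best
  single local hit.
* The Fisher test covers the 2×2 design only; per-clade tables, odds-ratio
  intervals and multiple-testing corrections across clades are out of scope.
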