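---
title: "Discovering hidden splice junctions with personal genome alignment"
author: "hiddensplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering hidden splice junctions with personal genome alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiddensplice)
```

## The problem

Spliced RNA-seq aligners rely on the canonical splice-site dinucleotides —
GT..AG for ~99% of mammalian introns, with GC..AG and AT..AC as minor
classes — to place reads across splice junctions. When a SNP creates a
splice-site dinucleotide that exists only in an individual's genome, the
junction reads produced from that site cannot be aligned to the reference
genome: the motif simply is not there. These "hidden" splice junctions are
invisible to reference-based RNA-seq analysis.

The remedy implemented here is to align each individual's reads to their own
genome. From a phased SNP VCF we substitute each haplotype's alleles into
the reference, producing two personal genomes (hap1, hap2) with unchanged
coordinates (SNVs only, so no liftover is needed). Reads are aligned to the
reference and to both personal genomes; a junction reported solely in the
hap1 alignment is *hap1-specific*, solely in hap2 *hap2-specific*, in both
haplotype alignments but not the reference *hap1hap2-specific*. Their union
is the set of personal-specific junctions. The mirror category —
junctions reported solely in the reference alignment of reads that fail to
map to either personal genome — estimates the false-positive rate of the
whole procedure, because no biological mechanism should produce them from
reads generated by the personal genome.

## Alignment contract

The pipeline does not align full-scale data itself; it ingests SAM/BAM from
an external spliced aligner and *enforces the contract* that makes the set
logic sound:

* zero mismatches within reads (so allele-carrying reads cannot
  cross-align), at most 20 reported hits;
* spliced alignment only across canonical motifs, maximum intron
  300,000 nt, minimum junction overhang 12 nt;
* truncated reads, and mates of truncated or unmapped reads, count as
  unmapped (`classify_read_mapping`; what "truncated" means in SAM terms is
  not standardised, so the default policy — any soft/hard clipping —
  is exposed as `max_clip`).

For tests and toy data the package bundles `align_reads`, an exact-match
brute-force spliced aligner that realises this contract honestly at desk
scale: a read aligns iff it matches contiguously, or across exactly one
enumerated canonical-motif gap with both anchors ≥ 12 nt and zero
mismatches. It is deliberately slow and simple — its job is fidelity, not
throughput — and refuses nothing silently: any unexplained read is reported
unmapped, exactly as the contract demands.

## Junction representation and identity

A junction is stored as the 1-based coordinates of the first and last
intronic base, the convention of splice-junction tables emitted by common
spliced aligners. Identity is the coordinate triple (chrom, start, end)
*only*: strand and motif are deliberately excluded, because the same
coordinates legitimately receive different motif calls on the reference and
a personal genome — that difference is the phenomenon under study. Support
is counted as *distinct* leftmost alignment positions, which collapses PCR
stacks; raising the overhang can only lower this count (a property the test
suite asserts). Motifs are read from the genome named by each set's label,
and the three minus-strand patterns seen on the forward strand (CT..AC,
CT..GC, GT..AT) imply the minus strand.

## Filters

Personal-specific junctions must be supported by at least 2 distinct reads,
and must carry a sample SNP inside one of their four splice-site
dinucleotide positions; everything else may reflect mapping artifacts of
SNPs elsewhere in the reads (the simulator plants exactly this confounder
with its `n_elsewhere` events, and the filter removes them). The two
filters commute — asserted as a property test. A junction whose coordinates
exactly match an annotated intron (from the GTF, via transcript-wise exon
gaps) is *known*, anything else *novel*; a coordinate match with
conflicting strand is flagged but still counted known, since strand
inference from a single motif can fail on short non-canonical contexts.

In the reverse (false-positive) direction the same filters are applied
symmetrically by default. Whether the original procedure also imposed the
splice-site-SNP filter on reverse-run junctions is unknowable from the
outside; symmetry is the defensible default and the asymmetric behaviour is
available via `apply_to_hg19` in `filter_splice_site_snp_junctions`.

## Usage quantification

For a personal junction with PSJ distinct reads, and OSJ the summed
distinct reads of all annotated junctions whose introns overlap it by at
least one base, the relative usage is PSJ/(PSJ+OSJ), computed only in the
junction set of the genome where the personal junction was identified (a
junction expressed from hap2 must not be diluted by hap1's reads).
Cross-individual reporting is the unweighted mean over individuals in which
the junction was detected, plus a detection frequency: the fraction of
splice-site-SNP carriers showing the junction.

Usage is only interpretable when the competition is well defined, so the
alternative-splice-site subset additionally requires: exactly one expressed
overlapping reference junction sharing exactly one splice site; a combined
PSJ+OSJ of at least 10 distinct reads; and a homozygous splice-site SNP
(in a heterozygote the non-carrier haplotype manufactures reference reads
that say nothing about the carrier allele). "Expressed" means at least one
distinct read in the same genome's junction set; no separate cutoff is
imposed. The offset between the shared-site partners feeds the frame-shift
predicate: the pair is potentially frame-shifting iff the offset is not a
multiple of 3 (a 3-nt NAGNAG tandem acceptor is the canonical in-frame
case, producing a single-codon difference).

## Maximum-entropy splice-site scoring

Site strength is scored with maximum-entropy models in the MaxEntScan
architecture: the 5' model scores a 9-mer (3 exonic + 6 intronic bases)
with consensus-position odds for the near-invariant GT and a joint
maximum-entropy distribution over the remaining 7 positions; the 3' model
scores a 23-mer (20 intronic + 3 exonic), with the consensus AG removed and
the remaining 21 positions scored by a product/quotient of block
probabilities (blocks 1–7, 8–14, 15–21, 5–11, 12–18 over blocks 5–7, 8–11,
12–14, 15–18). All scores are log2 odds against an i.i.d. background
(A/T 0.27, C/G 0.23), in bits, rounded to two decimals only for display.

Two implementation facts matter for interpretation:

1. **The fitting machinery is real.** `fit_maxent_block` computes the
   maximum-entropy distribution subject to arbitrary first- and
   second-order marginal constraints by iterative proportional fitting over
   the full 4^k state space, to a marginal tolerance of 1e-10. The test
   suite verifies that fitting a model's own marginals returns the model,
   and that scoring agrees with independent string-space and full-chain
   oracles to machine precision. The 3' block decomposition is the exact
   junction-tree factorisation for chain-structured dependence, and the
   tests confirm it reproduces the direct 21-mer joint probability.
2. **The bundled parameters are synthetic.** The shipped tables
   (`inst/extdata/maxent_synthetic`, md5-checksummed; loading fails hard on
   any mismatch) are exact marginals of a documented generative model:
   position-specific frequencies reflecting mammalian donor/acceptor
   consensus, a donor coupling between the exonic −1 and intronic +5
   positions, and a pyrimidine-tract Markov chain with run-reinforcing
   adjacent couplings. Scores are therefore internally consistent and
   fully reproducible, and Δ scores (personal − reference) have the
   correct sign semantics, but absolute values are **not comparable to
   scores from models trained on human splice-site alignments**. Published
   worked-example values from such models will not be reproduced, and the
   test suite records this honestly rather than papering over it.

When a splice-site SNP falls inside the reference site's scoring window,
the reference sequence is modified to carry the personal allele before
scoring (`reference_adjusted_for_snp`), so Δ isolates the choice of site
from the allele difference — this is what makes acceptor-swap geometries
(reference site corrupted, new site 1 nt downstream) score sensibly.
Windows containing ambiguous bases are reported unscored rather than
imputed.

## Haplotype LD and GWAS linking

Because the input is phased, r² between a splice-site SNP and a GWAS
catalog SNP is computed directly from haplotype frequencies,
(p_ab − p_a·p_b)² / (p_a(1−p_a)·p_b(1−p_b)), with no EM step; on phased
data this equals the squared Pearson correlation of the allele vectors
(asserted to 1e-12 against brute force). Monomorphic loci are reported
missing. The catalog is a user-supplied TSV (snp_id, chrom, pos, p_value,
trait) filtered at p < 1e-3 and deduplicated by (snp_id, trait) keeping the
smallest p. Links are emitted above r² > 0.8; a splice SNP that is itself a
catalog SNP self-links with r² = 1. Candidates are restricted to the same
chromosome within 1 Mb by default — an engineering bound, not a statistical
choice — with `window_bp = Inf` available for chromosome-wide search.

## The simulator: what it emulates, and what it does not

`simulate_scenario` builds a toy genome of three-exon genes (exons
130–180 nt, introns 150–280 nt, alternating genomic strand so minus-strand
motif logic is always exercised), plants splice-site events with a chosen
zygosity mix, and emits paired-end 60 nt reads (140 nt fragments) with
distinct jittered junction-spanning starts, plus a truth table. Planted
event types: donor creation at an offset inside the intron; acceptor
creation upstream of the reference acceptor; a NAGNAG tandem acceptor 3 nt
downstream; an acceptor swap (reference site corrupted, new site 1 nt
downstream); donor destruction (the reverse-run false-positive mechanism);
and elsewhere-in-read exonic SNPs (the splice-site-SNP filter's target).
Default conditions: coverage 6 distinct starts per junction, a 1:1
personal:reference read ratio (so expected usage 0.5), one planted
duplicate start to exercise distinct-read counting.

Deliberate non-realism: no sequencing errors or quality scores, no indels,
fixed fragment length, no expression-level variation, no multi-isoform
genes beyond the planted pairs, and genome sizes of tens of kilobases.
Consequently, passing tests demonstrate the correctness of the set logic,
filters, counting and scoring mechanics under the stated alignment
contract — they do not demonstrate robustness to alignment noise, repeat
sequence, or annotation incompleteness in real genomes.

## Numerical and design choices

* Coordinates are preserved exactly by SNV-only personalization;
  ref-mismatching VCF records are skipped with a warning (chromosome
  naming and patch differences are common), two records at one position
  are a hard error, and "chr"-prefix differences are auto-reconciled.
  Half-missing phased genotypes (".|1") are skipped and counted.
* Soft-masked (lowercase) reference input is accepted and REF alleles are
  checked case-insensitively; output genomes are uniformly uppercase (the
  DNA containers normalise case at construction).
* Multi-mapped alignment lines all contribute support; the distinct-start
  rule bounds double counting.
* Intron length bounds (20 nt minimum by default) separate true gaps from
  deletions; junction dinucleotide lookups fail loudly if a chromosome is
  absent.
* The three worked-example locus reconstructions (`worked_example_loci`)
  carry published site *geometries* (acceptor 5 nt upstream; GC→GT donor
  activation; acceptor swap 1 nt downstream) in synthetic sequence
  context, and the discovery pipeline recovers the offsets from reads.
* Test problem sizes: scenarios of 6–12 genes (9–15 kb genomes), 10,000
  random CIGARs against the one-base-at-a-time oracle, 1,000 random LD
  panels, 100 usage-recovery replicates, 50-sequence scorer panels.

## Limitations

Indels and structural variants are rejected at ingestion (extending
personalization beyond SNVs would break coordinate identity and is future
work). The scorer offers no weight-matrix or first-order-Markov fallback
modes, no branch-point or enhancer/silencer scoring. The LD stage performs
no population-stratification handling. The bundled aligner must not be
used beyond toy scale; production data should come from a real spliced
aligner configured to the contract above.
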