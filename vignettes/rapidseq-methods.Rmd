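---
title: "rapidseq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rapidseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidseq)
```

rapidseq reimplements, at desk scale, the computational stack of a rapid
clinical whole-genome sequencing workflow: a hash-index short-read
mapper, a haplotype-based small-variant caller, an ACMG-style variant
categorizer, and a phenotype- plus inheritance-driven trio interpreter,
together with a synthetic-data generator and a concordance evaluator so
the whole chain is testable without any external download. This
vignette explains the models, the tunable parameters, and the design
choices made where the design was genuinely open.

## The hash index and dynamic seed extension

The reference is indexed by its primary seeds (21-nt substrings,
forward strand only). A seed occurring at more than `max_hits` (16)
locations is not stored as a hit list; instead an EXTEND record tells
the query to join `ext_increment` (3) nt of flanking read sequence onto
each side and re-query with the longer seed, iteratively, up to 64 nt
per side — a maximal extended seed of 21 + 2×64 = 149 nt. Seeds that
remain high-frequency at the cap are stored as a marker and return no
hits: an uninformative seed is better ignored than allowed to spray
candidates. Reads with too few flanking bases to satisfy an EXTEND
record receive the same marker. Hits are recorded at the forward-strand
start of the *primary* seed, which keeps alignment diagonals consistent
during chaining; occurrences too close to a contig edge to extend
symmetrically are dropped from extended groups.

Keys are exact strings rather than packed hashes. At desk scale memory
is irrelevant, and exact keys make the index directly checkable against
a naive substring scan, which the test suite does. Index construction
is deterministic: the serialized dump is byte-identical across rebuilds.

## Mapping

Seeds are extracted at every even read offset (50% density), queried in
both orientations, and grouped into chains by exact alignment diagonal
(reference position minus read offset). Nearby diagonals are *not*
merged; chains on different diagonals survive independently and are
reconciled by alignment, the simplest rule that is still testable. A
chain is filtered when another chain at least four times longer
overlaps more than half of its read span ("mostly overlaps" is not
defined by the original description; we fix it at >50%).

Each chain is extended by gapless alignment on its diagonal: per-base
match/mismatch scores with the best contiguous segment kept (a Kadane
scan), the rest soft-clipped. Smith-Waterman (full O(mn), affine gaps,
traceback to CIGAR) runs when the gapless score falls below
`trigger_fraction` (0.9) of the perfect score or an end clip exceeds
`clip_trigger` (5 nt). Scoring defaults (match 2, mismatch 3, gap open
5, gap extend 1, unclipped bonus 5) are BWA-MEM-like; the source
pipeline publishes none. The software aligner is deliberately
full-matrix — a hardware wavefront is an implementation detail, not a
contract.

Pairing examines all candidate combinations: a proper pair is
forward–reverse on one contig with an implied insert inside
mean ± 4 sd. The pair score is the sum of alignment scores minus a
penalty of one point per sd of insert deviation (capped at 30, which is
also the improper-pair penalty). The insert model is fitted from the
first 10,000 proper pairs aligned without rescue, falling back to the
configured mean/sd (350/50). For an unpaired chain, a rescue scan
searches the expected mate window for the mate's leading 24-mer within
Hamming distance 3; matches become candidate positions that are then
aligned like any chain (the original description is ambiguous about
whether rescue adds chains or alignments; we add positions, then
align).

MAPQ is `clamp(round(mapq_coeff/L · (S1 − S2)) − β·log2(1 + N2), 0,
60)` with `mapq_coeff` 6.0, β 2.0, and N2 the number of candidates
scoring within 2 of the second best; a read with no second-best
candidate takes the cap. The published coefficient schedule "varying by
read length" is not disclosed, so this α(L) = 6/L is our stand-in,
stated in configuration. One wrinkle matters: a candidate that places a
mostly *disjoint* segment of the read (a chimeric segment, e.g. the far
side of a deletion junction) is not an alternative placement and is
excluded from S2 — otherwise every junction-spanning read would be
punished for its own split. Reads whose primary alignment covers less
than 80% of the read emit up to three supplementary records.

## Duplicates

Read pairs sharing both mates' 5'-unclipped positions and orientations
(clip-adjusted, the usual Picard criterion — the source describes no
criterion) form a duplicate group; the highest pair-score member stays
unflagged, ties broken by read id. Optical duplicates are out of scope:
no tile coordinates are modeled.

## Variant calling

Callable columns have ≥ `min_depth` (4) reads at MAPQ ≥ 20, duplicates
excluded. Active regions are maximal runs of callable columns where the
non-reference evidence fraction (mismatches, indels, soft-clip
boundaries of ≥5 nt) reaches 0.15 with at least 3 supporting reads —
the absolute floor keeps isolated sequencing errors at low depth from
triggering assembly. Runs are padded 50 nt, 150 nt when they carry
indel evidence, and merged.

Reads assigned to a region (including, for assembly only, unmapped
reads whose mate landed nearby — both orientations are added since
their strand is unknown) are decomposed into k-mers over the reference
backbone. "Degenerate" is concrete here: duplicated backbone k-mers, a
cycle reachable from the source, or no source-to-sink path; a
degenerate graph is rebuilt at the next k in {10, 25, 40, 55}.
Non-reference edges seen fewer than 2 times are pruned. Source-to-sink
paths become haplotypes, capped at 128 preferring higher-weight paths;
a path's weight is the minimum edge count along it (the original
leaves sum-vs-min unstated). Each haplotype is globally aligned back to
the reference segment with a gentle long-gap scheme (gap open 6,
extend 0.2) so a single long indel beats a run of mismatches, and its
events are left-normalized. Indels longer than 470 nt are discarded as
assembly artifacts; the cap is configurable and motivated by the
largest events the emulated pipeline observed (263-nt deletion, 469-nt
insertion), both of which the test suite recovers from 40× reads.

P(r|H) is a pair-HMM forward sum over all alignments — global in the
read, local in the haplotype (uniform start prior over columns, free
end). Mismatch probabilities come from base qualities capped by MAPQ;
gap opening uses a PCR error model keyed to homopolymer run length,
`10^-(4 − 0.5·min(run, 6))`, gap extension 0.1. The published error
model is undisclosed; this stand-in is overridable in
`caller_params()`. Reads are *not* trimmed to the region before HMM
evaluation: junction reads carry their evidence for long insertions in
soft-clipped bases that trimming would discard, and the cost of
read overhang beyond the haplotype window is (to first order) the same
for every haplotype of the region, so it cancels in the genotype
posterior.

Genotyping scans event positions. P(r|e) is the maximum P(r|H) over
haplotypes supporting the event (supporting the reference = carrying no
event overlapping the position); a diplotype's per-read likelihood is
the even mixture ½P(r|e1) + ½P(r|e2); only reads overlapping the
position multiply into P(R|e) (the alternative — all region reads — is
not stated in the source; overlap is the defensible choice). Priors:
1 − θ for homozygous reference, θ = 0.001 split evenly across
non-reference diplotypes. The winner is emitted with genotype quality
−10·log10(1 − posterior), capped at 99.

## Annotation and interpretation

Consequences come from transcript geometry and codon translation:
intronic ±1–2 are splice disruptions, acceptor −3..−20 the
polypyrimidine tract, intronic >20 nt deep intronic; exonic positions
translate through the spliced CDS, with the most severe consequence
across transcripts kept. Categories: 1 known disease-causing, 5 known
benign (known status wins — a known-benign truncating variant stays 5),
4 for variants at MAF ≥ 0.02 ("commonly observed" has no published
number; 2% is ours), 2 for truncating/splice-disrupting types, 3 for
possibly-causal types including synonymous variants that create a
GT/AG dinucleotide within 3 nt (a deliberately simple cryptic-splice
proxy), 4 otherwise.

The interpreter ranks diseases by the count of matching patient HPO
terms (ties alphabetical), unions their genes, and filters trio
variants by category set, strict MAF cutoff (or warehouse absence in
uniqueness mode), and inheritance: de novo requires both parents
reference at GQ ≥ 30 everywhere; recessive accepts homozygotes with
carrier parents, X-hemizygotes in males, or two heterozygotes in one
gene inherited in trans, one per parent; dominant candidates follow an
affected-only model and must also be de novo unless a parent is flagged
affected. A missing parental genotype marks a pattern unresolved rather
than excluded. Semantic-similarity (Phenomizer-style) ranking is out of
scope; match-count ranking is the engine.

## The synthetic data generator

The generator defines the study conditions rather than adapting to
them: 2×101-nt pairs, insert ~ Normal(350, 50) truncated at twice the
read length, SNVs at 10⁻³/nt, indels at 1.25×10⁻⁴/nt with geometric
sizes (mean 3, capped at 470), events half heterozygous / half
homozygous, i.i.d. substitution errors at 0.2% with constant reported
Q30 (optionally a linear 3' decay), uniform fragment placement.
Overlapping event draws are dropped rather than re-drawn — at these
rates the difference is negligible. What it does *not* emulate:
GC-dependent coverage bias, indel sequencing errors, quality-correlated
error clustering, optical duplicates, and repetitive genome structure
(the reference is uniform random, so seeds are almost always unique and
MAPQ is near-saturated). Passing tests therefore demonstrate
correctness of the machinery under clean conditions, not performance on
a repeat-rich human genome.

Concordance matches records on (contig, position, reference, alternate)
after left-normalizing both sets against the same reference; the
genotype-level comparison additionally requires the called zygosity.
Specificity needs a denominator the source never defines; we use
confident-region non-variant positions (genome length minus truth
count), stated in the report header.

## Problem sizes and numerical choices

The shipped acceptance analyses use a 250-kb diploid genome at 40× and
20× (≈50,000 and 25,000 read pairs), a 50-kb genome for the 10–40×
depth titration, and a 30-kb genome for structural-event recovery —
sizes chosen so the full suite re-runs in minutes while keeping ≈300
planted events per genome, enough to resolve sensitivities near 99.5%.
The pair-HMM runs in linear probability space with a 10⁻³⁰⁰ floor
(region-scale reads never approach it); Smith-Waterman ties break
toward the earliest reference position, then fewest gap openings;
alignment candidates within 5 nt of an existing candidate are
deduplicated. Diplotype posteriors are normalized in log10 space with a
max-shift.

## Known limitations

Single-sample calling only (no gVCF, no joint genotyping); no VQSR by
design — the emulated workflow rejects it for rare-disease use;
structural variants beyond the assembly window and repeat expansions
are out of scope, as are pseudogene disambiguation and optical
duplicates. The annotator's splice model is geometric, not spectral;
the interpreter's differential is a counting engine, not a semantic
one. The simulator's uniform random reference understates the mapping
difficulty of real genomes.
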