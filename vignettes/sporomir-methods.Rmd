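---
title: "Methods: small-RNA discovery and temperature-dependent miRNA profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA discovery and temperature-dependent miRNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sporomir` re-implements, as a single testable pipeline, the in-silico
procedure used to characterise conserved and novel microRNAs in small-RNA
libraries from conifer somatic embryos grown at three epitype-inducing
temperatures (18, 23, 28 °C), to call temperature-dependent differentially
expressed miRNAs (DEMs), to predict their mRNA targets, and to select
anti-correlated miRNA–target pairs, including those hitting epigenetic
regulators. Because the original sequencing data are at a scale (tens of
millions of reads, a 20-Gb genome) that is neither necessary nor practical
for verifying the *method*, the package ships a synthetic-data module that
plants every structure the pipeline is supposed to find — MIR hairpin loci,
isomiR variants, temperature-structured expression, anti-correlated target
sites — into a toy genome, so each stage can be scored against a known
answer key.

## The pipeline stage by stage

### Preprocessing

Reads from the 18 libraries (2 genotypes × 3 maturation stages × 3
temperatures) are collapsed into distinct sequence tags with per-library
counts. Tags are filtered to 19–27 nt (both bounds inclusive — the idiomatic
reading of a "19–27 nt" range) and sequences whose *pooled* total across all
libraries is 1 are removed as likely sequencing or stochastic errors.
Pooling before singleton removal was an open choice; we pool because
discovery itself operates on reads pooled over libraries, and a per-library
mode is available (`drop_singletons(per_library = TRUE)`). A conservation
identity (reads in = reads with N + length-filtered + singletons + survivors)
is tracked and asserted in the tests.

### Conserved annotation

Tags are compared to a reference mature set (in real use, a miRBase-style
FASTA plus family table; in simulation, the planted "conserved" guides) by a
sliding *ungapped* alignment: end offsets up to ±4 nt at either end, at
least 17 nt of overlap, and at most 2 substitutions inside the overlap. The
±4/17 envelope is our instantiation of "up to 2 mismatches" matching that
must also tolerate isomiR end variation; the tie-break (fewest
substitutions, then smallest total end offset, then lexicographically
smallest reference id) is fixed for determinism. Every distinct tag that
matches the reference is counted as a conserved miRNA — this deliberately
treats isomiRs as first-class miRNAs, which is how family member counts in
this literature are tallied. Each hit's modification is classified from its
offsets: negative offsets are trims; positive offsets are extensions, split
into templated (the flanking genomic bases match) versus nontemplated 3′
tails, with uniform `T` runs called uridylation and `A` runs adenylation.
Without genomic context the extension is reported as "template-unknown"
rather than guessed.

### Novel discovery

Tags are mapped to gene-model sequences on both strands, ungapped, with up
to 2 mismatches (a pigeonhole 6-mer seed index; the tests prove equality
with a full Hamming scan). Multi-mapping tags contribute fractionally
(1/k per placement) to locus totals, but full counts to expression — the
quantification follows the per-miRNA annotation, not the per-locus one.
Overlapping placements on one strand merge into read stacks, and a stack
with ≥100 (fractional) mapped reads becomes a candidate locus. The phrase
"at least 100 reads of distinct tags" is ambiguous between total reads and
distinct tags; we implement total reads, configurable via
`min_locus_reads`.

A folding window grows around the stack's modal tag from 80 nt of flank per
side to 300 nt in 20-nt steps, then more coarsely until the window reaches
1 kb, stopping at the first window whose fold validates. Folding is a
weighted maximum-pairing dynamic programme (GC = 3, AU = 2, GU = 1, hairpin
loop ≥ 3 nt) with a deterministic traceback — not a thermodynamic model.
We chose it because it is self-contained, exactly verifiable against
brute-force enumeration (a property the tests exercise on all windows
≤ 14 nt), and sufficient to recover designed hairpins; an external
thermodynamic folder could be slotted behind `fold_hairpin()`'s contract.

Duplex validation instantiates the community criteria for miRNA annotation
with explicit numbers: the guide must have ≥14 positions paired into one
stem arm, ≤5 positions outside the duplex, and ≤3 *asymmetric-bulge*
nucleotides; it must not span the terminal loop. Two subtleties matter in
practice. First, simple mismatches form *symmetric* internal loops and are
therefore not bulges; counting every interior unpaired base as a bulge
would reject hairpins with 3 designed mismatches, which the criteria are
meant to admit. Second, a maximum-weight fold of a window with random
flanks occasionally pairs one or two guide bases off-arm; up to 2 such
stray pairings are tolerated and treated as unpaired, since they are fold
noise rather than duplex structure.

The guide is the highest-count tag on the hairpin (ties broken to the
longer, then lexicographically smaller tag, logged); the star is the
highest-count opposite-arm tag within 6 nt of the theoretical star — the
guide's duplex partner span shifted rigidly by 2 nt toward the precursor 3′
end, the canonical 2-nt 3′-overhang geometry. Displacement is measured as
the larger of the two end offsets, so a rigid 6-nt shift is accepted and a
7-nt shift rejected; measuring "total" displacement as the sum of both end
offsets would make the stated 6-nt tolerance unreachable for rigid shifts.
If no tag qualifies, the theoretical star is emitted with count 0. Arm
labels (-5p/-3p) follow precursor geometry. Candidates whose guide is
conserved are routed out of the novel set; the rest are named
`Pab-miRn{serial}_{arm}`, with identical guides from multiple precursors
collapsed into one miRNA.

### Expression and differential calling

RPKM = count / (library size/10⁶ × length in kb), with library sizes taken
as post-filter read totals. The 18 libraries are condensed to 3 temperature
conditions × 6 replicates: genotype and stage are treated as replicates,
mirroring the temperature-centric contrasts of the study design. miRNAs
need a mean raw count ≥10 within at least one condition to be "expressed"
(the per-single-library reading is available via `per_library = TRUE`).

The pairwise test is Kal's Z-test on pooled proportions — the classic test
of the GUI package used in this literature; log2 ratios are computed on
condition-mean RPKM with a pseudo-value of half the smallest nonzero RPKM
to guard zeros. A miRNA is a DEM iff some contrast has |log2 ratio| > 1
*and* p < 0.05, both strict. No multiple-testing correction is applied by
default, matching the raw-p convention of the source analysis; a Fisher
exact alternative is available via `method = "fisher"`. The joint threshold
makes the caller conservative; the tests verify an empirical null DEM rate
≤ 7% on 500 miRNAs × 200 null replicates.

Profile clustering is deliberately not an algorithmic clustering: with
three conditions and per-contrast significance signs there are exactly 13
weak orderings of {18, 23, 28}, of which 12 are non-flat. Each DEM's sign
triple (direction if significant, else 0) is mapped to one of these 12
classes; sign triples that violate transitivity (possible because
significance gates each sign independently) are re-signed from the
condition-mean ranks and flagged. This reproduces a 12-cluster label space
structurally rather than by tuning a clustering algorithm.

### Target prediction and integration

Target scanning follows the plant target-server convention: an expectation
penalty E summing match 0, G:U 0.5, mismatch 1, gap 2, doubled at miRNA
positions 2–13 (the seed), with at most one gap and a default cutoff
E ≤ 3.0. Sites with any non-match at positions 9–11 are labelled
translational, others cleavage; the label is informational and does not
affect pairing. Only the best (minimum-E, leftmost on ties) site per
miRNA–transcript pair enters integration. The scanner is verified against
exhaustive alignment enumeration on small instances, and perfect-complement
sites always score 0.

Pairs are refined by Pearson correlation over the three temperature
condition means (miRNA RPKM means versus mRNA means). Pearson is the
default reading of an unqualified "correlation"; with n = 3, Spearman is
nearly degenerate. A pair is retained iff r < −0.6 (strict), the miRNA is a
DEM and the transcript a DEG; degenerate zero-variance profiles yield
undefined r and are flagged, never retained. Target transcripts carry an
optional annotation mapping them to one of eight epigenetic-regulator
categories (DNA methylation, histone methylation/acetylation/
phosphorylation/ubiquitination, chromatin remodeling, sRNA pathways,
thermosensing); summary tables census retained pairs per category and per
domain family.

## The synthetic experiment

The generator's defaults are the study conditions: 18 libraries (2
genotypes × 3 stages × 3 temperatures) of 100,000 reads each over a
200-kb genome with 300 gene models and 40 planted MIR loci. Each locus is
mature (20–22 nt) + loop (8–20 nt) + near-reverse-complement arm with 0–3
designed mismatches, embedded ≥300 nt from its host transcript's edges.
Hairpins are planted *inside* transcripts because discovery maps to gene
models only, exactly as the original analysis did — an intergenic hairpin
would be undiscoverable by construction. Half the guides are flagged
conserved and emitted as the reference mature set; star arms are sampled at
1/5–1/20 of guide abundance so the "higher frequency → guide" rule is
always decidable.

Read lengths mix point masses at 21, 22, 24 and 31 nt with a uniform
15–35 nt component, reproducing the tri-modal length profile of embryonic
small-RNA pools (the 31–32 nt class is simulated only as a length mode; its
biology is out of scope). 60% of reads derive from planted arms and 40%
are genome fragments; background fragments are real subsequences, not
random strings, so spurious stacks can and do reach the 100-read locus
threshold and the threshold is meaningfully exercised. isomiR variants
(substitution, 5′/3′ trimming, templated 3′ extension, nontemplated 3′ U/A
tails) are applied at configurable per-read rates, and uniform per-base
sequencing errors at 0.002 — desk-scale stand-ins for the error processes
the study filtered against, not an instrument error model.

60% of planted miRNAs get temperature-dependent profiles: a random non-flat
weak ordering spanning a 4-fold change (clearly above the 2-fold calling
threshold, below saturation). Each such miRNA receives one planted target
site — the reverse complement of its guide, possibly with 1–2 designed
mismatches outside the seed — in a distinct non-host transcript, 70% of
them regulator-annotated. The linked transcript's condition means are
constructed so that their Pearson correlation with the miRNA's expected
means is *exactly* the configured strength (default −0.9): the residual
direction is the orthogonal complement of the standardized profile in the
centered 3-point space. This makes "planted anti-correlation" a property of
the truth rather than a noisy aspiration, while the pipeline still sees
noise through counting error on the miRNA side. Unlinked transcripts get
independent profiles with random amplitudes, some of which are DEGs and
some flat.

What the generator does not emulate — adapter contamination, instrument-
specific error profiles, RNA secondary-structure biases in library
preparation, per-library depth variation, a realistic genome with repeat
families and miRNA gene clusters — bounds what passing tests show: they
validate the *method's* correctness and calibration, not its performance on
real conifer data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 output converts to
  1-based closed.
* The fold traceback prefers pairing over leaving a base unpaired on ties,
  scanning partners left to right, so structures are deterministic.
* `U` is normalised to `T` on input; reads containing `N` are discarded and
  counted, never silently dropped.
* Zero-variance expression profiles, empty tag sets, empty pair sets and
  zero-transcript genomes are all defined, tested paths.
* The pseudo-value for log ratios (half the minimum nonzero RPKM) is
  recomputed per expression matrix; with an all-zero matrix it falls back
  to 0.5.
* Sub-seeds for the generator's stages are derived linearly from the master
  seed and kept below 2³¹.

## Problem sizes used by the tests

The test suite and the acceptance script run the generator at its default
scale (18 × 100,000 reads, 40 loci) for the planted-recovery properties,
500 miRNAs × 200 replicates for the null calibration, 200 random sequences
of length ≤ 14 for the fold oracle, and 50 × 50 instances for the
matching/mapping oracles. These sizes were chosen so that every oracle
comparison is exhaustive and the planted-truth statistics are stable to a
few percent, while a full run stays comfortably within a desktop session.

## Known limitations

* The Nussinov-style fold maximises pairing weight, not free energy; on
  windows with pairing-rich flanks it occasionally pairs one or two guide
  bases off-arm or misses a designed pair, which is why guide recovery on
  planted truth is a few percent below 100 rather than exact.
* Kal's test treats pooled libraries as one proportion and therefore
  ignores replicate dispersion; it is anti-conservative for overdispersed
  real data. The joint fold-change threshold compensates at desk scale (the
  null calibration shows this), but a negative-binomial model would be the
  modern choice and is intentionally out of scope.
* With only three condition means, the Pearson correlation used for pair
  refinement takes a small discrete set of shapes; its strict −0.6 cutoff
  should be read as a coarse anti-correlation screen, not an inference.
* Cluster labels reproduce the 12-class label *space*; a mapping to any
  particular published cluster numbering would require the original data.
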