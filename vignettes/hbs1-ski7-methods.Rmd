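---
title: "Classifying HBS1/SKI7 isoforms and splice fates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying HBS1/SKI7 isoforms and splice fates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ski7tools)
```

## The biological problem

In most eukaryotes a single locus encodes both HBS1 — the translational
GTPase that, with PELOTA, rescues stalled ribosomes — and SKI7, the
adaptor that recruits the cytosolic RNA exosome to the SKI2/SKI3/SKI8
complex. The switch between the two is alternative splicing: a cassette
exon carries a short, deeply conserved SKI7-like motif (plant consensus
`A+SLFaaa[P/L]`), and a second conserved element, the Patch 4-like motif
(plant consensus `IaPFKFDaPSPDDhVxx`), sits immediately downstream.
Transcripts that include the cassette encode SKI7; transcripts that skip
it encode HBS1. A third fate exists: retention of the intron at the
cassette's 3' end introduces in-frame stop codons (a "poison intron"),
leaving the transcript unproductive and, because those stops sit upstream
of several exon-exon junctions, presumably a target of nonsense-mediated
decay (NMD). `ski7tools` implements each of those determinations —
degenerate motif scanning, five-region architecture annotation, splice
event detection, premature-stop analysis, and consensus derivation — as
testable, parameterized operations.

## The motif model

A degenerate consensus string is compiled into one residue set per
position. The notation's class symbols are resolved through a
configurable alphabet whose defaults are:

* `+` = {K, R}. Whether histidine counts as positively charged is left to
  the user (`residue_alphabet(plus = c("K","R","H"))`); the default
  excludes it, the conservative reading of the notation.
* `h` = {A, V, L, I, M, F, W, Y}.
* `a` = {A, V, L, I, G}. Glycine is included because the Arabidopsis
  SKI7-like motif `AKSLFGSVP` carries a glycine at an aliphatic position
  of the plant consensus; an alphabet under which the best-characterized
  plant motif mismatches its own lineage consensus at two positions would
  be self-defeating.

Scanning scores every window by its matched-position fraction and keeps
windows within a mismatch allowance. The defaults — 2 mismatches for
short (9-position) motifs, 3 for long (≥ 15) ones — reflect that even the
Arabidopsis motif scores 8/9 against the plant consensus, and that
cross-lineage orthologs diverge further; exact matching would reject real
SKI7 proteins. Overlapping hits are all reported; consumers resolve ties
by highest score, then leftmost position, keeping the scanner itself
pure.

## Architecture and isoform classes

Five detectors run per protein:

* **Acidic N-terminus** — the D/E fraction of the first 50 residues
  (window configurable). The region is called at a threshold of 0.25; the
  canonical Arabidopsis exemplar reaches 0.40, but grass SKI7 orthologs
  have a much shorter acidic stretch, so the default is deliberately
  permissive. The evidence value is always reported, so stricter
  downstream filtering loses nothing.
* **RanBP2-type zinc finger** — the four-cysteine spacing
  `C-x(2,4)-C-x(9,14)-C-x(2)-C`, the canonical profile for this domain
  family; all non-overlapping matches are reported so tandem duplications
  (as in the Solanaceae HBS1-only loci) yield two regions. Reported
  boundaries are pattern-match boundaries, not any particular genome
  annotation's coordinates.
* **SKI7-like and Patch 4-like motifs** — best scan hit per consensus for
  the chosen lineage. The lineage (plant vs metazoan consensus pair) is
  an explicit argument, never guessed from the input.
* **Translational GTPase** — a Walker-A box `G-x(4)-G-K-[S/T]` whose
  match starts in the C-terminal half, marking the region through the
  protein's end. This is a deliberate heuristic: callers with a real
  domain-profile hit can inject its interval, which takes precedence.

The isoform class is a pure function of the two motif presences (both →
`SKI7_COMPLETE`, neither → `HBS1_LIKE`, one → `SKI7_NO_PATCH4` /
`SKI7_NO_MOTIF`). Failures of the acidic-N or zinc-finger detectors never
change the class — diverged orthologs with short N-termini still classify
by their motifs — and motifs found out of canonical N→C order are flagged
(`order_ok = FALSE`) but not reclassified, since degraded paralogs can
carry poorly placed, low-scoring motif remnants. Degenerate grass-type
"poorly aligned" Patch 4 motifs surface as low-evidence hits rather than
a separate class.

## Splice events, premature stops and the NMD rule

Event calling compares each transcript with the gene's reference, chosen
as the longest annotated CDS with lexicographic tie-breaking — a
deterministic stand-in for "the full gene model", which for these loci is
the long SKI7-encoding form. An exon missing from one transcript with
both flanking exons shared and adjacent is a cassette event; an exon
exactly spanning an exon–intron–exon triple is a retained intron; introns
sharing a donor but not an acceptor (with the far boundary of the
differing exon unchanged, which excludes coordinate coincidences produced
by exon skipping) are alternative acceptors, and symmetrically for
donors. `delta_nt` is the signed mRNA length change, and
`frame_preserving` is exactly `delta_nt %% 3 == 0`.

ORF analysis scans the annotated frame from the CDS start to the end of
the mRNA, recording every stop. The reference termination point is the
**last** in-frame stop of that scan, and every earlier stop is a
premature termination codon (PTC). This choice matters for poison-intron
transcripts: annotation pipelines truncate their CDS at the first stop,
and taking the annotated end codon as the termination point would make
such transcripts appear PTC-free. Anchoring on the terminal stop of the
frame instead makes the poison stops premature relative to the downstream
reading frame, while a clean CDS still reports an empty PTC list. The NMD
rule is then the canonical operational form of "stops upstream of
exon-exon junctions": a transcript is an NMD candidate when some PTC lies
at least 50 nt (configurable) upstream of a downstream exon-exon
junction. The rule is monotone in the distance threshold, a property the
test suite checks over randomized ORF layouts.

Classification applies the NMD override first — a transcript with a
qualifying PTC is `NMD_UNPRODUCTIVE` no matter what it encodes — then
maps the architecture class to `SKI7_CODING`, `HBS1_CODING`, `PARTIAL`
(single-motif architectures) or `OTHER`. Transcripts without an annotated
CDS fall back to longest-ORF mode with a warning; when the longest ORF is
not the first-ATG ORF (the alternative-start/uORF situation seen in some
grass SKI7 transcripts), the analysis is flagged ambiguous and the
transcript is labeled `PARTIAL` rather than guessing a reinitiation
outcome — no reinitiation probability model is attempted.

## Consensus derivation

Alignment columns (gaps excluded from frequencies) are reduced to symbols
in priority order: majority residue at frequency ≥ `f_residue` (0.7);
else the most specific class symbol — `+`, then `a`, then `h`, since `a`
⊂ `h` under the defaults — whose member frequency reaches `f_class`
(0.8); else a bracket of the top two residues at joint frequency ≥
`f_pair` (0.8); else `x`. Columns with more than `max_gap` (0.5) gaps are
dropped, which is how "trimming uncommon insertions" is realized. These
thresholds are this package's own operational choices: no numeric
derivation rule exists for the published consensus strings, so the
defaults were chosen once so that clean class-conforming columns emit
class symbols and were not tuned afterwards. Every derived string is
guaranteed to recompile through the pattern compiler (a closure property
the tests exercise for all six registry strings).

Percent identity uses an ends-free (terminal gaps unpenalized) global
alignment with match +1, mismatch 0, gap open 10, gap extend 0.5, and
divides matches by alignment columns excluding terminal-gap columns. For
the near-identical paralog pairs this statistic is quoted for, the
terminal-gap convention barely moves the number; it is documented here
because conventions differ across tools.

## The synthetic-data generator

The generator emulates the canonical locus topology so that every
pipeline stage can be validated against construction-time ground truth:

* An 8-exon plus-strand gene (configurable) whose cassette exon (index 4
  by default) encodes the SKI7-like motif and the **first nine residues**
  of the Patch 4-like motif, the rest of which continues on the next
  exon. Placing the Patch 4 boundary on the cassette makes exon skipping
  ablate both motifs, so the skipping form classifies `HBS1_LIKE` and
  labels `HBS1_CODING` — the fate the locus model requires — while the
  motif still begins immediately after the SKI7-like element, as in the
  real proteins.
* A poison intron at the cassette's 3' end, built from whole codons
  (every exon boundary falls on a codon boundary) with exactly
  `poison_stop_count` stops (default 2) and a stop-free remainder;
  retention is frame-preserving, so setting the count to 0 produces a
  translatable retention form, which correctly loses its NMD label.
* A rare alternative acceptor 15 nt (default; any multiple of 3)
  upstream of the cassette acceptor, adding 5 in-frame residues with no
  class change.
* 5'/3' UTRs of 30 nt, the 3' UTR assembled from non-stop codons so the
  planted stops are the only premature ones in any splice form's frame.
* An acidic N-terminus with a D/E fraction of exactly 0.40 by default
  (the canonical exemplar's value), a zinc-finger scaffold, and a
  Walker-A box at ~65 % of the protein.

Coding background is drawn from eight residues (N, Q, T, D, E, H, W, Y)
that cannot contribute to any default motif position, Walker-A box or
zinc-finger cysteine, so planted features are provably the only features
— ground truth is unambiguous by construction, not by re-running the
classifier. Codons come from a fixed preferred-codon table (common
Arabidopsis choices) purely for determinism; no codon-usage realism is
claimed. All output is byte-deterministic under the seed carried by the locus specification.

The protein-set generator cycles through the four isoform classes,
ablating motifs by background replacement. Point mutations are applied
outside *anchor* positions — the initiator methionine, the four
zinc-coordinating cysteines and the Walker-A box — while motif residues
remain mutable. Anchoring the structural skeleton keeps mutated proteins
recognizably members of the family, while leaving motifs mutable means
high mutation rates genuinely degrade classification (at a per-residue
rate of 0.3, roughly 2–3 of a 9-mer's positions mutate, often exceeding
the mismatch allowance), which is the degradation behaviour the
generator is meant to expose; it is recorded, not asserted at an exact
value.

The alignment generator realizes a consensus by cycling each row through
the position's residue-set members (row *i* takes member *i* mod *k*)
before applying noise. Cycling rather than uniform sampling guarantees
that at zero noise the empirical column frequencies sit exactly on the
generating consensus's structure, so the derived consensus matches every
row — with uniform sampling a `[P/L]` column can drift past the
majority-residue threshold and emit a literal that fails minority rows,
which would make the closure property flaky rather than exact.

## What the synthetic fixtures do and do not show

Passing on synthetic data demonstrates internal consistency: the
classifiers invert the generator exactly at zero noise, the NMD rule and
event calling behave per their definitions, and derived consensus
strings are closed under recompilation. Real loci add everything the
generator deliberately omits: splice-site strength, codon-usage and
composition biases, motif divergence beyond the mismatch allowance,
annotation errors, organellar paralogs (only the standard genetic code is
implemented), and transcript abundance — the published inclusion
estimates from RNA-seq (~20 % cassette inclusion) are expression
measurements that this package does not recompute. Likewise the
published lineage consensus strings were derived from curated ortholog
alignments; re-deriving them verbatim requires those exact sequence sets
and is database-version dependent, so the acceptance surface checks the
derivation machinery on synthetic alignments instead.

## Numerical and interface conventions

Coordinates are 0-based half-open internally; GFF3 I/O converts at the
boundary (1-based inclusive). Minus-strand exons are stored in ascending
genomic order and iterated in transcript order via the strand flag.
Ambiguity codes collapse to N and N-containing codons translate to X.
Translation never emits `*`: a terminal stop is dropped and internal
stops become `X` placeholders (their codon indices are kept separately),
preserving the positional register that premature-stop bookkeeping
relies on. Problem sizes used by the test and acceptance surface — 40
proteins, 20 randomized loci, depth-20 alignments, ≥ 1000 randomized NMD
cases — were chosen as the smallest sets that exercise every class and
branch while keeping the default runs quick on a laptop.

## Known limitations

* The trGTPase detector is a single-box heuristic, not a profile search;
  inject externally computed domain intervals for serious use.
* No PSSM/HMM motif scoring and no match statistics (E-values); scores
  are matched fractions.
* Splice-form quantification, splice-site strength, 3D structure and
  phylogeny are out of scope.
* The reference-transcript rule (longest CDS) can select a minor form if
  its annotated CDS happens to be longest — e.g. an alternative-acceptor
  form 15 nt longer than the canonical one; event kinds are unaffected
  but `delta_nt` signs flip with the reference.
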