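---
title: "Models and methods: SECIS discovery and selenoprotein gene finding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SECIS discovery and selenoprotein gene finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secisscan)
```

## The problem

Selenocysteine (Sec, the 21st amino acid) is encoded by UGA, a codon that
normally terminates translation. Recoding UGA as Sec requires a cis-acting
stem-loop in the mRNA, the SECIS element, which in archaea and eukaryotes
sits in the 3'-UTR of the selenoprotein gene. Annotating a selenoproteome
from assembled genomes therefore couples two searches: protein-level
evidence that a gene carries an in-frame TGA aligned to a known
selenoprotein family's Sec residue, and RNA-structure-level evidence that a
SECIS-like element follows the gene. `secisscan` implements both, plus the
bookkeeping around them (Sec-machinery inventory, the Sec-utilization
verdict, operon adjacency, motif-composition statistics) and a synthetic
genome generator that makes the whole pipeline testable against planted
ground truth.

## SECIS structural models

Three structural classes are modelled. The two eukaryote-type classes share
a quartet core whose 5' side reads `NNGA` (typically `AUGA`, sometimes
`GUGA`) and whose 3' side reads `GA` or `AA`:

* **type I** (`eSECIS_I`): upper stem 7–15 bp with at most 2 mismatches,
  apical loop 8–20 nt;
* **type II** (`eSECIS_II`): same core and upper stem, plus a ministem of
  2–8 bp (at most 1 mismatch) inside the apical region, separated from the
  upper stem by a 4–12 nt bulge, with a 2–6 nt apical loop;
* **euryarchaeal-type** (`eaSECIS`): lower stem 3–10 bp and upper stem
  3–6 bp separated by a `GAA_A` bulge, apical loop 3–19 nt. Its canonical
  form in methanogens carries three consecutive S–S (C/G–G/C) pairs in the
  upper stem, which `classify_euryarchaeal()` flags but never requires.

Each model is executed as a structured-motif pattern in a PatScan-style
dialect (printed by `builtin_patterns()`). A stem is a named length-ranged
segment plus a pairing back-reference `r1~p1[m,d,i]`: the partner must
align against the reverse of the segment with at most `d` deletions, `i`
insertions, and `m` aligned columns outside the pairing rule
`r1 = {au, ua, gc, cg, gu, ug}`. Two consequences of that rule are worth
stating explicitly: a G·U wobble is a *pair*, not a mismatch, and `N` never
satisfies a pairing rule (conservative handling of ambiguous bases).

In the type II pattern the upper-stem segment spans 6–14 bp while the model
prose says 7–15: the final `N` of the `NNGAN` core literal is counted as
the first upper-stem base pair, which reconciles the two without altering
either. Candidate bookkeeping does the same (+1) when reporting type II
upper-stem lengths.

The matcher reports **every** distinct placement (start plus full segment
binding), exhaustively over declared length ranges. This is deliberate: it
makes the matcher checkable against an independent brute-force enumerator
(`match_all_naive()`), which the test suite runs on hundreds of random
sequences. The production matcher prunes and memoises; the reference
enumerator tries every start and every length assignment and verifies
back-references by enumerating all placements of deletions and insertions —
two genuinely different algorithms that must agree exactly.

## Energy filter

Candidates that satisfy the geometric constraints are scored by a
fixed-structure nearest-neighbor free-energy evaluation (Turner 2004
parameters, 37 °C): stacking terms over adjacent pairs, hairpin-loop
closure by size with terminal mismatches and the tabulated
tetra/hexa/triloops, bulge and internal-loop initiations with Ninio
asymmetry, and terminal-AU penalties at helix ends. Candidates must score
below **−5.0 kcal/mol**, the threshold previously used for SECIS screening
in this lineage; it is a `secis_params()` default, not a constant.

Deliberate choices:

* **Fixed structure, not folding.** The candidate's own pairing map is
  evaluated, rather than free-folding the window and re-deriving a
  structure. This keeps the filter a pure, deterministic function of
  (sequence, pairing map), makes energies additive over disjoint stems, and
  keeps the threshold meaningful. The test suite freezes 20 reference
  values computed by a reference folding program constrained to the same
  structures and requires agreement in sign and within 2 kcal/mol.
* **Threshold applies to the candidate hairpin**, not the whole-window
  fold. (The published procedure does not say which was used; this is our
  reading, recorded here, not asserted as the original authors' intent.)
* **Small-loop approximation.** The dedicated 1×1/1×2/2×2 internal-loop
  lookup tables of the full Turner set are approximated by the generic
  initiation + asymmetry + terminal-mismatch formula. 1×n (n>2) and 2×3
  loops use their dedicated terms. Candidate structures produced by the
  patterns rarely contain the approximated loop shapes; the frozen-fixture
  cross-check bounds the residual error.
* **Hairpin loops under 3 nt score +Inf.** The type II pattern permits a
  2-nt apical loop, but no physical hairpin can close one; such matches can
  therefore never pass the energy filter. The validator still accepts the
  full 2–6 nt model range.

Overlapping candidates of one class collapse to the lowest-energy one
(ties: leftmost start, then longer stem) — energy is the models' only
ranking signal. Where type I and type II both survive on one locus, both
are reported and flagged `coexisting`.

## Selenoprotein gene finding

The detection signal is the **Sec/TGA pair**: an alignment column where a
query protein's `U` sits opposite a genomic TGA codon. Alignments come
either from real tblastn/JackHMMER tabular output (extended outfmt 6 with
`qlen slen qseq sseq`; `read_tabular_alignments()`) or from the package's
own six-frame Smith–Waterman (`local_align_protein_vs_sixframe()`), which
exists so that the pipeline and its tests are self-contained at desk scale.
The aligner scores `U` like cysteine and gives a configurable bonus
(default +8) to `U` aligned against a stop; its e-values are Karlin–Altschul
estimates with the published gapped BLOSUM62(11,1) constants. Multi-copy
families (hdrA and frhD typically occur in several copies) are found by
iterative mask-and-realign (`local_align_all_hits()`).

Every reported Sec codon is re-read from the genome and must literally be
`TGA` on the coding strand — an invariant asserted on every run. Around
each verified codon, `extend_orf()` extends in frame: downstream to the
first `TAA`/`TAG` (TGA reads through as `U`), upstream to the *nearest*
`ATG`/`GTG`/`TTG` start bounded by the first in-frame stop. Alternative
starts reflect archaeal usage; the nearest-start rule is our choice where
the published procedure says only "a reasonable ORF". Proteins shorter than
35 aa are flagged (and excluded from phylogenetic use downstream), not
silently dropped.

The organism-level verdict follows the two-part criterion: **Sec+** requires
(i) at least three genes of the Sec encoding system — SecS, EFSec, PSTK,
SelD, tRNA-Sec — and (ii) at least one known selenoprotein gene. Two
readings of "(including tRNA-Sec)" are supported: by default tRNA-Sec
counts toward the tally but is not individually mandatory; strict mode
(`strict_trna = TRUE`) additionally requires it. Presence/absence is
counted per component, not per copy. `detect_operon_pairs()` reports
consecutive same-strand hdrA–frhD pairs with an intergenic gap of at most
60 nt (configurable), reflecting the observation that these genes
consistently travel together and likely share one SECIS element.

## The synthetic-data generator

`simulate_genome()` builds benchmark organisms: i.i.d. background
nucleotides at a configured GC fraction (default 0.45, near the median of
the archaeal assemblies this pipeline targets), protein-coding genes on
random strands without overlap, one in-frame TGA per selenoprotein gene at
a recorded position, a 3'-UTR SECIS element of a class drawn from the
configured mix 5–30 nt after the stop, a configurable machinery complement,
and an optional co-planted hdrA–frhD pair with a short same-strand gap
(default 30 nt). The emitted query proteins are the planted proteins, so an
identity-level search has exact ground truth; a truth ledger records every
planted element with its drawn parameters. All randomness flows from one
seed, and reruns are byte-identical.

Planted SECIS geometries are drawn uniformly within the model ranges and
redrawn until the constructed element clears the −5.0 kcal/mol criterion it
will be screened with — an element that cannot pass the model's own energy
filter is not a valid planted instance (a 3+3 bp all-GC element with a
19 nt loop, for example, is geometrically legal but energetically
hopeless). Two related choices: type II apical loops are sampled from
3–6 nt because a 2-nt loop cannot close a hairpin at all, and stems default
to strongly GC-biased composition (`stem_gc = 0.9`; the recovery benchmarks
use 1.0, i.e. perfect all-S stems, matching their stated "perfect stems,
GC-rich" condition).

What the generator does **not** emulate — and hence what passing benchmarks
do not show about real data: realistic codon usage and coding statistics,
homology at less-than-identity (unless a mutation rate is configured),
assembly artifacts, contamination, overlapping genes, and SECIS elements
that deviate from the three models. Recovery results on generator output
are a correctness check of the machinery, not a sensitivity estimate for
diverged genomes.

The dinucleotide-preserving shuffle (`shuffle_negative_controls()`, random
Eulerian walk over the dinucleotide transition graph) provides matched
negative controls. The per-window false-positive rate of the scan on
shuffled windows is reported by the acceptance script as a tracked
regression metric; no fixed bound is asserted, since the models are
intentionally permissive and the published procedure ranks by energy rather
than controlling a false-positive rate.

## Numerical and interface conventions

Internal coordinates are 0-based half-open everywhere; GFF3 I/O converts
to/from 1-based inclusive, which confines off-by-one risk to one boundary.
Sequences are stored in the DNA alphabet (`U` mapped to `T` on input) and
transliterated to RNA only at the pattern-matching and presentation
boundary. The scan window spans 30 nt upstream to 600 nt downstream of the
annotated CDS end, *including* the stop codon, because UGA stops often
overlap the `AUGA` core of the following element — measuring from the stop
codon's start would clip exactly the interesting overlap. Pipeline stages
write deterministic primary outputs plus a JSON manifest without
timestamps, so identical runs are byte-identical; logs go to stderr.

## Problem sizes used in the checks

The bundled checks run: oracle equivalence on 500 random strings (length
30–60) against all three patterns truncated to a ≤40 nt span; 200 planted
elements per SECIS class in 630-nt windows; 100 planted selenoprotein genes
across 5 organisms for Sec-codon precision/recall; the exhaustive
2^5 × {0,1,2} trait table; 40 random annotation sets (≤50 genes) for operon
detection; 20 frozen energy fixtures; and a duplicated full-pipeline run
for byte-identity. These sizes were chosen so the full suite completes on a
laptop-class single core in minutes while keeping every statistical check
comfortably powered.

## Known limitations

* The matcher implements the dialect subset the three patterns need —
  pairing-rule declarations, literals, length-ranged segments,
  back-references with budgets, literal alternations — not the full PatScan
  language.
* E-values from the built-in aligner are estimates; for real screens, run
  tblastn/JackHMMER and feed the tabular output in.
* The energy evaluator scores the candidate structure as given; it will not
  notice that a window folds into something better than the candidate.
* Cys-homolog verification, contamination screening, tRNA structure
  prediction and phylogenetics are out of scope; tRNA-Sec presence is
  consumed as an annotation.
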