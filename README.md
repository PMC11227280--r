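# secisscan

Discovery of SECIS elements and selenoprotein genes in archaeal genome
assemblies.

Selenocysteine (Sec), the 21st amino acid, is encoded by UGA — normally a
stop codon. Whether a UGA is read through as Sec is decided by a cis-acting
RNA stem-loop in the mRNA, the **SECIS element**, located in the 3'-UTR in
archaea and eukaryotes. Annotating selenoproteomes from assemblies (MAGs in
particular) therefore means combining protein-level evidence — a known
selenoprotein family's Sec residue aligned to a genomic TGA — with
RNA-structure evidence in the region downstream of the gene. `secisscan`
implements that pipeline for the three SECIS classes relevant to archaeal
genomes, end to end and fully testable against synthetic genomes with
planted ground truth.

## What it does

* **Structured-motif matching** (`parse_pattern()`, `match_all()`): a
  PatScan-dialect engine with literals, length-ranged segments,
  alternations, and stem back-references `r1~p1[m,d,i]` that align a
  partner against the reverse of a segment under the pairing rule
  `r1 = {au, ua, gc, cg, gu, ug}` with mismatch/deletion/insertion budgets.
  An independent exhaustive enumerator (`match_all_naive()`) ships with the
  package as a correctness reference.
* **SECIS structural models** (`builtin_patterns()`, `scan_window()`,
  `validate_candidate()`): type I eukaryote-like (GA_[G/A]A quartet core,
  7–15 bp upper stem with ≤2 mismatches, 8–20 nt apical loop), type II
  (same core and stem plus a 2–8 bp ministem, 4–12 nt bulge, 2–6 nt apical
  loop), and euryarchaeal-like (3–10 bp lower stem, GAA_A bulge, 3–6 bp
  upper stem, 3–19 nt apical loop). Scanning covers 30 nt upstream to
  600 nt downstream of each gene's 3' end.
* **Free-energy filter** (`energy()`): fixed-structure nearest-neighbor
  evaluation (Turner 2004 parameters) of each candidate's pairing map;
  candidates must score below −5.0 kcal/mol.
* **Selenoprotein gene finding** (`find_sec_tga_pairs()`, `extend_orf()`):
  Sec/TGA alignment pairs verified against the genome, UGA read-through ORF
  extension, family assignment, 35-aa length flagging. Consumes real
  tblastn/JackHMMER tabular output (extended outfmt 6) or uses the built-in
  six-frame Smith–Waterman for self-contained runs.
* **Trait classification** (`classify_sec_trait()`): Sec+ requires ≥3 of
  {SecS, EFSec, PSTK, SelD, tRNA-Sec} plus ≥1 selenoprotein gene; a strict
  mode additionally requires tRNA-Sec.
* **Operon adjacency** (`detect_operon_pairs()`): consecutive same-strand
  hdrA–frhD pairs with short intergenic gaps.
* **Motif statistics** (`composition_profiles()`): position-wise nucleotide
  composition of the SECIS core and the unpaired-adenine region.
* **Synthetic benchmarks** (`simulate_genome()`,
  `shuffle_negative_controls()`): deterministic genomes with planted
  machinery genes, selenoprotein genes and SECIS elements, plus a
  machine-readable truth ledger and dinucleotide-preserving negative
  controls.

## Worked example

Simulate a benchmark organism, scan for SECIS candidates, call
selenoprotein genes from the planted (identity) queries, and classify the
Sec-utilization trait:

```r
library(secisscan)

sim  <- simulate_genome(sim_config(seed = 1), out_dir = "sim")
tab  <- cmd_scan_secis("sim/synth1.fasta", "sim/synth1.gff3", "out")
head(tab[, c("contig_id", "start", "end", "strand", "gene_id",
             "model_class", "core5", "core3", "dG")], 8)
```

```
      contig_id start end strand     gene_id model_class core5 core3    dG
 synth1_contig3   104 148      - synth1_g002    eSECIS_I  GUGA    GA  -9.8
 synth1_contig3   104 148      - synth1_g002   eSECIS_II  GUGA    GA -11.7
 synth1_contig1   425 476      + synth1_g003    eSECIS_I  GGGA    AA  -5.4
 synth1_contig1   425 476      + synth1_g003   eSECIS_II  GGGA    AA -10.2
 synth1_contig1   512 566      + synth1_g003   eSECIS_II  GCGA    AA  -6.0
 synth1_contig1   749 804      + synth1_g003    eSECIS_I  GCGA    AA  -6.2
 synth1_contig1   749 804      + synth1_g003   eSECIS_II  GCGA    AA  -6.2
 synth1_contig2   656 695      - synth1_g004    eSECIS_I  AUGA    GA -20.2
```

Each row is one candidate: genomic interval (0-based half-open), the
model class it satisfied, the core context read at the quartet (`AUGA…GA`
being the canonical form), and the fixed-structure free energy in
kcal/mol (all below the −5.0 filter). Identical intervals reported under
both eSECIS classes are one locus that satisfies both models (flagged
`coexisting` in the full table).

```r
hits <- cmd_find_selenoproteins("sim/synth1.fasta",
                                queries = "sim/synth1_queries.fasta",
                                out_dir = "out")
hits[, c("contig_id", "family", "codon_start", "codon_end", "strand",
         "n_support", "short")]
```

```
      contig_id family codon_start codon_end strand n_support short
 synth1_contig1   FrhA         988       990      +         1 FALSE
 synth1_contig2   FrhD         910       912      -         2 FALSE
 synth1_contig2   HdrA        1156      1158      -         2 FALSE
 synth1_contig3   PrxL         249       251      -         1 FALSE
 synth1_contig3   SelD         596       598      +         1 FALSE
```

Five Sec codons (1-based inclusive genomic coordinates), one per planted
gene; each codon re-reads literally as `TGA` on its coding strand. The
co-planted hdrA–frhD pair is adjacent on one strand, 30 nt apart:

```r
detect_operon_pairs(read_gff3("sim/synth1.gff3"))
#>       contig_id strand       gene1 label1       gene2 label2 gap
#>  synth1_contig2      - synth1_g005   frhD synth1_g004   hdrA  30

cmd_classify_trait(list(synth1 = list(annotations = "sim/synth1.gff3",
                                      hits = hits)), "out")
#>  organism_id SecS EFSec PSTK SelD tRNA-Sec machinery_count n_selenoproteins verdict
#>       synth1    1     1    1    1        1               5                5    Sec+
```

All five machinery components plus five selenoprotein genes: the organism
is classified Sec+.

A command-line front-end with the same stages as subcommands
(`simulate`, `scan-secis`, `find-selenoproteins`, `classify-trait`,
`logo-stats`) is installed at `inst/scripts/secisscan.R`.

## Alignment input dialect

For real screens, run tblastn with
`-outfmt '6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore qlen slen qseq sseq'`
and pass the file to `read_tabular_alignments()` /
`cmd_find_selenoproteins(alignment_table = ...)`. The aligned sequence
columns (`qseq`, `sseq`) are required — Sec/TGA pairing reads alignment
columns; minus-strand alignments are encoded by `sstart > send`.

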