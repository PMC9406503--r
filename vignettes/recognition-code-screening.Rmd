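---
title: "Screening peptides with the 1-L protein-RNA recognition code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening peptides with the 1-L protein-RNA recognition code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onelcode)
```

## The model

The hypothesis behind this package is that some RNA-binding proteins (RBPs)
carry amino-acid stretches that are *letter-for-letter* compatible with the
RNA they recognize, with each amino acid standing for the nucleotide found
at the **second position of its codons**. The second codon position is the
most conserved and most physicochemically informative one, and it induces a
clean partition of the 20 standard amino acids: F/L/I/M/V stand for U,
P/T/A for C, Y/H/Q/N/K/D/E for A, and C/W/R/G for G. Serine is the single
degenerate residue — its UCN codons put C at position 2 while AGU/AGC put
G — so serine stands for either C or G.

Transcribing a peptide under this code is a per-residue substitution, but
two genuine choices remain and the package enumerates all of their
combinations, giving **four candidate nucleotide sequences per peptide**:

1. *Direction.* The peptide backbone can be read N→C or C→N while
   nucleotides are written 5′→3′. The reverse-mode transcript is the plain
   character reversal of the forward one (not a complement); the package
   implements it that way and property-tests the equivalence with
   transcribing the reversed peptide.
2. *Serine policy.* All serines become C, or all become G — a global
   choice per variant. Allowing a per-residue choice would produce
    $2^{\#S}$ variants rather than four and is deliberately not offered.

Two worked examples anchor the implementation. The N-terminal fragment
`QNQIQQ` of the yeast WDR33 homologue — an RBP that reads the poly(A)
signal — transcribes in reverse mode to `AAUAAA`, exactly the hexameric
polyadenylation signal. The most conserved stretch of the first RNA
recognition motif of HUR/ELAVL1, `NLIVNYLPQNMTQDE`, transcribes forward to
`AUUUAAUCAAUCAAA`: an `AUUUA` AU-rich element followed by a PAS-like
`AAUCAAA` spaced by one C. Both are frozen as exact-string tests; the
second also checks that the *strict* PAS scanner does **not** fire on the
spaced element.

## Motif scanning

Variants are scanned literally (no complementing — strandedness belongs to
the search stage), with 1-based closed coordinates as is conventional in
R/Bioconductor interval containers:

* **PAS** — every occurrence of `AATAAA` (DNA spelling), overlaps included.
* **ARE class I** — every occurrence of the pentamer `ATTTA`.
* **ARE class II** — maximal runs of overlapping `ATTTA` copies (starts 4
  apart), each run one hit.
* **ARE class III** — the U-rich class. "Rich in U" has no standard
  quantitative definition, so the package always reports the literal
  `TTTC` word and additionally reports maximal merged windows of length
  `w = 8` with T-fraction ≥ `0.75`. Both parameters are configurable;
  nothing downstream depends on the windowed rule, and the defaults were
  fixed once as a conservative reading of "rich in U" (three quarters of a
  two-turn RNA stretch).

All scanners are re-checked in the test suite against naive brute-force
reimplementations on random sequences.

## Search: seed-and-extend with expectation values

Each of the four variants is searched **separately** against the
transcriptome, on both strands. The design mirrors short-query nucleotide
BLAST: exact shared words of length 7 seed candidate subjects; match +2,
mismatch −3; gap open 5, gap extend 2 (a length-$k$ gap costs
$5 + 2k$); expectation threshold 100; at most 500 distinct subjects. These
are this package's defaults, stated as such — not verbatim NCBI
internals — and all are configurable. Low-complexity filtering is off by
default: the queries of interest are 6–42 nt and A/U-rich, exactly what a
DUST-style filter would erase.

Two implementation choices matter:

* **Seeding selects, DP scores.** Word seeds only decide *which*
  (subject, strand) pairs are examined; each candidate pair is then scored
  by a full Gotoh local-alignment dynamic program with affine gaps
  (compiled code). At desk scale a full-width band costs little, and it
  makes the aligner *exact* given a seed: whenever query and subject share
  one word of length 7, the reported best score provably equals the full
  Smith–Waterman score. The test suite verifies this against
  `Biostrings::pairwiseAlignment()` — an independent implementation used
  only as an oracle — over hundreds of seeded random pairs.
* **Minus strand by query reverse complement.** The index stores
  plus-strand words only; the minus strand is searched by
  reverse-complementing the query, and subject coordinates are emitted on
  the plus strand with `s_start > s_end`, the BLAST tabular convention, so
  hit tables round-trip through `-outfmt 6` files and external BLASTn runs
  can be imported unchanged.

`N` never matches anything: words containing `N` are not indexed or used as
seeds, and the aligner scores `N` against any letter as a mismatch.

Expectation values use the Karlin–Altschul form $E = K m n e^{-\lambda S}$
with $m$ the query length and $n$ the summed database length. $(\lambda, K)$
ship as constants for the supported schemes (+2/−3: $\lambda = 0.625$,
$K = 0.41$; +1/−2: $\lambda = 1.28$, $K = 0.46$), NCBI-style values for
uniform composition; `solve_karlin_lambda()` solves the defining equation
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ exactly for any scheme, and a
test checks the shipped default against the solved root (0.625 vs 0.6326,
within 2%). Computing $K$ from first principles is out of scope; custom
schemes require user-supplied values. E-values on short queries are
approximate by nature — edge effects are not corrected — and the package
treats them as a ranking and filtering device, which is how the screening
procedure uses them.

Ties among equal-E hits are broken by subject id, then subject start, so
hit tables are byte-reproducible.

## Classification

The screening rule is mechanical: group hits by (subject, strand);
plus-strand groups become *repressive* calls (the peptide would engage the
mRNA itself, suppressing translation), minus-strand groups *promotive*
calls (the peptide would engage antisense regulators, de-repressing the
mRNA). A subject hit on both strands yields two calls — the package does
not attempt to resolve which wins, and none of the downstream reports
merge them. Reports attach the conventional colors (green = repressive,
yellow = promotive) and a header caveat that the direction of the effect
is a modeling convention that may be inverted in vivo. An optional
transcript→gene map collapses isoforms, best E-value winning per gene and
mode.

## Synthetic data and what passing tests show

`random_transcriptome()` generates i.i.d. backgrounds with configurable GC
fraction; `plant_queries()` substitutes queries (or their reverse
complements) at recorded offsets, one plant per transcript, lengths
unchanged, and returns a ground-truth manifest. The study conditions used
by the tests and the acceptance script were fixed once: 40 transcripts of
300–600 nt at GC 0.5 (the scale of a focused mRNA panel), 20 planted
25-residue peptide transcripts on mixed strands, and 200 random
query/subject pairs of 20–60 / 100–500 nt sharing a planted 7-mer for the
aligner oracle. Under these conditions every exact plant of length ≥ 7 is
recovered at 100% identity with the correct strand and mode.

The generator emulates only what the search machinery needs: word
statistics, strand asymmetry, planted exact occurrences. It does **not**
model real transcript structure — UTRs, splicing, repeat families, codon
bias, or the length distribution of the human transcriptome. Passing the
planted-recovery tests therefore shows the *mechanics* are correct
(seeding, strand handling, coordinates, classification), not that screening
a real transcriptome yields biologically meaningful gene lists; gene-level
findings additionally depend on database composition and on selection
thresholds that are outside this package's scope.

## Numerical and degenerate-input choices

* Empty peptides transcribe to empty variants; empty hit tables classify
  to empty, well-formed call tables.
* Non-standard residues (X, B, Z, U, O, \*) map to `N` with a warning by
  default; a strict mode errors. Lowercase residues are accepted and read
  case-insensitively (some published sequences use lowercase
  typographically for spacer positions).
* A single query shorter than the word size is an explicit error naming
  both lengths; the batch and pipeline surfaces skip such variants with a
  warning naming them, so a short peptide cannot abort a screen.
* All stochastic functions take explicit seeds, run in a private RNG scope
  and restore the caller's RNG state.
* The pipeline writes machine output only to files, logs counts per stage
  to standard error, and aborts with the stage name and cause on any
  stage failure.

## Known limitations

* The recognition code itself is a hypothesis; this package implements the
  screening procedure, not evidence for in-vivo regulation.
* E-values use uncorrected Karlin–Altschul statistics with shipped
  constants; for publication-grade statistics on a real database, import
  an external BLASTn run via `parse_blast_tabular()` instead.
* Only the standard genetic code is supported for deriving the
  residue→nucleotide table.
* The word index is an in-memory hash designed for desk-scale FASTA, not
  genome-scale databases.
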