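# onelcode

Screening peptides as candidate RNA-binding regulators with the one-letter
(1-L) protein–RNA recognition code.

Some RNA-binding proteins appear to recognize RNA through amino-acid
stretches that are letter-for-letter compatible with the nucleotide sequence
they bind: each amino acid corresponds to the nucleotide at the **second
position of its codons**. Under the standard genetic code this gives a clean
partition of the 20 amino acids —

| second-position letter | amino acids |
|---|---|
| U/T | F, L, I, M, V |
| C | P, T, A (+ S via UCN) |
| A | Y, H, Q, N, K, D, E |
| G | C, W, R, G (+ S via AGU/AGC) |

— with serine the single ambiguous residue (C or G). `onelcode` turns a
peptide into its four candidate nucleotide sequences (two reading
directions, N→C and C→N, times the two serine policies), scans them for
regulatory elements (the AAUAAA polyadenylation signal and AU-rich element
classes I–III), searches them against a transcriptome on both strands with a
word-seeded local aligner (word size 7, match +2 / mismatch −3, gap 5/2,
Karlin–Altschul expectation values `E = K·m·n·e^(−λS)`), and classifies each
hit transcript:

* **sense (plus-strand) hit** → candidate post-transcriptional **repression**
  ("green"),
* **antisense (minus-strand) hit** → candidate post-transcriptional
  **promotion** ("yellow").

The direction of the biological effect is a modeling convention and may in
reality be inverted; reports carry that caveat. The package is aimed at
desk-scale screens: worked peptide examples, synthetic transcriptomes with
planted ground truth, and interop with NCBI BLASTn 12-column tabular output
for genome-scale runs done externally.

## Worked example

The canonical amyloid-β 42 peptide, transcribed and screened against a
synthetic transcriptome with one antisense plant:

```r
library(onelcode)
ab <- example_peptides()[["abeta42"]]
v  <- enumerate_variants(ab, peptide_id = "abeta42")
v[, c("variant_id", "sequence")]
#>   variant_id      sequence
#> 1 abeta42|fwd|S-C ACATGAACGAATAAAATTTTCAATGCAAGCTTGTTTGGTTTC
#> 2 abeta42|fwd|S-G ACATGAAGGAATAAAATTTTCAATGGAAGCTTGTTTGGTTTC
#> 3 abeta42|rev|S-C CTTTGGTTTGTTCGAACGTAACTTTTAAAATAAGCAAGTACA
#> 4 abeta42|rev|S-G CTTTGGTTTGTTCGAAGGTAACTTTTAAAATAAGGAAGTACA

scan_pas(v$sequence[1], v$variant_id[1])
#>        variant_id motif_class start end matched
#> 1 abeta42|fwd|S-C         PAS    10  15  AATAAA

scan_are(v$sequence[1], "ARE_III", v$variant_id[1])
#>        variant_id motif_class start end  matched
#> 1 abeta42|fwd|S-C     ARE_III    18  21     TTTC
#> 2 abeta42|fwd|S-C     ARE_III    39  42     TTTC
#> 3 abeta42|fwd|S-C     ARE_III    34  41 TTTGGTTT
```

The forward transcript carries one exact poly(A) signal (positions 10–15),
two literal `TTTC` words (the U-rich class-III ARE element) and one merged
T-rich region — the peptide looks like a plausible small RNA-binding
regulator under this code. Searching all four variants against a 20-transcript
synthetic transcriptome in which the forward S-C variant was planted in
reverse complement (an antisense plant):

```r
txome <- random_transcriptome(20, c(300, 500), gc_fraction = 0.5, seed = 101)
pl    <- plant_queries(txome, c(`abeta42|fwd|S-C` = v$sequence[1]), "minus", seed = 102)
calls <- classify_hits(search_variants(v, pl$transcriptome))
head(calls, 3)
#>   subject_id       mode  best_evalue best_score n_hits
#> 1 synth_0014  promotive 2.173948e-18         84      4
#> 2 synth_0012  promotive 5.117152e-01         20      4
#> 3 synth_0018 repressive 5.117152e-01         20      4
```

The planted transcript (`synth_0014`) tops the list as *promotive* — an
antisense, minus-strand hit at 100% identity (raw score 84 = 42 matches × 2,
E ≈ 2×10⁻¹⁸). The remaining calls are the background of short chance
word matches that an expectation threshold of 100 deliberately lets
through; their E-values near 1 tell you how seriously to take them.

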