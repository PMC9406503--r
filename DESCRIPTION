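Package: onelcode
Title: Protein-RNA Recognition Screening with the Second-Position Codon Code
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Transcribes peptide and protein sequences into the nucleotide
    sequences they are compatible with under the one-letter (1-L) protein-RNA
    recognition code, in which each amino acid corresponds to the nucleotide
    at the second position of its codons (serine being the only two-letter
    residue, C or G). The four candidate sequences per peptide (two reading
    directions times two serine policies) are scanned for regulatory elements
    (the AAUAAA polyadenylation signal and AU-rich element classes I-III),
    searched against a transcriptome on both strands with a word-seeded
    local aligner reporting BLAST-style expectation values, and hit
    transcripts are classified as candidates for post-transcriptional
    repression (sense hits) or promotion (antisense hits). Includes a
    synthetic-transcriptome generator with planted ground truth and
    import/export of NCBI BLAST 12-column tabular output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
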