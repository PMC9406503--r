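# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, brute force, external reference implementations) so it stays
# independent of the package's own code paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent local-alignment oracle: Biostrings' Smith-Waterman under the
# identical scoring scheme (a length-k gap costs gap_open + k * gap_extend
# in both implementations).
sw_oracle_score <- function(q, s, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
}

# Brute-force occurrence scanner (all overlapping matches of a literal word).
naive_occurrences <- function(seq, word) {
  n <- nchar(seq); k <- nchar(word)
  if (n < k) return(integer(0))
  which(vapply(seq_len(n - k + 1L),
               function(i) substr(seq, i, i + k - 1L) == word, logical(1)))
}

# Brute-force maximal T-rich regions: mark qualifying windows one by one,
# then merge contiguous/overlapping ones by linear scan.
naive_t_rich <- function(seq, w, f) {
  n <- nchar(seq)
  if (n < w) return(data.frame(start = integer(0), end = integer(0)))
  ok <- integer(0)
  for (i in seq_len(n - w + 1L)) {
    win <- substr(seq, i, i + w - 1L)
    tcount <- sum(strsplit(win, "")[[1L]] == "T")
    if (tcount / w >= f) ok <- c(ok, i)
  }
  if (length(ok) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  starts <- ok[1L]; ends <- ok[1L] + w - 1L
  for (s in ok[-1L]) {
    if (s <= ends[length(ends)] + 1L) {
      ends[length(ends)] <- s + w - 1L
    } else {
      starts <- c(starts, s); ends <- c(ends, s + w - 1L)
    }
  }
  data.frame(start = starts, end = ends)
}

# A (query, subject) pair guaranteed to share at least one exact 7-mer:
# random backgrounds with a random query word copied into the subject.
seeded_pair <- function(qlen, slen, word = 7L) {
  q <- random_dna(qlen)
  s <- random_dna(slen)
  qpos <- sample.int(qlen - word + 1L, 1L)
  spos <- sample.int(slen - word + 1L, 1L)
  substr(s, spos, spos + word - 1L) <- substr(q, qpos, qpos + word - 1L)
  list(q = q, s = s)
}

write_temp_fasta <- function(seqs, type = "dna") {
  path <- tempfile(fileext = ".fasta")
  write_fasta(seqs, path, type = type)
  path
}
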