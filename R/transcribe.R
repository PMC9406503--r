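# Peptide -> candidate nucleotide sequences. Two reading directions (the
# peptide read N->C or C->N while nucleotides are emitted 5'->3') times two
# serine policies give the four candidate sequences per peptide. The serine
# policy is global per variant: all serines become C, or all become G.

#' Transcribe a peptide with the 1-L code
#'
#' Maps each residue to its second-codon-position nucleotide. In `"reverse"`
#' direction the peptide is read C-terminus to N-terminus, which makes the
#' output the plain character reversal (not the complement) of the forward
#' transcript under the same serine policy.
#'
#' @param peptide Amino-acid sequence (character scalar; whitespace stripped,
#'   case-insensitive). May be empty.
#' @param direction `"forward"` (N to C) or `"reverse"` (C to N).
#' @param serine_policy `"C"` or `"G"`, applied to every serine.
#' @param code An `onel_code` object.
#' @param alphabet `"dna"` (default, T) or `"rna"` (U) for display; the
#'   internal alphabet is DNA.
#' @param unknown Non-standard residue policy, see [onel_lookup()].
#' @return A character scalar, one nucleotide per residue.
#' @examples
#' transcribe_peptide("QNQIQQ", direction = "reverse")             # "AATAAA"
#' transcribe_peptide("QNQIQQ", direction = "reverse", alphabet = "rna")
#' transcribe_peptide("NLIVNYLPQNMTQDE")                  # "ATTTAATCAATCAAA"
#' @export
transcribe_peptide <- function(peptide,
                               direction = c("forward", "reverse"),
                               serine_policy = c("C", "G"),
                               code = onel_code(),
                               alphabet = c("dna", "rna"),
                               unknown = c("N", "error")) {
  direction <- match.arg(direction)
  serine_policy <- match.arg(serine_policy)
  alphabet <- match.arg(alphabet)
  unknown <- match.arg(unknown)
  stopifnot(is.character(peptide), length(peptide) == 1L, !is.na(peptide))
  peptide <- toupper(gsub("\\s", "", peptide))
  if (nchar(peptide) == 0L) return("")

  map <- residue_map(code, serine_policy)
  residues <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  if (direction == "reverse") residues <- rev(residues)
  nts <- unname(map[residues])
  bad <- is.na(nts)
  if (any(bad)) {
    if (unknown == "error") {
      stop("non-standard residue(s): ",
           paste(unique(residues[bad]), collapse = ", "), call. = FALSE)
    }
    warning("non-standard residue(s) ",
            paste(unique(residues[bad]), collapse = ", "),
            " mapped to N", call. = FALSE)
    nts[bad] <- "N"
  }
  out <- paste(nts, collapse = "")
  if (alphabet == "rna") out <- chartr("T", "U", out)
  out
}

# Flat residue -> single nucleotide vector under a fixed serine policy.
residue_map <- function(code, serine_policy) {
  stopifnot(inherits(code, "onel_code"))
  map <- vapply(code$mapping, `[[`, "", 1L)
  map[["S"]] <- serine_policy
  map
}

#' Enumerate the four candidate variants of a peptide
#'
#' Produces the four labeled transcripts `{forward, reverse} x {S-C, S-G}`,
#' in that order, with deterministic variant ids
#' `"<peptide_id>|fwd|S-C"`, ..., `"<peptide_id>|rev|S-G"`. For a
#' serine-free peptide the S-C and S-G sequences coincide within each
#' direction; all four labeled rows are still reported unless `dedupe = TRUE`
#' collapses rows with identical sequence (keeping the first label).
#'
#' @inheritParams transcribe_peptide
#' @param peptide_id Identifier used to build variant ids.
#' @param dedupe Collapse variants with identical sequence?
#' @return A data.frame with columns `variant_id`, `peptide_id`, `direction`,
#'   `serine_policy`, `sequence`, `length`.
#' @examples
#' enumerate_variants(example_peptides()[["abeta42"]], peptide_id = "abeta42")
#' @export
enumerate_variants <- function(peptide, peptide_id = "query",
                               code = onel_code(), dedupe = FALSE,
                               alphabet = c("dna", "rna"),
                               unknown = c("N", "error")) {
  alphabet <- match.arg(alphabet)
  unknown <- match.arg(unknown)
  stopifnot(is.character(peptide_id), length(peptide_id) == 1L,
            nchar(peptide_id) > 0L)
  combos <- expand.grid(
    serine_policy = c("C", "G"),
    direction = c("forward", "reverse"),
    stringsAsFactors = FALSE
  )[, c("direction", "serine_policy")]
  seqs <- mapply(
    function(d, s) transcribe_peptide(peptide, d, s, code = code,
                                      alphabet = alphabet, unknown = unknown),
    combos$direction, combos$serine_policy,
    USE.NAMES = FALSE
  )
  out <- data.frame(
    variant_id = paste0(
      peptide_id, "|",
      ifelse(combos$direction == "forward", "fwd", "rev"),
      "|S-", combos$serine_policy
    ),
    peptide_id = peptide_id,
    direction = combos$direction,
    serine_policy = combos$serine_policy,
    sequence = seqs,
    length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  if (dedupe) out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate variants for every record of a protein FASTA
#'
#' @param peptides Named character vector of amino-acid sequences, as
#'   returned by [read_fasta()] with `type = "protein"`.
#' @inheritParams enumerate_variants
#' @return A data.frame, row-bound [enumerate_variants()] output.
#' @export
enumerate_variants_all <- function(peptides, code = onel_code(),
                                   dedupe = FALSE,
                                   alphabet = c("dna", "rna"),
                                   unknown = c("N", "error")) {
  alphabet <- match.arg(alphabet)
  unknown <- match.arg(unknown)
  if (is.null(names(peptides)) || anyNA(names(peptides)) ||
      any(names(peptides) == "")) {
    stop("'peptides' must be a named character vector", call. = FALSE)
  }
  do.call(rbind, lapply(names(peptides), function(id) {
    enumerate_variants(peptides[[id]], peptide_id = id, code = code,
                       dedupe = dedupe, alphabet = alphabet, unknown = unknown)
  }))
}
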