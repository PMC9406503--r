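# FASTA in/out behind Biostrings, normalized to the plain named character
# vectors the rest of the package works with.

#' Read a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] / [Biostrings::readAAStringSet()],
#' truncating headers at the first whitespace, upper-casing sequences, and
#' rejecting empty files and duplicate ids.
#'
#' @param path FASTA file path (wrapped or unwrapped lines).
#' @param type `"dna"` or `"protein"`.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in '", path, "'", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"dna"`, `"rna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "rna", "protein")) {
  type <- match.arg(type)
  check_named_seqs(seqs, "seqs")
  set <- switch(type,
    dna = Biostrings::DNAStringSet(seqs),
    rna = Biostrings::RNAStringSet(seqs),
    protein = Biostrings::AAStringSet(seqs)
  )
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
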