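# The 1-L protein-RNA recognition code: one nucleotide per amino acid, taken
# from the second position of the residue's codons. The 20 standard amino
# acids partition cleanly by that letter; serine is the single exception
# (TCN -> C, AGT/AGC -> G) and therefore carries two letters.

STANDARD_AA <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Second-position partition of the standard genetic code.
ONEL_PARTITION <- list(
  T = c("F", "L", "I", "M", "V"),
  C = c("P", "T", "A"),
  A = c("Y", "H", "Q", "N", "K", "D", "E"),
  G = c("C", "W", "R", "G")
)

new_onel_code <- function(mapping, source) {
  mapping <- mapping[order(names(mapping))]
  structure(list(mapping = mapping, source = source), class = "onel_code")
}

#' The built-in 1-L recognition code
#'
#' Returns the amino-acid to nucleotide mapping in which each standard amino
#' acid corresponds to the nucleotide found at the second position of its
#' codons. Serine maps to the two-letter set `{C, G}` (its codons split
#' between TCN and AGT/AGC); every other residue maps to a single letter.
#' The internal alphabet is DNA; see [transcribe_peptide()] for RNA display.
#'
#' @return An object of class `onel_code`: a list with `mapping` (named list
#'   of nucleotide character vectors, one entry per amino acid) and `source`
#'   (`"builtin"` here).
#' @seealso [derive_onel_code()] to recompute the same table from a codon
#'   table, [onel_lookup()] for per-residue lookup.
#' @examples
#' code <- onel_code()
#' code$mapping$S   # c("C", "G")
#' code$mapping$Q   # "A"
#' @export
onel_code <- function() {
  mapping <- list()
  for (nt in names(ONEL_PARTITION)) {
    for (aa in ONEL_PARTITION[[nt]]) mapping[[aa]] <- nt
  }
  mapping[["S"]] <- c("C", "G")
  new_onel_code(mapping, "builtin")
}

#' Derive the 1-L code from a codon table
#'
#' Recomputes the amino-acid to nucleotide mapping from an explicit codon
#' table by collecting, for each amino acid, the distinct letters at codon
#' position 2. Stop codons are ignored. With the standard genetic code the
#' result is identical to [onel_code()]; the derivation exists so the
#' built-in table is verifiable rather than asserted.
#'
#' @param codon_table Named character vector mapping DNA codons to one-letter
#'   amino-acid codes, with `"*"` for stops. Defaults to
#'   [Biostrings::GENETIC_CODE].
#' @return An `onel_code` object with `source = "derived-from-codon-table"`.
#' @examples
#' identical(derive_onel_code()$mapping, onel_code()$mapping)
#' @export
derive_onel_code <- function(codon_table = Biostrings::GENETIC_CODE) {
  if (is.null(names(codon_table)) ||
      !all(grepl("^[ACGT]{3}$", names(codon_table)))) {
    stop("'codon_table' must be named by DNA triplets over {A,C,G,T}",
         call. = FALSE)
  }
  sense <- codon_table[codon_table != "*"]
  aas <- unique(unname(sense))
  missing_aa <- setdiff(STANDARD_AA, aas)
  if (length(missing_aa) > 0L) {
    stop("codon table lacks codons for: ", paste(missing_aa, collapse = ", "),
         call. = FALSE)
  }
  second <- substr(names(sense), 2L, 2L)
  mapping <- lapply(
    split(second, unname(sense)),
    function(x) sort(unique(x))
  )
  new_onel_code(mapping, "derived-from-codon-table")
}

#' Look up the nucleotide for one residue
#'
#' @param code An `onel_code` object.
#' @param residue A single amino-acid letter (case-insensitive).
#' @param serine_policy `"C"` or `"G"`: which of serine's two letters to emit.
#' @param unknown Policy for non-standard residues (`B`, `J`, `O`, `U`, `X`,
#'   `Z`, `*`, ...): `"N"` substitutes the placeholder `N` with a warning
#'   (the default, since real protein FASTA contains `X`; `N` never seeds or
#'   extends an alignment), `"error"` stops.
#' @return A single DNA letter.
#' @examples
#' onel_lookup(onel_code(), "N")        # "A"
#' onel_lookup(onel_code(), "S", "G")   # "G"
#' @export
onel_lookup <- function(code, residue, serine_policy = c("C", "G"),
                        unknown = c("N", "error")) {
  stopifnot(inherits(code, "onel_code"))
  serine_policy <- match.arg(serine_policy)
  unknown <- match.arg(unknown)
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L) {
    stop("'residue' must be a single letter", call. = FALSE)
  }
  residue <- toupper(residue)
  if (residue == "S") return(serine_policy)
  nt <- code$mapping[[residue]]
  if (is.null(nt)) {
    if (unknown == "error") {
      stop("non-standard residue '", residue, "'", call. = FALSE)
    }
    warning("non-standard residue '", residue, "' mapped to N", call. = FALSE)
    return("N")
  }
  nt
}

#' @export
print.onel_code <- function(x, ...) {
  cat("1-L protein-RNA recognition code (", x$source, ")\n", sep = "")
  for (aa in names(x$mapping)) {
    cat("  ", aa, " -> ", paste(x$mapping[[aa]], collapse = ","), "\n",
        sep = "")
  }
  invisible(x)
}

#' Export / import the code table as TSV
#'
#' Two columns: `residue` and the comma-joined nucleotide set. Round-trips
#' exactly through [read_onel_code()].
#'
#' @param code An `onel_code` object.
#' @param path File path.
#' @return `write_onel_code()` returns `path` invisibly; `read_onel_code()`
#'   returns an `onel_code` with `source = "imported"`.
#' @export
write_onel_code <- function(code, path) {
  stopifnot(inherits(code, "onel_code"))
  df <- data.frame(
    residue = names(code$mapping),
    nucleotides = vapply(code$mapping, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_onel_code
#' @export
read_onel_code <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!identical(sort(colnames(df)), c("nucleotides", "residue"))) {
    stop("expected columns 'residue' and 'nucleotides'", call. = FALSE)
  }
  mapping <- lapply(strsplit(df$nucleotides, ",", fixed = TRUE), sort)
  names(mapping) <- df$residue
  code <- new_onel_code(mapping, "imported")
  validate_onel_code(code)
  code
}

validate_onel_code <- function(code) {
  m <- code$mapping
  if (!setequal(names(m), STANDARD_AA)) {
    stop("code must cover exactly the 20 standard amino acids", call. = FALSE)
  }
  sizes <- lengths(m)
  if (sizes[["S"]] != 2L || any(sizes[setdiff(names(sizes), "S")] != 1L)) {
    stop("serine must map to 2 nucleotides and every other residue to 1",
         call. = FALSE)
  }
  if (!all(unlist(m) %in% c("A", "C", "G", "T"))) {
    stop("code values must be DNA letters", call. = FALSE)
  }
  invisible(code)
}
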