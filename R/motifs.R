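# Regulatory-element scanners for transcribed variants (the candidate
# "imaginary RNA"). Motif matching is literal on the variant as written; no
# complementing is applied here (strandedness is the search module's job).
# Coordinates are 1-based closed intervals.

MOTIF_CLASSES <- c("PAS", "ARE_I", "ARE_II", "ARE_III")

empty_motif_hits <- function() {
  data.frame(
    variant_id = character(0), motif_class = character(0),
    start = integer(0), end = integer(0), matched = character(0),
    stringsAsFactors = FALSE
  )
}

motif_hits <- function(variant_id, motif_class, start, end, seq) {
  if (length(start) == 0L) return(empty_motif_hits())
  data.frame(
    variant_id = variant_id, motif_class = motif_class,
    start = as.integer(start), end = as.integer(end),
    matched = substring(seq, start, end),
    stringsAsFactors = FALSE
  )
}

# All (possibly overlapping) occurrences of a literal word; left-to-right.
find_literal <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq))
  start(m)
}

#' Scan for the polyadenylation signal
#'
#' Reports every occurrence of the hexamer `AATAAA` (RNA `AAUAAA`) in a
#' variant sequence, overlapping occurrences included, in left-to-right
#' order.
#'
#' @param sequence Variant nucleotide sequence over `{A,C,G,T,N}` (a plain
#'   character scalar; `N` matches nothing).
#' @param variant_id Label carried into the output.
#' @return A data.frame with columns `variant_id`, `motif_class`, `start`,
#'   `end` (1-based, inclusive), `matched`; zero rows when nothing matches.
#' @examples
#' scan_pas("AATAAA")
#' scan_pas(transcribe_peptide(example_peptides()[["abeta42"]]))
#' @export
scan_pas <- function(sequence, variant_id = "variant") {
  check_nt_sequence(sequence)
  pos <- find_literal(sequence, "AATAAA")
  motif_hits(variant_id, "PAS", pos, pos + 5L, sequence)
}

#' Scan for AU-rich elements
#'
#' Class definitions follow the standard ARE classification:
#' * `ARE_I` — every occurrence of the pentamer `ATTTA`.
#' * `ARE_II` — maximal runs of two or more overlapping `ATTTA` copies
#'   (successive starts 4 apart, e.g. `ATTTATTTA`), each run reported as one
#'   hit spanning it.
#' * `ARE_III` — the U-rich class: every occurrence of the literal `TTTC`,
#'   plus every maximal T-rich region (merged windows of length `w` whose
#'   T fraction is at least `t_frac`), as separate hits.
#'
#' The literal `TTTC` is always reported for class III; the windowed rule is
#' a configurable surrogate for "rich in U", which has no standard
#' quantitative definition.
#'
#' @inheritParams scan_pas
#' @param are_class One of `"ARE_I"`, `"ARE_II"`, `"ARE_III"`.
#' @param w Window length for the class-III T-rich rule (>= 4).
#' @param t_frac Minimum T fraction in a qualifying window, in (0, 1].
#' @return A data.frame as in [scan_pas()].
#' @examples
#' scan_are("ATTTATTTA", "ARE_II")   # one merged hit spanning both copies
#' scan_are("GGTTTCGG", "ARE_III")
#' @export
scan_are <- function(sequence, are_class = c("ARE_I", "ARE_II", "ARE_III"),
                     variant_id = "variant", w = 8L, t_frac = 0.75) {
  are_class <- match.arg(are_class)
  check_nt_sequence(sequence)
  if (!is.numeric(w) || length(w) != 1L || w < 4) {
    stop("'w' must be a single number >= 4", call. = FALSE)
  }
  if (!is.numeric(t_frac) || length(t_frac) != 1L ||
      t_frac <= 0 || t_frac > 1) {
    stop("'t_frac' must be in (0, 1]", call. = FALSE)
  }
  w <- as.integer(w)

  switch(are_class,
    ARE_I = {
      pos <- find_literal(sequence, "ATTTA")
      motif_hits(variant_id, "ARE_I", pos, pos + 4L, sequence)
    },
    ARE_II = {
      pos <- find_literal(sequence, "ATTTA")
      runs <- overlapping_runs(pos, step = 4L, min_copies = 2L)
      motif_hits(variant_id, "ARE_II",
                 vapply(runs, min, 0L), vapply(runs, max, 0L) + 4L, sequence)
    },
    ARE_III = {
      lit <- find_literal(sequence, "TTTC")
      hits <- motif_hits(variant_id, "ARE_III", lit, lit + 3L, sequence)
      win <- t_rich_regions(sequence, w, t_frac)
      rbind(hits, motif_hits(variant_id, "ARE_III", win$start, win$end,
                             sequence))
    }
  )
}

# Group motif start positions into maximal runs of overlapping copies where
# successive starts are exactly `step` apart; keep runs of >= min_copies.
overlapping_runs <- function(pos, step, min_copies) {
  if (length(pos) < min_copies) return(list())
  grp <- cumsum(c(1L, diff(pos) != step))
  runs <- split(pos, grp)
  runs[lengths(runs) >= min_copies]
}

# Maximal T-rich regions: merge all length-w windows with T fraction >= f.
t_rich_regions <- function(seq, w, f) {
  n <- nchar(seq)
  if (n < w) return(data.frame(start = integer(0), end = integer(0)))
  is_t <- as.integer(strsplit(seq, "", fixed = TRUE)[[1L]] == "T")
  counts <- cumsum(is_t)
  starts <- seq_len(n - w + 1L)
  t_in_win <- counts[starts + w - 1L] - c(0L, counts)[starts]
  ok <- starts[t_in_win / w >= f]
  if (length(ok) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  # merge overlapping qualifying windows [s, s+w-1]
  grp <- cumsum(c(1L, diff(ok) > w))
  data.frame(
    start = vapply(split(ok, grp), min, 0L),
    end = vapply(split(ok, grp), max, 0L) + w - 1L
  )
}

#' Scan a table of variants for all motif classes
#'
#' @param variants Data.frame from [enumerate_variants()] (needs columns
#'   `variant_id`, `sequence`).
#' @param classes Motif classes to scan (default: PAS plus the three ARE
#'   classes).
#' @inheritParams scan_are
#' @return One data.frame of motif hits across all variants and classes.
#' @export
scan_motifs <- function(variants, classes = MOTIF_CLASSES, w = 8L,
                        t_frac = 0.75) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "sequence") %in% colnames(variants)))
  classes <- match.arg(classes, MOTIF_CLASSES, several.ok = TRUE)
  out <- lapply(seq_len(nrow(variants)), function(i) {
    vid <- variants$variant_id[i]
    seq <- variants$sequence[i]
    do.call(rbind, lapply(classes, function(cl) {
      if (cl == "PAS") scan_pas(seq, vid)
      else scan_are(seq, cl, vid, w = w, t_frac = t_frac)
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_motif_hits() else out
}

check_nt_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("'sequence' must be a single character string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("'sequence' must be over the alphabet {A,C,G,T,N}", call. = FALSE)
  }
  invisible(sequence)
}
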