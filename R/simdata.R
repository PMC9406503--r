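# Synthetic transcriptomes with planted ground truth. Background sequences
# are i.i.d. with a configurable GC fraction (no higher-order composition
# structure); planting substitutes the query (or its reverse complement)
# into a transcript at a recorded offset, keeping lengths fixed, and the
# manifest records the ground truth for end-to-end recovery checks.

#' Generate a random background transcriptome
#'
#' Sequences are i.i.d. draws with base probabilities
#' `A = T = (1 - gc)/2`, `C = G = gc/2`; lengths are uniform over
#' `length_range`. Regeneration with the same seed is byte-identical, and
#' the caller's RNG state is left untouched.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range Integer min/max transcript length (min >= 50).
#' @param gc_fraction Target G+C fraction, in (0, 1).
#' @param seed Random seed.
#' @return A named character vector (`synth_0001`, ...).
#' @examples
#' txome <- random_transcriptome(5, c(200, 400), 0.5, seed = 1)
#' nchar(txome)
#' @export
random_transcriptome <- function(n_transcripts, length_range = c(200L, 400L),
                                 gc_fraction = 0.5, seed = 1L) {
  stopifnot(is.numeric(n_transcripts), length(n_transcripts) == 1L,
            n_transcripts >= 1)
  if (length(length_range) != 2L || any(length_range < 50) ||
      length_range[1] > length_range[2]) {
    stop("'length_range' must be c(min, max) with 50 <= min <= max",
         call. = FALSE)
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("'gc_fraction' must be in (0, 1)", call. = FALSE)
  }
  n_transcripts <- as.integer(n_transcripts)
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  with_seed(seed, {
    span <- as.integer(length_range[2] - length_range[1] + 1L)
    lens <- length_range[1] + sample.int(span, n_transcripts,
                                         replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
            collapse = "")
    }, "")
    names(seqs) <- sprintf("synth_%04d", seq_len(n_transcripts))
    seqs
  })
}

#' Plant queries into a transcriptome with a ground-truth manifest
#'
#' Substitutes each query verbatim (strand `"plus"`) or as its reverse
#' complement (strand `"minus"`) into a distinct transcript at a random
#' offset, keeping transcript lengths fixed. The manifest records where
#' each plant went; [verify_manifest()] re-checks it against the emitted
#' sequences.
#'
#' @param transcriptome Named character vector of background transcripts.
#' @param queries Named character vector of query sequences; at most one
#'   plant per transcript, so `length(queries) <= length(transcriptome)`.
#' @param strands Character vector of `"plus"`/`"minus"`, recycled over
#'   queries.
#' @param seed Random seed governing transcript choice and offsets.
#' @return A list with `transcriptome` (modified vector) and `manifest`
#'   (data.frame: `subject_id`, `query_id`, `strand`, `offset` (1-based),
#'   `planted_sequence`).
#' @examples
#' txome <- random_transcriptome(4, c(200, 300), 0.5, seed = 1)
#' pl <- plant_queries(txome, c(q1 = "ACGTACGTACGTACGT"), "plus", seed = 2)
#' pl$manifest
#' @export
plant_queries <- function(transcriptome, queries, strands = "plus",
                          seed = 1L) {
  check_named_seqs(transcriptome, "transcriptome")
  check_named_seqs(queries, "queries")
  strands <- rep_len(strands, length(queries))
  if (!all(strands %in% c("plus", "minus"))) {
    stop("'strands' must be 'plus' or 'minus'", call. = FALSE)
  }
  if (length(queries) > length(transcriptome)) {
    stop("more queries (", length(queries), ") than transcripts (",
         length(transcriptome), "); one plant per transcript", call. = FALSE)
  }
  with_seed(seed, {
    targets <- sample(seq_along(transcriptome), length(queries))
    rows <- vector("list", length(queries))
    for (i in seq_along(queries)) {
      ti <- targets[i]
      subj <- transcriptome[[ti]]
      qlen <- nchar(queries[[i]])
      if (qlen > nchar(subj)) {
        stop("query '", names(queries)[i], "' (", qlen,
             " nt) is longer than transcript '",
             names(transcriptome)[ti], "' (", nchar(subj), " nt)",
             call. = FALSE)
      }
      planted <- if (strands[i] == "plus") queries[[i]] else
        revcomp(queries[[i]])
      offset <- sample.int(nchar(subj) - qlen + 1L, 1L)
      substr(subj, offset, offset + qlen - 1L) <- planted
      transcriptome[[ti]] <- subj
      rows[[i]] <- data.frame(
        subject_id = names(transcriptome)[ti],
        query_id = names(queries)[i],
        strand = strands[i], offset = offset,
        planted_sequence = planted,
        stringsAsFactors = FALSE
      )
    }
    list(transcriptome = transcriptome, manifest = do.call(rbind, rows))
  })
}

#' Re-verify a plant manifest against a transcriptome
#'
#' @param transcriptome Named character vector.
#' @param manifest Manifest data.frame from [plant_queries()].
#' @return `TRUE` if every planted sequence is present verbatim at its
#'   recorded offset, else `FALSE`.
#' @export
verify_manifest <- function(transcriptome, manifest) {
  stopifnot(is.data.frame(manifest))
  all(vapply(seq_len(nrow(manifest)), function(i) {
    subj <- transcriptome[[manifest$subject_id[i]]]
    if (is.null(subj) || is.na(subj)) return(FALSE)
    off <- manifest$offset[i]
    planted <- manifest$planted_sequence[i]
    substr(subj, off, off + nchar(planted) - 1L) == planted
  }, logical(1)))
}
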