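# Interop with NCBI BLAST 12-column tabular output (-outfmt 6):
# qseqid sseqid pident length mismatch gapopen qstart qend sstart send
# evalue bitscore. Strand is implicit in the subject coordinates:
# sstart > send marks the minus strand.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Write a hit table as BLAST 12-column tabular
#'
#' @param hits Hit data.frame from [seed_extend_search()] or
#'   [parse_blast_tabular()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  df <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$identity_pct, 3), length = hits$align_len,
    mismatch = hits$mismatches, gapopen = hits$gap_opens,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    evalue = signif(hits$evalue, 6), bitscore = round(hits$bit_score, 1),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse BLAST 12-column tabular output
#'
#' Reads standard `-outfmt 6` rows into the package's hit-table layout,
#' inferring strand from the subject coordinates. Comment lines (`#`) are
#' skipped; malformed rows are reported with their line number. The raw
#' alignment score is not part of the format and is returned as `NA`.
#'
#' @param path Path to a tabular hit file.
#' @return A hit data.frame (see [seed_extend_search()]).
#' @export
parse_blast_tabular <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(empty_hits())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- keep[nf != 12L][1L]
    stop("line ", bad, ": expected 12 tab-separated columns, found ",
         nf[which(nf != 12L)[1L]], call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  num_cols <- 3:12
  nums <- suppressWarnings(apply(mat[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  if (anyNA(nums)) {
    bad_row <- which(apply(nums, 1, anyNA))[1L]
    stop("line ", keep[bad_row], ": non-numeric value in a numeric column",
         call. = FALSE)
  }
  sstart <- as.integer(nums[, 7]); send <- as.integer(nums[, 8])
  data.frame(
    query_id = mat[, 1], subject_id = mat[, 2],
    strand = ifelse(sstart > send, "minus", "plus"),
    identity_pct = nums[, 1], align_len = as.integer(nums[, 2]),
    mismatches = as.integer(nums[, 3]), gap_opens = as.integer(nums[, 4]),
    q_start = as.integer(nums[, 5]), q_end = as.integer(nums[, 6]),
    s_start = sstart, s_end = send,
    evalue = nums[, 9], bit_score = nums[, 10], score = NA_integer_,
    stringsAsFactors = FALSE
  )
}
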