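# Word-seeded local alignment of variants against a transcriptome, both
# strands, with BLAST-style expectation values. Exact word seeds (default
# length 7) select candidate (subject, strand) pairs; each candidate is then
# scored by a full gapped local-alignment DP, so the best hit per pair is
# exact under the scoring scheme rather than extension-heuristic. The minus
# strand is searched by reverse-complementing the query; subject coordinates
# are reported on the plus strand with the BLAST convention s_start > s_end.

# Karlin-Altschul constants for the supported (match, mismatch) schemes,
# uniform base composition. NCBI-style approximations; see
# solve_karlin_lambda() for the exact ungapped lambda of any scheme.
KARLIN_TABLE <- list(
  "2,-3" = c(lambda = 0.625, K = 0.41),
  "1,-2" = c(lambda = 1.28, K = 0.46)
)

#' Search parameter set
#'
#' Defaults mirror short-query nucleotide BLAST behaviour: word size 7,
#' match +2 / mismatch -3, gap open 5 / gap extend 2 (a length-k gap costs
#' `gap_open + k * gap_extend`), expectation threshold 100, at most 500
#' distinct subjects, and no low-complexity filtering (the queries of
#' interest are short and A/T-rich, which composition filters would erase).
#' These are this package's defaults, not verbatim NCBI internals.
#'
#' @param word_size Seed word length (>= 4).
#' @param match,mismatch Match reward (> 0) and mismatch penalty (< 0).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param evalue_max Keep hits with expectation value at most this.
#' @param max_targets Maximum number of distinct subjects reported.
#' @param lambda_k Named numeric `c(lambda=, K=)` for the expectation-value
#'   statistics. Defaults to the shipped constants for the chosen
#'   (match, mismatch) scheme; for a scheme not in the shipped table you must
#'   supply your own values.
#' @return An object of class `search_params` (a validated list).
#' @examples
#' search_params()
#' search_params(word_size = 11, evalue_max = 10)
#' @export
search_params <- function(word_size = 7L, match = 2L, mismatch = -3L,
                          gap_open = 5L, gap_extend = 2L,
                          evalue_max = 100, max_targets = 500L,
                          lambda_k = NULL) {
  if (is.null(lambda_k)) {
    key <- paste0(match, ",", mismatch)
    lambda_k <- KARLIN_TABLE[[key]]
    if (is.null(lambda_k)) {
      stop("no built-in (lambda, K) for match=", match, ", mismatch=",
           mismatch, "; supply lambda_k = c(lambda=, K=)", call. = FALSE)
    }
  }
  if (!is.numeric(lambda_k) || !all(c("lambda", "K") %in% names(lambda_k)) ||
      lambda_k[["lambda"]] <= 0 || lambda_k[["K"]] <= 0) {
    stop("'lambda_k' must be a named numeric with positive 'lambda' and 'K'",
         call. = FALSE)
  }
  p <- list(
    word_size = as.integer(word_size), match = as.integer(match),
    mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend), evalue_max = as.numeric(evalue_max),
    max_targets = as.integer(max_targets),
    lambda_k = lambda_k[c("lambda", "K")]
  )
  stopifnot(
    p$word_size >= 4L,
    p$match > 0L, p$mismatch < 0L,
    p$gap_open >= 0L, p$gap_extend >= 0L,
    p$evalue_max > 0, p$max_targets >= 1L
  )
  structure(p, class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat("search parameters: word", x$word_size,
      sprintf("| score %+d/%+d gap %d/%d", x$match, x$mismatch,
              x$gap_open, x$gap_extend),
      "| E <=", x$evalue_max, "| max targets", x$max_targets,
      sprintf("| lambda %.4g K %.4g\n",
              x$lambda_k[["lambda"]], x$lambda_k[["K"]]))
  invisible(x)
}

#' Solve the Karlin-Altschul equation for the ungapped lambda
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for `lambda > 0` under an
#' i.i.d. background, the defining equation of the scale parameter of local
#' ungapped alignment score statistics. Requires a negative expected
#' per-column score.
#'
#' @param match,mismatch Match/mismatch scores.
#' @param base_freq Background base frequencies (length 4, summing to 1).
#' @return The positive root `lambda`.
#' @examples
#' solve_karlin_lambda(2, -3)   # ~0.633 at uniform composition
#' @export
solve_karlin_lambda <- function(match = 2, mismatch = -3,
                                base_freq = rep(0.25, 4)) {
  stopifnot(length(base_freq) == 4L, abs(sum(base_freq) - 1) < 1e-8)
  p_match <- sum(base_freq^2)
  exp_score <- p_match * match + (1 - p_match) * mismatch
  if (exp_score >= 0) {
    stop("expected per-column score must be negative", call. = FALSE)
  }
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  uniroot(f, c(1e-9, 50), tol = 1e-12)$root
}

#' Expectation value and bit score of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' total database length; `bits = (lambda * S - log K) / log 2`.
#'
#' @param score Raw alignment score (> 0).
#' @param query_len,db_len Query length and summed database length (> 0).
#' @param lambda_k Named numeric `c(lambda=, K=)`.
#' @return A numeric expectation value (resp. bit score).
#' @examples
#' evalue_from_score(40, 42, 1e5, c(lambda = 0.625, K = 0.41))
#' @export
evalue_from_score <- function(score, query_len, db_len, lambda_k) {
  stopifnot(all(score > 0), query_len > 0, db_len > 0,
            is.numeric(lambda_k), all(c("lambda", "K") %in% names(lambda_k)))
  lambda_k[["K"]] * query_len * db_len * exp(-lambda_k[["lambda"]] * score)
}

#' @rdname evalue_from_score
#' @export
bit_score <- function(score, lambda_k) {
  stopifnot(is.numeric(lambda_k), all(c("lambda", "K") %in% names(lambda_k)))
  (lambda_k[["lambda"]] * score - log(lambda_k[["K"]])) / log(2)
}

# All words of length w starting at each position; names are start offsets.
sequence_words <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  starts <- seq_len(n - w + 1L)
  substring(seq, starts, starts + w - 1L)
}

#' Build an exact-word index over a transcriptome
#'
#' Indexes every plus-strand word of length `word_size` to its
#' `(subject, offset)` postings. Words containing `N` are not indexed.
#' The minus strand needs no postings: it is searched by
#' reverse-complementing the query.
#'
#' @param transcriptome Named character vector of transcript sequences
#'   (see [read_fasta()]).
#' @param word_size Word length.
#' @return An object of class `word_index` with elements `word_size`,
#'   `subject_ids`, `subject_lengths`, `postings` (an environment keyed by
#'   word, each value an integer matrix with columns `sid`, `pos`) and
#'   `n_postings`.
#' @examples
#' idx <- build_word_index(c(t1 = "ACGTACG"), word_size = 4)
#' idx$n_postings   # 4
#' @export
build_word_index <- function(transcriptome, word_size = 7L) {
  check_named_seqs(transcriptome, "transcriptome")
  word_size <- as.integer(word_size)
  stopifnot(word_size >= 4L)
  all_words <- character(0); all_sid <- integer(0); all_pos <- integer(0)
  for (i in seq_along(transcriptome)) {
    ws <- sequence_words(transcriptome[[i]], word_size)
    if (length(ws) == 0L) next
    keep <- !grepl("N", ws, fixed = TRUE)
    all_words <- c(all_words, ws[keep])
    all_sid <- c(all_sid, rep.int(i, sum(keep)))
    all_pos <- c(all_pos, which(keep))
  }
  postings <- new.env(parent = emptyenv(), size = max(1L, length(all_words)))
  if (length(all_words) > 0L) {
    by_word <- split(seq_along(all_words), all_words)
    for (wd in names(by_word)) {
      k <- by_word[[wd]]
      postings[[wd]] <- cbind(sid = all_sid[k], pos = all_pos[k])
    }
  }
  structure(
    list(word_size = word_size,
         subject_ids = names(transcriptome),
         subject_lengths = nchar(unname(transcriptome)),
         postings = postings,
         n_postings = length(all_words)),
    class = "word_index"
  )
}

#' @export
print.word_index <- function(x, ...) {
  cat("word index:", length(x$subject_ids), "subjects,",
      x$n_postings, "postings of length", x$word_size, "\n")
  invisible(x)
}

empty_hits <- function() {
  data.frame(
    query_id = character(0), subject_id = character(0), strand = character(0),
    identity_pct = numeric(0), align_len = integer(0),
    mismatches = integer(0), gap_opens = integer(0),
    q_start = integer(0), q_end = integer(0),
    s_start = integer(0), s_end = integer(0),
    evalue = numeric(0), bit_score = numeric(0), score = integer(0),
    stringsAsFactors = FALSE
  )
}

# Candidate subject indices sharing at least one indexed word with qseq.
seed_candidates <- function(qseq, index) {
  ws <- sequence_words(qseq, index$word_size)
  ws <- unique(ws[!grepl("N", ws, fixed = TRUE)])
  sids <- integer(0)
  for (wd in ws) {
    p <- index$postings[[wd]]
    if (!is.null(p)) sids <- c(sids, p[, "sid"])
  }
  sort(unique(sids))
}

#' Seed-and-extend search of one query against a transcriptome
#'
#' Searches both strands: the query as written gives plus-strand hits, its
#' reverse complement minus-strand hits. Exact shared words of length
#' `word_size` select candidate subjects, and each candidate
#' (subject, strand) pair is scored by gapped local-alignment dynamic
#' programming under the scheme in `params`; the single best local alignment
#' per pair is reported. Hits with expectation value above
#' `params$evalue_max` are dropped, the rest sorted by ascending E-value
#' (ties by subject id, then subject start), and at most
#' `params$max_targets` distinct subjects are retained.
#'
#' Coordinates are 1-based inclusive; on the minus strand the subject
#' coordinates are reported on the plus strand with `s_start > s_end`
#' (BLAST convention), and the query span refers to the query as written.
#'
#' @param query Query nucleotide sequence (character scalar), at least
#'   `word_size` long.
#' @param transcriptome Named character vector of subject sequences.
#' @param params A [search_params()] object.
#' @param query_id Label carried into the hit table.
#' @param index Optional prebuilt [build_word_index()] over the same
#'   transcriptome (must have matching `word_size`); built on the fly when
#'   omitted.
#' @return A data.frame of alignment hits with columns `query_id`,
#'   `subject_id`, `strand`, `identity_pct`, `align_len`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `evalue`,
#'   `bit_score`, `score`.
#' @examples
#' txome <- c(t1 = paste(rep("ACGT", 30), collapse = ""))
#' seed_extend_search("ACGTACGTACGT", txome, search_params())
#' @export
seed_extend_search <- function(query, transcriptome,
                               params = search_params(),
                               query_id = "query", index = NULL) {
  stopifnot(inherits(params, "search_params"))
  check_nt_sequence(query)
  check_named_seqs(transcriptome, "transcriptome")
  qlen <- nchar(query)
  if (qlen < params$word_size) {
    stop("query length ", qlen, " is shorter than the word size ",
         params$word_size, call. = FALSE)
  }
  if (is.null(index)) {
    index <- build_word_index(transcriptome, params$word_size)
  } else {
    stopifnot(inherits(index, "word_index"))
    if (index$word_size != params$word_size) {
      stop("index word size (", index$word_size,
           ") does not match params word size (", params$word_size, ")",
           call. = FALSE)
    }
    if (!identical(index$subject_ids, names(transcriptome))) {
      stop("index subjects do not match the supplied transcriptome",
           call. = FALSE)
    }
  }
  db_len <- sum(index$subject_lengths)

  rows <- list()
  for (strand in c("plus", "minus")) {
    qseq <- if (strand == "plus") query else revcomp(query)
    for (sid in seed_candidates(qseq, index)) {
      subj <- transcriptome[[sid]]
      a <- sw_align_cpp(qseq, subj, params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
      if (a[["score"]] <= 0L) next
      ev <- evalue_from_score(a[["score"]], qlen, db_len, params$lambda_k)
      if (ev > params$evalue_max) next
      if (strand == "plus") {
        qs <- a[["q_start"]]; qe <- a[["q_end"]]
        ss <- a[["s_start"]]; se <- a[["s_end"]]
      } else {
        # alignment used revcomp(query): map back to the query as written,
        # flip subject coordinates so s_start > s_end marks the minus strand
        qs <- qlen - a[["q_end"]] + 1L; qe <- qlen - a[["q_start"]] + 1L
        ss <- a[["s_end"]]; se <- a[["s_start"]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query_id, subject_id = index$subject_ids[sid],
        strand = strand,
        identity_pct = 100 * a[["matches"]] / a[["align_len"]],
        align_len = a[["align_len"]], mismatches = a[["mismatches"]],
        gap_opens = a[["gap_opens"]],
        q_start = qs, q_end = qe, s_start = ss, s_end = se,
        evalue = ev, bit_score = bit_score(a[["score"]], params$lambda_k),
        score = a[["score"]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$evalue, hits$subject_id, pmin(hits$s_start, hits$s_end)), ,
               drop = FALSE]
  keep_subjects <- unique(hits$subject_id)
  if (length(keep_subjects) > params$max_targets) {
    keep_subjects <- keep_subjects[seq_len(params$max_targets)]
    hits <- hits[hits$subject_id %in% keep_subjects, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Search every variant of a peptide separately
#'
#' Runs [seed_extend_search()] for each row of a variant table (each of the
#' four candidate sequences is searched independently) against one shared
#' word index, and row-binds the hit tables. Variants shorter than the word
#' size cannot seed and are skipped with a warning naming them (unlike the
#' single-query [seed_extend_search()], which treats that as an error).
#'
#' @param variants Data.frame from [enumerate_variants()].
#' @inheritParams seed_extend_search
#' @return A combined hit data.frame.
#' @export
search_variants <- function(variants, transcriptome,
                            params = search_params(), index = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "sequence") %in% colnames(variants)))
  if (is.null(index)) {
    index <- build_word_index(transcriptome, params$word_size)
  }
  short <- nchar(variants$sequence) < params$word_size
  if (any(short)) {
    warning("skipping variant(s) shorter than the word size (",
            params$word_size, "): ",
            paste(variants$variant_id[short], collapse = ", "),
            call. = FALSE)
    variants <- variants[!short, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(variants)), function(i) {
    seed_extend_search(variants$sequence[i], transcriptome, params,
                       query_id = variants$variant_id[i], index = index)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_hits() else out
}

check_named_seqs <- function(x, what) {
  if (!is.character(x) || length(x) == 0L) {
    stop("'", what, "' must be a non-empty named character vector",
         call. = FALSE)
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("'", what, "' must have non-empty names", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate ids in '", what, "': ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
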