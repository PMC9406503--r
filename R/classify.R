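# Strand-labeled hits -> per-subject regulation calls. The modeling rule:
# a plus-strand (sense) alignment marks the transcript as a candidate for
# post-transcriptional repression, a minus-strand (antisense) alignment as a
# candidate for promotion. A subject hit on both strands yields two calls,
# one per mode. The biological direction of the effect is a modeling
# convention and may in reality be inverted; reports carry that caveat.

MODE_COLORS <- c(repressive = "green", promotive = "yellow")

empty_calls <- function() {
  data.frame(
    subject_id = character(0), mode = character(0),
    best_evalue = numeric(0), best_score = numeric(0),
    n_hits = integer(0), supporting_variants = character(0),
    stringsAsFactors = FALSE
  )
}

#' Classify alignment hits into regulation calls
#'
#' Groups hits by `(subject_id, strand)` and emits one call per group:
#' plus-strand groups become `"repressive"`, minus-strand groups
#' `"promotive"`. Each call carries the minimum E-value, maximum score,
#' hit count and the sorted set of supporting variant ids; calls are sorted
#' by ascending best E-value (ties by subject id, then mode).
#'
#' An optional transcript-to-gene map collapses isoforms: subjects are
#' renamed to their gene and groups re-aggregated per `(gene, mode)`, the
#' best E-value winning. Unmapped subjects keep their own id.
#'
#' @param hits Hit data.frame from [seed_extend_search()],
#'   [search_variants()] or [parse_blast_tabular()].
#' @param gene_map Optional data.frame with columns `transcript_id`,
#'   `gene_id`.
#' @return A data.frame with columns `subject_id`, `mode`, `best_evalue`,
#'   `best_score`, `n_hits`, `supporting_variants` (comma-joined).
#' @examples
#' hits <- data.frame(query_id = "v1", subject_id = "G", strand = "plus",
#'                    evalue = 0.5, score = 30)
#' classify_hits(hits)
#' @export
classify_hits <- function(hits, gene_map = NULL) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) return(empty_calls())
  needed <- c("query_id", "subject_id", "strand", "evalue", "score")
  missing_cols <- setdiff(needed, colnames(hits))
  if (length(missing_cols) > 0L) {
    stop("hits lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(hits$strand %in% c("plus", "minus"))) {
    stop("strand must be 'plus' or 'minus'", call. = FALSE)
  }
  subject <- hits$subject_id
  if (!is.null(gene_map)) {
    stopifnot(is.data.frame(gene_map),
              all(c("transcript_id", "gene_id") %in% colnames(gene_map)))
    idx <- match(subject, gene_map$transcript_id)
    subject <- ifelse(is.na(idx), subject, gene_map$gene_id[idx])
  }
  mode <- ifelse(hits$strand == "plus", "repressive", "promotive")
  key <- paste(subject, mode, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  calls <- do.call(rbind, lapply(groups, function(k) {
    data.frame(
      subject_id = subject[k[1L]], mode = mode[k[1L]],
      best_evalue = min(hits$evalue[k]),
      best_score = if (all(is.na(hits$score[k]))) NA_real_
                   else as.numeric(max(hits$score[k], na.rm = TRUE)),
      n_hits = length(k),
      supporting_variants = paste(sort(unique(hits$query_id[k])),
                                  collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  calls <- calls[order(calls$best_evalue, calls$subject_id, calls$mode), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Render a regulation report
#'
#' Adds the conventional color column (`"green"` for repressive,
#' `"yellow"` for promotive) and renders the call table as TSV, JSON or a
#' human-readable text table. The text and TSV headers carry the
#' interpretive caveat that sense/antisense mode assignment is a modeling
#' convention, not a measured direction of regulation.
#'
#' @param calls Call data.frame from [classify_hits()].
#' @param format `"tsv"`, `"json"` or `"text"`.
#' @return A character scalar holding the rendered document.
#' @export
render_report <- function(calls, format = c("tsv", "json", "text")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(calls))
  df <- calls
  df$color <- if (nrow(df)) unname(MODE_COLORS[df$mode]) else character(0)
  cols <- c("subject_id", "mode", "color", "best_evalue", "best_score",
            "n_hits", "supporting_variants")
  df <- df[, cols, drop = FALSE]
  caveat <- paste0(
    "# mode assignment: sense (plus-strand) hit = repressive, ",
    "antisense (minus-strand) hit = promotive; a modeling convention, ",
    "the biological direction may be inverted"
  )
  switch(format,
    tsv = {
      con <- textConnection("out", "w", local = TRUE)
      writeLines(caveat, con)
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      paste0(paste(out, collapse = "\n"), "\n")
    },
    json = paste0(jsonlite::toJSON(df, dataframe = "rows",
                                   digits = NA, pretty = TRUE), "\n"),
    text = {
      hdr <- paste(nrow(df), "regulation call(s)")
      body <- if (nrow(df) == 0L) "(no calls)" else
        paste(capture_table(df), collapse = "\n")
      paste0(caveat, "\n", hdr, "\n", body, "\n")
    }
  )
}

capture_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}

#' @rdname render_report
#' @param path Output file path.
#' @return `write_report()` returns `path` invisibly.
#' @export
write_report <- function(calls, path, format = c("tsv", "json", "text")) {
  format <- match.arg(format)
  writeLines(render_report(calls, format), path, sep = "")
  invisible(path)
}
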