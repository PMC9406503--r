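# Pipeline configuration and the end-to-end run:
# transcribe -> motifs -> search (each variant separately) -> classify.
# Configuration precedence: package defaults < YAML config file < arguments
# supplied explicitly in the call. Logging goes to standard error via
# message(); machine output goes only to files.

#' Assemble a pipeline configuration
#'
#' @param peptide_fasta Path to the protein FASTA with the query
#'   peptide(s).
#' @param transcriptome_fasta Path to the target transcriptome FASTA.
#' @param out_dir Output directory (created if absent).
#' @param directions Reading directions to keep (`"forward"`, `"reverse"`).
#' @param serine_policies Serine policies to keep (`"C"`, `"G"`).
#' @param alphabet `"dna"` or `"rna"`: display alphabet for the variant
#'   FASTA (searching always uses DNA internally).
#' @param motif_classes Motif classes to scan.
#' @param are_window,are_tfrac Class-III ARE window parameters, see
#'   [scan_are()].
#' @param search A [search_params()] object, or (in a YAML file) a mapping
#'   of its arguments.
#' @param gene_map_tsv Optional TSV with columns `transcript_id`,
#'   `gene_id`, used to collapse isoforms in [classify_hits()].
#' @param formats Report formats to write (`"tsv"`, `"json"`, `"text"`).
#' @param dedupe Collapse duplicate variant sequences before searching?
#' @param seed Seed recorded in the config (the pipeline itself is
#'   deterministic; the seed matters when the transcriptome comes from
#'   [random_transcriptome()]).
#' @param config_file Optional YAML file whose entries override the
#'   defaults (and are themselves overridden by explicit arguments).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(peptide_fasta = NULL, transcriptome_fasta = NULL,
                            out_dir = "onelcode_out",
                            directions = c("forward", "reverse"),
                            serine_policies = c("C", "G"),
                            alphabet = "dna",
                            motif_classes = MOTIF_CLASSES,
                            are_window = 8L, are_tfrac = 0.75,
                            search = search_params(),
                            gene_map_tsv = NULL,
                            formats = c("tsv", "json"),
                            dedupe = FALSE,
                            seed = 1L,
                            config_file = NULL) {
  cfg <- list(
    peptide_fasta = peptide_fasta, transcriptome_fasta = transcriptome_fasta,
    out_dir = out_dir, directions = directions,
    serine_policies = serine_policies, alphabet = alphabet,
    motif_classes = motif_classes, are_window = are_window,
    are_tfrac = are_tfrac, search = search, gene_map_tsv = gene_map_tsv,
    formats = formats, dedupe = dedupe, seed = seed
  )
  if (!is.null(config_file)) {
    yml <- yaml::read_yaml(config_file)
    bad <- setdiff(names(yml), names(cfg))
    if (length(bad) > 0L) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(yml$search)) yml$search <- do.call(search_params, yml$search)
    cfg <- modifyList(cfg, yml)
  }
  # explicit call arguments win over the file
  supplied <- as.list(match.call())[-1L]
  supplied$config_file <- NULL
  supplied <- lapply(supplied, eval, envir = parent.frame())
  cfg <- modifyList(cfg, supplied)

  stopifnot(all(cfg$directions %in% c("forward", "reverse")),
            all(cfg$serine_policies %in% c("C", "G")),
            cfg$alphabet %in% c("dna", "rna"),
            all(cfg$motif_classes %in% MOTIF_CLASSES),
            all(cfg$formats %in% c("tsv", "json", "text")),
            inherits(cfg$search, "search_params"))
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Reads the peptide and transcriptome FASTA files, enumerates the
#' candidate variants, scans them for motifs, searches each variant
#' separately against the transcriptome on both strands, classifies the
#' hits into regulation calls, and writes all stage outputs under
#' `config$out_dir`: `variants.fasta`, `motifs.tsv`, `hits.tsv` (extended,
#' with strand and header), `hits_outfmt6.tsv` (BLAST-compatible),
#' `calls.tsv` / `calls.json` / `calls.txt` per requested format. Per-stage
#' record counts are logged to standard error; any stage error aborts with
#' the stage name and cause.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with `variants`, `motifs`, `hits`, `calls`,
#'   `files` (named output paths) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$peptide_fasta) || is.null(config$transcriptome_fasta)) {
    stop("config needs both 'peptide_fasta' and 'transcriptome_fasta'",
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  peptides <- run_stage("input", read_fasta(config$peptide_fasta, "protein"))
  transcriptome <- run_stage("input",
                             read_fasta(config$transcriptome_fasta, "dna"))
  message("input: ", length(peptides), " peptide(s), ",
          length(transcriptome), " transcript(s)")

  variants <- run_stage("transcribe", {
    v <- enumerate_variants_all(peptides, dedupe = config$dedupe)
    v[v$direction %in% config$directions &
        v$serine_policy %in% config$serine_policies, , drop = FALSE]
  })
  if (nrow(variants) == 0L) {
    stop("[stage: transcribe] no variants left after direction/serine ",
         "filtering", call. = FALSE)
  }
  files$variants <- file.path(config$out_dir, "variants.fasta")
  out_seqs <- variants$sequence
  if (config$alphabet == "rna") out_seqs <- chartr("T", "U", out_seqs)
  write_fasta(setNames(out_seqs, variants$variant_id), files$variants,
              type = config$alphabet)
  message("transcribe: ", nrow(variants), " variant(s)")

  motifs <- run_stage("motifs",
    scan_motifs(variants, classes = config$motif_classes,
                w = config$are_window, t_frac = config$are_tfrac))
  files$motifs <- file.path(config$out_dir, "motifs.tsv")
  write.table(motifs, files$motifs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("motifs: ", nrow(motifs), " hit(s)")

  hits <- run_stage("search",
    search_variants(variants, transcriptome, params = config$search))
  files$hits <- file.path(config$out_dir, "hits.tsv")
  write.table(hits, files$hits, sep = "\t", quote = FALSE, row.names = FALSE)
  files$hits_outfmt6 <- file.path(config$out_dir, "hits_outfmt6.tsv")
  write_blast_tabular(hits, files$hits_outfmt6)
  message("search: ", nrow(hits), " alignment hit(s) on ",
          length(unique(hits$subject_id)), " subject(s)")

  calls <- run_stage("classify", {
    gene_map <- NULL
    if (!is.null(config$gene_map_tsv)) {
      gene_map <- read.table(config$gene_map_tsv, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    }
    classify_hits(hits, gene_map = gene_map)
  })
  for (fmt in config$formats) {
    ext <- c(tsv = "tsv", json = "json", text = "txt")[[fmt]]
    files[[paste0("calls_", fmt)]] <- file.path(config$out_dir,
                                                paste0("calls.", ext))
    write_report(calls, files[[paste0("calls_", fmt)]], fmt)
  }
  message("classify: ", nrow(calls), " regulation call(s)")

  invisible(list(variants = variants, motifs = motifs, hits = hits,
                 calls = calls, files = files, config = config))
}
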