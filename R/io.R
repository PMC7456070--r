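#' Read a FASTA file of coding sequences
#'
#' Sequences are uppercased and normalized to the RNA alphabet (T mapped to
#' U); record ids are the first whitespace-delimited token of each header.
#' Empty files, duplicate ids and characters outside A/C/G/T/U are errors,
#' reported with the record id and offending position.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return named character vector of RNA sequences.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "atgaaa"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  seqs <- normalize_rna(as.character(set), ids = ids)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read transcript models from a FASTA and a model table
#'
#' The table is tab-separated with columns `transcript_id`, `cds_offset`,
#' `junctions` (comma-separated transcript coordinates, possibly empty) and
#' an optional `tx_len`. Every table row must match a FASTA record holding
#' its CDS; [transcript_model()] invariants are enforced.
#'
#' @param fasta path to the CDS FASTA.
#' @param table path to the transcript-model table.
#' @return list of [transcript_model()] objects.
#' @export
read_transcript_models <- function(fasta, table) {
  seqs <- read_fasta(fasta)
  tab <- utils::read.delim(table, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  need <- c("transcript_id", "cds_offset", "junctions")
  if (!all(need %in% names(tab)))
    stop(sprintf("model table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  missing <- setdiff(tab$transcript_id, names(seqs))
  if (length(missing))
    stop(sprintf("transcript(s) in table missing from FASTA: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    jtxt <- tab$junctions[i]
    j <- if (is.na(jtxt) || !nzchar(jtxt)) integer() else {
      v <- suppressWarnings(as.integer(strsplit(jtxt, ",", fixed = TRUE)[[1L]]))
      if (anyNA(v))
        stop(sprintf("%s: non-numeric junction field '%s'",
                     tab$transcript_id[i], jtxt), call. = FALSE)
      v
    }
    tx_len <- if ("tx_len" %in% names(tab) && nzchar(tab$tx_len[i]))
      as.integer(tab$tx_len[i]) else NULL
    transcript_model(tab$transcript_id[i], seqs[[tab$transcript_id[i]]],
                     cds_offset = as.integer(tab$cds_offset[i]),
                     junctions = j, tx_len = tx_len)
  })
}

#' Write a transcript-model table
#'
#' @param models list of [transcript_model()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_transcript_models <- function(models, path) {
  tab <- data.frame(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    cds_offset = vapply(models, `[[`, 0L, "cds_offset"),
    junctions = vapply(models, function(m) paste(m$junctions, collapse = ","), ""),
    tx_len = vapply(models, `[[`, 0L, "tx_len"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table and classify status
#'
#' Tab-separated with header columns `transcript_id`, `log2fc`, `padj`.
#' A `status` column (down/up/unchanged) is added per [classify_de_status()];
#' row order is preserved.
#'
#' @param path DE table path.
#' @param lfc_threshold absolute log2 fold-change threshold (strict).
#' @param padj_threshold adjusted-p threshold (strict).
#' @return data.frame with columns transcript_id, log2fc, padj, status.
#' @export
read_de_table <- function(path, lfc_threshold = 1.0, padj_threshold = 0.05) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "log2fc", "padj")
  if (!all(need %in% names(tab)))
    stop(sprintf("DE table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  tab$log2fc <- suppressWarnings(as.numeric(tab$log2fc))
  tab$padj <- suppressWarnings(as.numeric(tab$padj))
  if (anyNA(tab$log2fc) || anyNA(tab$padj))
    stop("non-numeric log2fc/padj value in DE table", call. = FALSE)
  tab$status <- classify_de_status(tab$log2fc, tab$padj,
                                   lfc_threshold, padj_threshold)
  tab[c(need, "status")]
}

# Commented header recording provenance, written atop TSV outputs.
tsv_header_lines <- function(config = NULL, seed = NULL) {
  c(sprintf("# prfscan %s", as.character(utils::packageVersion("prfscan"))),
    if (!is.null(config)) sprintf("# config_md5 %s", config_fingerprint(config)),
    if (!is.null(seed)) sprintf("# seed %s", format(seed)))
}

write_tsv_with_header <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(tsv_header_lines(config, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a slippery-site/PRF-signal table
#'
#' The first three columns (`transcript_id`, `start`, `end`) are
#' BED-compatible (0-based, half-open). A commented header records the
#' package version, configuration fingerprint and seed.
#'
#' @param sites site data.frame from [scan_transcripts()].
#' @param path output TSV path.
#' @param config the [scan_config()] used.
#' @param seed seed used for the permutation stage.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path, config = NULL, seed = NULL) {
  write_tsv_with_header(sites, path, config = config, seed = seed)
}

#' Read back a site table written by [write_sites_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sites_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
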