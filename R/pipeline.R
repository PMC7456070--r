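#' Simulate a fixture directory
#'
#' Writes a synthetic transcriptome (FASTA of CDSs), a transcript-model
#' table, a DE table and the ground-truth table to `out_dir`. Deterministic
#' per seed: the same configuration produces byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @return invisibly, a list with the written paths and record counts.
#' @export
cmd_simulate <- function(out_dir, config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_transcriptome(config)
  de <- generate_de_table(sim$truth, config)
  paths <- list(fasta = file.path(out_dir, "transcripts.fa"),
                models = file.path(out_dir, "models.tsv"),
                de = file.path(out_dir, "de.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  seqs <- setNames(vapply(sim$models, `[[`, "", "cds"),
                   vapply(sim$models, `[[`, "", "transcript_id"))
  if (length(seqs)) write_fasta(seqs, paths$fasta) else
    writeLines(character(), paths$fasta)
  write_transcript_models(sim$models, paths$models)
  utils::write.table(de, paths$de, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf("simulate: wrote %d transcripts to %s",
                  length(sim$models), out_dir))
  invisible(c(paths, list(n = length(sim$models))))
}

#' Scan a transcriptome for -1 PRF signals and write a site table
#'
#' Wraps the scanner and structure stages over a FASTA + model table and
#' writes a TSV whose first three columns are BED-compatible.
#'
#' @param fasta CDS FASTA path.
#' @param models_table transcript-model table path.
#' @param out output sites TSV path.
#' @param config a [scan_config()].
#' @return invisibly, the site data.frame.
#' @export
cmd_scan <- function(fasta, models_table, out, config = scan_config()) {
  models <- read_transcript_models(fasta, models_table)
  sites <- scan_transcripts(models, config, fold = TRUE)
  sites$end <- sites$start + 7L
  cols <- c("transcript_id", "start", "end", "heptamer", "trna_class",
            "site_of_action", "in_frame", "spacer", "pair_score", "z",
            "p_perm", "passes")
  write_sites_tsv(sites[cols], out, config = config, seed = config$seed)
  message(sprintf("scan: %d transcripts, %d sites, %d passing signals",
                  length(models), nrow(sites), sum(sites$passes)))
  invisible(sites)
}

#' Frameshift/NMD verdicts for scanned transcripts
#'
#' Reads a site table written by [cmd_scan()], simulates the -1 slip at the
#' 5'-most passing Phe signal of each transcript, and writes per-transcript
#' PTC and NMD predictions.
#'
#' @param fasta CDS FASTA path.
#' @param models_table transcript-model table path.
#' @param sites_tsv site table from [cmd_scan()].
#' @param out output TSV path.
#' @param threshold NMD distance threshold in nt.
#' @return invisibly, the outcome data.frame.
#' @export
cmd_nmd <- function(fasta, models_table, sites_tsv, out, threshold = 50L) {
  models <- read_transcript_models(fasta, models_table)
  sites <- read_sites_tsv(sites_tsv)
  outcomes <- transcript_nmd(models, sites, threshold = threshold)
  write_tsv_with_header(outcomes, out)
  message(sprintf("nmd: %d transcripts with passing Phe signals, %d NMD-predicted",
                  nrow(outcomes), sum(outcomes$nmd_predicted)))
  invisible(outcomes)
}

#' Run the enrichment panel from files and write a report
#'
#' Reads a site table and a DE table, rebuilds transcript-level positive
#' sets, and writes the three-class enrichment panel for both comparators.
#'
#' @param fasta CDS FASTA path.
#' @param models_table transcript-model table path.
#' @param sites_tsv site table from [cmd_scan()].
#' @param de_tsv DE table path.
#' @param out output report TSV path.
#' @param ... passed to [prf_enrichment()].
#' @return invisibly, the `prf_enrichment` object.
#' @export
cmd_enrich <- function(fasta, models_table, sites_tsv, de_tsv, out, ...) {
  models <- read_transcript_models(fasta, models_table)
  sites <- read_sites_tsv(sites_tsv)
  de <- read_de_table(de_tsv)
  fit <- prf_enrichment(models, de, sites = sites, ...)
  write_tsv_with_header(fit$results, out)
  message(paste(utils::capture.output(print(fit)), collapse = "\n"))
  invisible(fit)
}
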