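#' Transcript model: CDS plus exon-junction coordinates
#'
#' The substrate of all scanning stages. Coordinates are 0-based and
#' half-open throughout. `cds_offset` is the transcript coordinate of the
#' first CDS base; each junction is recorded as the transcript coordinate of
#' the first base *after* the exon-exon junction, so distance arithmetic is
#' plain integer subtraction.
#'
#' @param transcript_id single identifier string.
#' @param cds coding sequence (DNA or RNA spelling; stored as RNA). Length
#'   must be at least 3 and a multiple of 3.
#' @param cds_offset non-negative integer transcript coordinate of the first
#'   CDS base.
#' @param junctions sorted (strictly increasing) integer vector of
#'   transcript coordinates, each the first base after a junction.
#' @param tx_len transcript length; defaults to `cds_offset + nchar(cds)`
#'   extended to cover the last junction. Junctions must lie in
#'   `[0, tx_len]`.
#' @return an object of class `transcript_model`.
#' @examples
#' transcript_model("t1", "AUGUUUUAA", junctions = c(4L, 20L), tx_len = 30L)
#' @export
transcript_model <- function(transcript_id, cds, cds_offset = 0L,
                             junctions = integer(), tx_len = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id))
  cds <- normalize_rna(cds, ids = transcript_id)
  n <- nchar(cds)
  if (n < 3L || n %% 3L != 0L)
    stop(sprintf("%s: CDS length %d is not a positive multiple of 3",
                 transcript_id, n), call. = FALSE)
  cds_offset <- as.integer(cds_offset)
  if (is.na(cds_offset) || cds_offset < 0L)
    stop(sprintf("%s: cds_offset must be a non-negative integer", transcript_id),
         call. = FALSE)
  junctions <- as.integer(junctions)
  if (anyNA(junctions))
    stop(sprintf("%s: non-numeric junction coordinate", transcript_id),
         call. = FALSE)
  if (length(junctions) > 1L && any(diff(junctions) <= 0L))
    stop(sprintf("%s: junctions must be strictly increasing", transcript_id),
         call. = FALSE)
  if (any(junctions < 0L))
    stop(sprintf("%s: junctions must be >= 0", transcript_id), call. = FALSE)
  if (is.null(tx_len)) {
    tx_len <- max(cds_offset + n, if (length(junctions)) max(junctions) else 0L)
  }
  tx_len <- as.integer(tx_len)
  if (tx_len < cds_offset + n)
    stop(sprintf("%s: tx_len shorter than cds_offset + CDS", transcript_id),
         call. = FALSE)
  if (any(junctions > tx_len))
    stop(sprintf("%s: junction beyond transcript length", transcript_id),
         call. = FALSE)
  structure(list(transcript_id = transcript_id, cds = cds,
                 cds_offset = cds_offset, junctions = junctions,
                 tx_len = tx_len),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript %s: CDS %d nt (offset %d), %d junction(s), tx %d nt\n",
              x$transcript_id, nchar(x$cds), x$cds_offset,
              length(x$junctions), x$tx_len))
  invisible(x)
}

#' Does a CDS contain an in-frame phenylalanine codon?
#'
#' `TRUE` iff any zero-frame codon of the CDS is UUU or UUC. Out-of-frame
#' occurrences do not count: the scan is over decoded codons.
#'
#' @param model a [transcript_model()].
#' @return logical scalar.
#' @examples
#' has_phe_codon(transcript_model("t", "AUGUUUUAA"))
#' has_phe_codon(transcript_model("t", "AUGGCGUAA"))
#' @export
has_phe_codon <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  any(cds_codons(model$cds) %in% PHE_CODONS)
}
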