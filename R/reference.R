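#' Published count data from the TYW2-knockout colon-cancer study
#'
#' The counts behind the headline proportions of the TYW2 epigenetic-loss
#' study that this package's analysis chain models: the RNA-seq
#' differential-expression tally in TYW2 CRISPR/Cas9-depleted HCT-116 cells
#' (2,370 altered transcripts, 2,046 of them down-regulated, 109 of the
#' down-regulated set carrying a predicted -1 PRF signal with a UUUU/C
#' slippery sequence) and the TYW2 promoter hypermethylation frequencies by
#' tumor type. Provided so that downstream summaries can recompute the
#' published percentages from their underlying counts.
#'
#' @return list with elements `de_total`, `de_down`, `prf_uuuuc_down` and
#'   `methylation` (data.frame with tumor type, methylated and total case
#'   counts).
#' @examples
#' counts <- tyw2_reference_counts()
#' 100 * counts$de_down / counts$de_total  # ~86% down-regulated
#' @export
tyw2_reference_counts <- function() {
  list(
    de_total = 2370L,
    de_down = 2046L,
    prf_uuuuc_down = 109L,
    methylation = data.frame(
      tumor_type = c("colorectal", "cervical", "gastric", "uterine"),
      methylated = c(79L, 45L, 51L, 60L),
      total = c(415L, 259L, 396L, 495L),
      stringsAsFactors = FALSE)
  )
}
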