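#' Find slippery heptamers in a CDS
#'
#' Scans the CDS for the X XXY YYZ pattern (N1=N2=N3 and N4=N5=N6; X may
#' equal Y, so e.g. UUUUUUU qualifies). With `require_frame = TRUE` only
#' frame-anchored sites are reported: the heptamer must start at CDS
#' coordinate 2 mod 3 so that N2 begins a zero-frame codon and the
#' post-slip codons N1N2N3 / N4N5N6 are the -1 frame. Overlapping sites in
#' homopolymeric runs are all reported; deduplication to transcript level
#' happens in the enrichment stage.
#'
#' @param model a [transcript_model()].
#' @param config a [scan_config()].
#' @return data.frame with columns transcript_id, start (0-based; the
#'   half-open end is start + 7), heptamer, p_codon (N2N3N4), a_codon
#'   (N5N6N7), trna_class (phe/lys/other), site_of_action (P/A/both/none)
#'   and in_frame, sorted by start.
#' @examples
#' m <- transcript_model("t1", "AUGCAAAAUUUUGCGUAA")
#' find_slippery_sites(m)
#' @export
find_slippery_sites <- function(model, config = scan_config()) {
  stopifnot(inherits(model, "transcript_model"), inherits(config, "scan_config"))
  cds <- model$cds
  if (nchar(cds) < 7L) return(empty_sites_df())
  starts <- find_slippery_starts_cpp(cds)
  if (config$require_frame) starts <- starts[starts %% 3L == 2L]
  if (!length(starts)) return(empty_sites_df())
  heptamer <- substr(rep(cds, length(starts)), starts + 1L, starts + 7L)
  cls <- classify_heptamers(heptamer, config$phe_mode)
  data.frame(transcript_id = model$transcript_id,
             start = as.integer(starts),
             heptamer = heptamer,
             p_codon = substr(heptamer, 2L, 4L),
             a_codon = substr(heptamer, 5L, 7L),
             trna_class = cls$trna_class,
             site_of_action = cls$site_of_action,
             in_frame = starts %% 3L == 2L,
             stringsAsFactors = FALSE)
}

empty_sites_df <- function() {
  data.frame(transcript_id = character(), start = integer(),
             heptamer = character(), p_codon = character(),
             a_codon = character(), trna_class = character(),
             site_of_action = character(), in_frame = logical(),
             stringsAsFactors = FALSE)
}

# Vectorized classification of slippery heptamers.
classify_heptamers <- function(heptamer, phe_mode) {
  p_codon <- substr(heptamer, 2L, 4L)
  a_codon <- substr(heptamer, 5L, 7L)
  suffix <- substr(heptamer, 4L, 7L)
  p_phe <- p_codon %in% PHE_CODONS; a_phe <- a_codon %in% PHE_CODONS
  p_lys <- p_codon %in% LYS_CODONS; a_lys <- a_codon %in% LYS_CODONS
  if (phe_mode == "a_site_suffix") {
    cls <- ifelse(suffix %in% PHE_SUFFIXES, "phe",
                  ifelse(suffix %in% LYS_SUFFIXES, "lys", "other"))
  } else {
    cls <- ifelse(p_phe | a_phe, "phe", ifelse(p_lys | a_lys, "lys", "other"))
  }
  in_p <- ifelse(cls == "phe", p_phe, ifelse(cls == "lys", p_lys, FALSE))
  in_a <- ifelse(cls == "phe", a_phe, ifelse(cls == "lys", a_lys, FALSE))
  soa <- ifelse(in_p & in_a, "both",
                ifelse(in_a, "A", ifelse(in_p, "P", "none")))
  list(trna_class = cls, site_of_action = soa)
}

#' Is a 7-mer a slippery heptamer?
#' @param heptamer 7-nt RNA string(s).
#' @return logical vector.
#' @export
is_slippery_heptamer <- function(heptamer) {
  stopifnot(all(nchar(heptamer) == 7L))
  n <- function(k) substr(heptamer, k, k)
  n(1) == n(2) & n(2) == n(3) & n(4) == n(5) & n(5) == n(6)
}

#' Attribute a slippery heptamer to its decoding tRNA
#'
#' Under `"a_site_suffix"` (the literal UUUU/C and AAAA/G reading) the class
#' is decided by positions N4-N7; under `"any_codon"` a heptamer is Phe-class
#' if either post-slip codon (P-site N2N3N4 or A-site N5N6N7) is UUU/UUC,
#' and analogously Lys-class for AAA/AAG. The site-of-action tag reports
#' which of the two codons is decoded by the attributed tRNA.
#'
#' @param heptamer a 7-nt slippery heptamer (precondition: matches X XXY YYZ).
#' @param phe_mode `"a_site_suffix"` or `"any_codon"`.
#' @return list with elements `trna_class` (phe/lys/other) and
#'   `site_of_action` (P/A/both/none).
#' @examples
#' classify_trna("GGGUUUC")                # phe, A site
#' classify_trna("UUUUUUA", "any_codon")   # HIV heptamer: phe via the P site
#' @export
classify_trna <- function(heptamer, phe_mode = c("a_site_suffix", "any_codon")) {
  phe_mode <- match.arg(phe_mode)
  heptamer <- normalize_rna(heptamer)
  stopifnot(length(heptamer) == 1L)
  if (!is_slippery_heptamer(heptamer))
    stop(sprintf("'%s' is not a slippery heptamer (X XXY YYZ)", heptamer),
         call. = FALSE)
  cls <- classify_heptamers(heptamer, phe_mode)
  list(trna_class = cls$trna_class, site_of_action = cls$site_of_action)
}
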