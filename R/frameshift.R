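#' Simulate a -1 frameshift and locate the premature termination codon
#'
#' After the slip the P- and A-site tRNAs re-pair to codons N1N2N3 and
#' N4N5N6, so -1-frame translation resumes at CDS coordinate
#' `site_start + 3` (codon N4N5N6) and proceeds in steps of 3. The PTC is
#' the first position p with `cds[p:p+3]` in \{UAA, UAG, UGA\}; if no stop
#' occurs before the CDS end the ribosome runs off and `ptc_found` is
#' FALSE.
#'
#' @param model a [transcript_model()].
#' @param site_start 0-based CDS coordinate of the heptamer's N1; must be
#'   frame-anchored (`site_start %% 3 == 2`).
#' @return list with `transcript_id`, `site_start`, `ptc_start` (0-based
#'   CDS coordinate of the stop's first base, or NA), `ptc_found`.
#' @examples
#' m <- transcript_model("t", "AUGCAAAAUUUUAAGUAA")
#' simulate_minus1(m, 5L)$ptc_start  # 11
#' @export
simulate_minus1 <- function(model, site_start) {
  stopifnot(inherits(model, "transcript_model"))
  site_start <- as.integer(site_start)
  if (site_start %% 3L != 2L)
    stop("site is not frame-anchored (start %% 3 must be 2)", call. = FALSE)
  L <- nchar(model$cds)
  stopifnot(site_start >= 0L, site_start + 7L <= L)
  p <- site_start + 3L
  ptc <- NA_integer_
  while (p + 3L <= L) {
    if (substr(model$cds, p + 1L, p + 3L) %in% STOP_CODONS) { ptc <- p; break }
    p <- p + 3L
  }
  list(transcript_id = model$transcript_id, site_start = site_start,
       ptc_start = ptc, ptc_found = !is.na(ptc))
}

#' Distance from a premature stop to the next exon-exon junction
#'
#' The distance is `j - (cds_offset + ptc_start + 3)`: from the first base
#' after the stop codon to the smallest junction strictly downstream of the
#' stop's last base. `NA` when no junction lies downstream (PTC in the last
#' exon).
#'
#' @param model a [transcript_model()].
#' @param ptc_start 0-based CDS coordinate of the stop codon's first base.
#' @return integer distance in nt, or NA.
#' @export
distance_to_next_junction <- function(model, ptc_start) {
  stopifnot(inherits(model, "transcript_model"), !is.na(ptc_start))
  stop_last <- model$cds_offset + as.integer(ptc_start) + 2L
  after <- model$junctions[model$junctions > stop_last]
  if (!length(after)) return(NA_integer_)
  min(after) - (stop_last + 1L)
}

#' Predict nonsense-mediated decay by the exon-junction rule
#'
#' A transcript is predicted to be an NMD substrate when the -1-frame PTC
#' exists and lies at least `threshold` nt upstream of the next exon-exon
#' junction. The canonical rule places the boundary at roughly 50-55 nt; the
#' default is 50 nt, inclusive.
#'
#' @param outcome a list with `ptc_found` and `dist_to_next_junction`
#'   (see [frameshift_outcome()]).
#' @param threshold minimum PTC-to-junction distance in nt.
#' @return logical scalar.
#' @export
predict_nmd <- function(outcome, threshold = 50L) {
  isTRUE(outcome$ptc_found) &&
    !is.na(outcome$dist_to_next_junction) &&
    outcome$dist_to_next_junction >= threshold
}

#' Full frameshift outcome at a slippery site
#'
#' Combines [simulate_minus1()], [distance_to_next_junction()] and
#' [predict_nmd()] into one record.
#'
#' @param model a [transcript_model()].
#' @param site_start 0-based, frame-anchored heptamer start.
#' @param threshold NMD distance threshold in nt.
#' @return list with transcript_id, site_start, ptc_start, ptc_found,
#'   dist_to_next_junction, nmd_predicted.
#' @export
frameshift_outcome <- function(model, site_start, threshold = 50L) {
  out <- simulate_minus1(model, site_start)
  out$dist_to_next_junction <- if (out$ptc_found)
    distance_to_next_junction(model, out$ptc_start) else NA_integer_
  out$nmd_predicted <- predict_nmd(out, threshold)
  out
}

#' Transcript-level NMD verdicts from annotated sites
#'
#' For each transcript the 5'-most *passing* Phe-class signal is taken as
#' the dominating slip site (the first slip encountered by the ribosome) and
#' its frameshift outcome gives the transcript-level verdict. Per-site
#' results remain available via [scan_transcripts()].
#'
#' @param models list of [transcript_model()] objects.
#' @param sites annotated site data.frame (from [scan_transcripts()] with
#'   `fold = TRUE`).
#' @param threshold NMD distance threshold in nt.
#' @return data.frame with one row per transcript carrying a passing
#'   Phe-class signal.
#' @export
transcript_nmd <- function(models, sites, threshold = 50L) {
  if (inherits(models, "transcript_model")) models <- list(models)
  idx <- setNames(seq_along(models), vapply(models, `[[`, "", "transcript_id"))
  keep <- sites[sites$trna_class == "phe" & sites$passes & sites$in_frame, ,
                drop = FALSE]
  if (!nrow(keep)) {
    return(data.frame(transcript_id = character(), site_start = integer(),
                      ptc_start = integer(), ptc_found = logical(),
                      dist_to_next_junction = integer(),
                      nmd_predicted = logical(), stringsAsFactors = FALSE))
  }
  keep <- keep[order(keep$transcript_id, keep$start), , drop = FALSE]
  first <- keep[!duplicated(keep$transcript_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(first)), function(i) {
    m <- models[[idx[[first$transcript_id[i]]]]]
    o <- frameshift_outcome(m, first$start[i], threshold)
    data.frame(transcript_id = o$transcript_id, site_start = o$site_start,
               ptc_start = ifelse(o$ptc_found, o$ptc_start, NA_integer_),
               ptc_found = o$ptc_found,
               dist_to_next_junction = o$dist_to_next_junction,
               nmd_predicted = o$nmd_predicted, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
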