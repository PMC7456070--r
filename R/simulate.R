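#' Synthetic transcriptome configuration
#'
#' Conditions for the ground-truth generator. Background coding sequences
#' are random non-stop codons (AUG first, one terminal stop); transcripts
#' selected for planting receive one frame-anchored slippery heptamer of
#' the chosen tRNA class, a spacer, a perfect reverse-complement hairpin
#' stem, a -1-frame stop codon and a downstream exon junction at a recorded
#' distance. The differential-expression layer assigns down-regulation with
#' a configurable odds ratio tied to the planted Phe signal.
#'
#' @param n_transcripts number of transcripts.
#' @param cds_len_range CDS length range in nt (values are used as
#'   multiples of 3).
#' @param junctions_per_transcript range of exon-junction counts.
#' @param p_plant_phe_signal,p_plant_lys_signal planting probabilities
#'   (their sum must not exceed 1).
#' @param hairpin_stem_len planted stem length in bp.
#' @param spacer planted spacer between heptamer and hairpin, in nt; must
#'   lie inside the scanner's spacer range to be recoverable.
#' @param base_p_down probability that a transcript without a planted Phe
#'   signal is down-regulated.
#' @param enrichment_odds_ratio odds ratio (>= 0) applied to the
#'   down-regulation odds of Phe-planted transcripts.
#' @param p_up probability that a non-down transcript is up-regulated,
#'   independent of planting.
#' @param seed integer seed; generation is fully reproducible.
#' @param reject_accidental resample background sequence containing
#'   accidental Phe/Lys-class slippery heptamers (default TRUE) so truth
#'   labels are unambiguous; disable to stress-test deduplication.
#' @return object of class `prf_sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000L,
                       cds_len_range = c(300L, 1500L),
                       junctions_per_transcript = c(2L, 8L),
                       p_plant_phe_signal = 0.2,
                       p_plant_lys_signal = 0.2,
                       hairpin_stem_len = 24L,
                       spacer = 6L,
                       base_p_down = 0.1,
                       enrichment_odds_ratio = 3,
                       p_up = 0.016,
                       seed = 1L,
                       reject_accidental = TRUE) {
  probs <- c(p_plant_phe_signal, p_plant_lys_signal, base_p_down, p_up)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p_plant_phe_signal + p_plant_lys_signal <= 1,
            enrichment_odds_ratio >= 0,
            hairpin_stem_len >= 3L, spacer >= 0L,
            n_transcripts >= 0L)
  cds_len_range <- as.integer(cds_len_range) %/% 3L * 3L
  stopifnot(length(cds_len_range) == 2L, cds_len_range[1L] >= 3L,
            cds_len_range[1L] <= cds_len_range[2L])
  cfg <- structure(list(
    n_transcripts = as.integer(n_transcripts),
    cds_len_range = cds_len_range,
    junctions_per_transcript = as.integer(junctions_per_transcript),
    p_plant_phe_signal = p_plant_phe_signal,
    p_plant_lys_signal = p_plant_lys_signal,
    hairpin_stem_len = as.integer(hairpin_stem_len),
    spacer = as.integer(spacer),
    base_p_down = base_p_down,
    enrichment_odds_ratio = enrichment_odds_ratio,
    p_up = p_up,
    seed = as.integer(seed),
    reject_accidental = isTRUE(reject_accidental)), class = "prf_sim_config")
  geom <- plant_geometry(cfg)
  min_needed <- 3L * 2L + geom$cassette_len + 2L + 3L + 3L
  if ((p_plant_phe_signal > 0 || p_plant_lys_signal > 0) &&
      cds_len_range[1L] < min_needed)
    stop(sprintf("infeasible config: minimum CDS length %d too short for a planted cassette (%d nt needed)",
                 cds_len_range[1L], min_needed), call. = FALSE)
  cfg
}

#' @export
print.prf_sim_config <- function(x, ...) {
  cat(sprintf("Synthetic transcriptome: n = %d, CDS %d-%d nt, seed %d\n",
              x$n_transcripts, x$cds_len_range[1L], x$cds_len_range[2L],
              x$seed))
  cat(sprintf("  planting: Phe %.2f, Lys %.2f (stem %d bp, spacer %d nt)\n",
              x$p_plant_phe_signal, x$p_plant_lys_signal,
              x$hairpin_stem_len, x$spacer))
  cat(sprintf("  DE layer: base P(down) %.3f, odds ratio %.2f, P(up) %.3f\n",
              x$base_p_down, x$enrichment_odds_ratio, x$p_up))
  invisible(x)
}

# Cassette geometry, all relative to the heptamer start s (which sits at a
# CDS coordinate congruent to 2 mod 3): heptamer (7 nt), spacer, hairpin
# (stem + 4 nt loop + stem), then the first -1-frame codon position at or
# after the hairpin end carries the planted UAA.
plant_geometry <- function(cfg) {
  hp <- 2L * cfg$hairpin_stem_len + 4L
  off <- 7L + cfg$spacer + hp           # first position after the hairpin
  m <- as.integer(ceiling((off - 3L) / 3L)) # -1 frame codons start at s+3+3m
  ptc_rel <- 3L + 3L * m
  list(hairpin_len = hp, ptc_rel = ptc_rel,
       cassette_len = ptc_rel + 3L)     # from s through the planted stop
}

NUC <- c("A", "C", "G", "U")
ALL_CODONS <- as.vector(outer(outer(NUC, NUC, paste0), NUC, paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

ACCIDENTAL_PATTERN <- "(AAA|CCC|GGG|UUU)(UUUU|UUUC|AAAA|AAAG)"

# The Phe/Lys-class slippery heptamers are 16 fixed 7-mers (4 homopolymer
# triplets x 4 class tetramers); fixed-string search is much faster than the
# regex for transcriptome-scale rejection.
CLASS_HEPTAMERS <- as.vector(outer(c("AAA", "CCC", "GGG", "UUU"),
                                   c("UUUU", "UUUC", "AAAA", "AAAG"),
                                   paste0))

has_class_heptamer <- function(x) {
  bad <- logical(length(x))
  for (p in CLASS_HEPTAMERS) bad <- bad | grepl(p, x, fixed = TRUE)
  bad
}

random_background_cds <- function(lengths, reject_accidental = TRUE,
                                  max_tries = 60L) {
  n <- length(lengths)
  gen <- function(lens) {
    k <- lens %/% 3L - 2L
    cod <- sample(NONSTOP_CODONS, sum(k), replace = TRUE)
    ends <- cumsum(k); starts <- ends - k + 1L
    term <- sample(STOP_CODONS, length(lens), replace = TRUE)
    vapply(seq_along(lens), function(i) {
      paste0("AUG", paste(cod[starts[i]:ends[i]], collapse = ""), term[i])
    }, character(1L))
  }
  out <- gen(lengths)
  if (reject_accidental) {
    for (try in seq_len(max_tries)) {
      bad <- has_class_heptamer(out)
      if (!any(bad)) break
      out[bad] <- gen(lengths[bad])
    }
    if (any(has_class_heptamer(out)))
      stop("could not generate accidental-free background sequence",
           call. = FALSE)
  }
  out
}

# All 0-based positions where a Phe- or Lys-class slippery heptamer occurs
# (frame-agnostic, overlap-aware).
class_pattern_positions <- function(seq, class) {
  pat <- if (class == "phe") "(?=([ACGU])\\1\\1UUU[UC])" else
    "(?=([ACGU])\\1\\1AAA[AG])"
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m) - 1L
}

# Validate a planted CDS: single in-frame stop (terminal), the planted
# heptamer is the only occurrence of its class, no cross-class occurrence,
# and the first -1-frame stop downstream of the slip is the planted one.
validate_plant <- function(cds, s, class, ptc) {
  cod <- cds_codons(cds)
  stops <- which(cod %in% STOP_CODONS)
  if (!identical(stops, length(cod))) return(FALSE)
  own <- class_pattern_positions(cds, class)
  other <- class_pattern_positions(cds, if (class == "phe") "lys" else "phe")
  if (!identical(own, s) || length(other)) return(FALSE)
  p <- s + 3L
  while (p + 3L <= nchar(cds)) {
    if (substr(cds, p + 1L, p + 3L) %in% STOP_CODONS) return(p == ptc)
    p <- p + 3L
  }
  FALSE
}

# Overwrite a clean background CDS with a planted cassette at heptamer
# start s (0-based). Returns list(cds, ptc) or NULL after too many tries.
plant_cassette <- function(cds, s, class, cfg, max_tries = 100L) {
  geom <- plant_geometry(cfg)
  ptc <- s + geom$ptc_rel
  L <- nchar(cds)
  gap <- geom$ptc_rel - (7L + cfg$spacer + geom$hairpin_len)
  for (try in seq_len(max_tries)) {
    x <- sample(NUC, 1L)
    z <- if (class == "phe") sample(c("U", "C"), 1L) else sample(c("A", "G"), 1L)
    yyy <- if (class == "phe") "UUU" else "AAA"
    heptamer <- paste0(strrep(x, 3L), yyy, z)
    spacer_seq <- paste(sample(NONSTOP_CODONS, cfg$spacer %/% 3L + 1L,
                               replace = TRUE), collapse = "")
    spacer_seq <- substr(spacer_seq, 1L, cfg$spacer)
    stem <- paste(sample(NUC, cfg$hairpin_stem_len, replace = TRUE),
                  collapse = "")
    loop <- paste(sample(NUC, 4L, replace = TRUE), collapse = "")
    filler <- if (gap > 0L)
      paste(sample(NUC, gap, replace = TRUE), collapse = "") else ""
    cassette <- paste0("GC", heptamer, spacer_seq, stem, loop,
                       rna_revcomp(stem), filler, "UAA")
    new_cds <- paste0(substr(cds, 1L, s - 2L), cassette,
                      substr(cds, s + geom$cassette_len + 1L, L))
    if (validate_plant(new_cds, s, class, ptc))
      return(list(cds = new_cds, ptc = ptc))
  }
  NULL
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' See [sim_config()] for the generative model. Truth records every planted
#' quantity so that each pipeline stage can be checked for exact recovery.
#'
#' @param config a [sim_config()].
#' @return list with `models` (list of [transcript_model()]) and `truth`
#'   (data.frame with transcript_id, planted_class, site_start, ptc_start,
#'   junction_distance, cds_offset, cds_len).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "prf_sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  truth <- data.frame(transcript_id = character(n),
                      planted_class = character(n),
                      site_start = rep(NA_integer_, n),
                      ptc_start = rep(NA_integer_, n),
                      junction_distance = rep(NA_integer_, n),
                      cds_offset = rep(NA_integer_, n),
                      cds_len = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(list(models = list(), truth = truth))
  ids <- sprintf("TX%05d", seq_len(n))
  lens <- sample(seq(config$cds_len_range[1L], config$cds_len_range[2L],
                     by = 3L), n, replace = TRUE)
  u <- runif(n)
  classes <- ifelse(u < config$p_plant_phe_signal, "phe",
                    ifelse(u < config$p_plant_phe_signal +
                             config$p_plant_lys_signal, "lys", "none"))
  cds <- random_background_cds(lens, config$reject_accidental)
  geom <- plant_geometry(config)
  jr <- config$junctions_per_transcript
  models <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    site_start <- NA_integer_; ptc <- NA_integer_; jdist <- NA_integer_
    if (classes[i] != "none") {
      kmax <- (L - 3L - 2L - geom$cassette_len - 2L) %/% 3L
      planted <- NULL
      for (attempt in seq_len(20L)) {
        k <- sample(seq_len(max(kmax, 1L)), 1L)
        s <- 3L * k + 2L
        planted <- plant_cassette(cds[i], s, classes[i], config)
        if (!is.null(planted)) { site_start <- s; break }
      }
      if (is.null(planted))
        stop(sprintf("infeasible config: could not plant a %s cassette in a %d nt CDS",
                     classes[i], L), call. = FALSE)
      cds[i] <- planted$cds
      ptc <- planted$ptc
    }
    cds_offset <- sample(0:200, 1L)
    tx_len <- cds_offset + L + sample(50:300, 1L)
    nj <- sample(jr[1L]:jr[2L], 1L)
    junc <- sort(unique(sample(seq_len(tx_len), min(nj, tx_len))))
    if (!is.na(ptc)) {
      jdist <- sample(20:150, 1L)
      stop_end <- cds_offset + ptc + 2L
      j_planted <- stop_end + 1L + jdist
      tx_len <- max(tx_len, j_planted + 10L)
      junc <- junc[junc <= stop_end | junc > j_planted]
      junc <- sort(unique(c(junc, j_planted)))
    }
    models[[i]] <- transcript_model(ids[i], cds[i], cds_offset = cds_offset,
                                    junctions = junc, tx_len = tx_len)
    truth$transcript_id[i] <- ids[i]
    truth$planted_class[i] <- classes[i]
    truth$site_start[i] <- site_start
    truth$ptc_start[i] <- ptc
    truth$junction_distance[i] <- jdist
    truth$cds_offset[i] <- cds_offset
    truth$cds_len[i] <- L
  }
  list(models = models, truth = truth)
}

#' Generate a differential-expression table tied to planted signals
#'
#' Each transcript is down-regulated with probability q where
#' `logit(q) = logit(base_p_down) + log(enrichment_odds_ratio)` for
#' Phe-planted transcripts (and plain `base_p_down` otherwise); non-down
#' transcripts are up-regulated with probability `p_up`, independent of
#' planting. Emitted log2 fold changes and adjusted p-values are drawn so
#' that the configured status thresholds reproduce the assigned labels
#' deterministically — the DE caller itself is not simulated, only the
#' downstream classification is under test.
#'
#' @param truth truth data.frame from [generate_transcriptome()].
#' @param config the same [sim_config()].
#' @return data.frame with columns transcript_id, log2fc, padj.
#' @export
generate_de_table <- function(truth, config) {
  stopifnot(inherits(config, "prf_sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  if (n == 0L)
    return(data.frame(transcript_id = character(), log2fc = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE))
  phe <- truth$planted_class == "phe"
  eta <- qlogis(config$base_p_down) +
    ifelse(phe, log(config$enrichment_odds_ratio), 0)
  q <- plogis(eta)
  down <- runif(n) < q
  up <- !down & runif(n) < config$p_up
  log2fc <- runif(n, -0.95, 0.95)
  padj <- runif(n, 0.05, 1)
  log2fc[down] <- -runif(sum(down), 1.2, 4)
  padj[down] <- runif(sum(down), 0, 0.049)
  log2fc[up] <- runif(sum(up), 1.2, 4)
  padj[up] <- runif(sum(up), 0, 0.049)
  data.frame(transcript_id = truth$transcript_id, log2fc = log2fc,
             padj = padj, stringsAsFactors = FALSE)
}
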