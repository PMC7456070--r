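#' Maximum base-pair fold of an RNA window
#'
#' Nussinov-style base-pair maximization over nested pairings, counting
#' Watson-Crick (A-U, G-C) plus G-U wobble pairs, with every hairpin loop
#' required to hold at least `min_loop` unpaired bases (a pair (i, j) needs
#' j - i > min_loop). No energy model is applied: the score is the maximal
#' number of nested pairs, which is self-contained and exactly verifiable by
#' enumeration; a thermodynamic folder is a documented extension point.
#' The traceback is deterministic: it prefers pairing the smallest i and,
#' among optimal partners, the largest j.
#'
#' @param seq non-empty RNA (or DNA-spelled) string.
#' @param min_loop minimum hairpin-loop length in nt.
#' @return list with `pair_score` (integer) and `structure` (dot-bracket
#'   string of one optimal traceback; the number of `(` equals
#'   `pair_score`).
#' @examples
#' max_basepair_fold("GGGAAAACCC")$pair_score  # 3
#' max_basepair_fold("GCGC")$pair_score        # 0: no pair with j - i > 3
#' @export
max_basepair_fold <- function(seq, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq), min_loop >= 0L)
  seq <- normalize_rna(seq)
  res <- nussinov_fold_cpp(seq, as.integer(min_loop))
  list(pair_score = as.integer(res$pair_score), structure = res$structure)
}

#' Permutation z-score for a folded window
#'
#' Shuffles the window `n_perm` times (mononucleotide shuffle, preserving
#' base composition), refolds each shuffle, and standardizes the observed
#' pair score against the shuffle distribution:
#' `z = (observed - mean) / sd`. The one-sided permutation p-value is
#' `(1 + #\{shuffle score >= observed\}) / (n_perm + 1)`. A shuffle SD of
#' zero (e.g. a homopolymer window) is flagged degenerate with z = 0.
#' Positive z means more pairing than expected from composition alone.
#'
#' @param window RNA string.
#' @param n_perm number of shuffles (>= 1).
#' @param min_loop minimum hairpin-loop length.
#' @param seed optional integer; if given, the shuffle stream is seeded
#'   locally and the caller's RNG state is restored afterwards.
#' @return list with `z`, `p_perm`, `degenerate`, `observed`, `perm_mean`,
#'   `perm_sd`.
#' @export
permutation_zscore <- function(window, n_perm = 100L, min_loop = 3L,
                               seed = NULL) {
  stopifnot(n_perm >= 1L)
  window <- normalize_rna(window)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  obs <- nussinov_fold_cpp(window, as.integer(min_loop))$pair_score
  ch <- strsplit(window, "", fixed = TRUE)[[1L]]
  shuffles <- vapply(seq_len(n_perm),
                     function(i) paste(sample(ch), collapse = ""),
                     character(1L))
  scores <- nussinov_score_batch_cpp(shuffles, as.integer(min_loop))
  m <- mean(scores); s <- stats::sd(scores)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) 0 else (obs - m) / s
  p_perm <- (1 + sum(scores >= obs)) / (n_perm + 1)
  list(z = z, p_perm = p_perm, degenerate = degenerate,
       observed = as.integer(obs), perm_mean = m,
       perm_sd = if (is.finite(s)) s else 0)
}

#' Call a complete -1 PRF signal at a slippery site
#'
#' For each spacer length in `[min_spacer, max_spacer]` the window of
#' `window_len` nt starting at `start + 7 + spacer` (truncated at the CDS
#' end) is folded; the spacer maximizing the pair score is kept (ties go to
#' the smallest spacer) and its window is assessed against the permutation
#' null. The signal passes when an element exists, its pair score is at
#' least `min_pairs`, and its z-score is at least `z_cutoff`.
#'
#' @param model a [transcript_model()].
#' @param site one row of a [find_slippery_sites()] data.frame (or any list
#'   with a 0-based `start`).
#' @param config a [scan_config()].
#' @return list of class `prf_signal` with `site`, `element` (NULL when no
#'   window fits downstream of the site) and `passes`.
#' @export
call_prf_signal <- function(model, site, config = scan_config()) {
  stopifnot(inherits(model, "transcript_model"))
  res <- fold_site(model$cds, as.integer(site$start), config,
                   structure = TRUE)
  out <- list(site = site, element = res$element, passes = res$passes)
  class(out) <- "prf_signal"
  out
}

# Fold the spacer-range windows downstream of one site. Internal workhorse
# behind call_prf_signal/annotate_prf_signals; `structure = FALSE` skips the
# traceback (the score and z are unaffected).
fold_site <- function(cds, start, config, structure = FALSE) {
  L <- nchar(cds)
  stopifnot(start >= 0L, start + 7L <= L)
  spacers <- config$min_spacer:config$max_spacer
  wstarts <- start + 7L + spacers
  wends <- pmin(wstarts + config$window_len, L)
  ok <- wends - wstarts >= 1L
  if (!any(ok)) return(list(element = NULL, passes = FALSE))
  spacers <- spacers[ok]; wstarts <- wstarts[ok]; wends <- wends[ok]
  wins <- substr(rep(cds, length(wstarts)), wstarts + 1L, wends)
  scores <- nussinov_score_batch_cpp(wins, config$min_loop)
  best <- which.max(scores) # ties resolve to the smallest spacer
  perm <- permutation_zscore(wins[best], n_perm = config$n_perm,
                             min_loop = config$min_loop)
  element <- list(window_start = wstarts[best], window_end = wends[best],
                  spacer = spacers[best],
                  pair_score = as.integer(scores[best]),
                  structure = if (structure)
                    nussinov_fold_cpp(wins[best], config$min_loop)$structure
                  else NULL,
                  z = perm$z, p_perm = perm$p_perm,
                  degenerate = perm$degenerate)
  passes <- element$pair_score >= config$min_pairs &&
    !perm$degenerate && perm$z >= config$z_cutoff
  list(element = element, passes = passes)
}

#' @export
print.prf_signal <- function(x, ...) {
  cat(sprintf("-1 PRF signal at %s:%d (%s, %s)\n",
              x$site$transcript_id, x$site$start, x$site$heptamer,
              x$site$trna_class))
  if (is.null(x$element)) {
    cat("  no downstream window within the CDS\n")
  } else {
    cat(sprintf("  element %d-%d (spacer %d): %d pairs, z = %.2f, p_perm = %.3g\n",
                x$element$window_start, x$element$window_end,
                x$element$spacer, x$element$pair_score, x$element$z,
                x$element$p_perm))
  }
  cat(sprintf("  passes: %s\n", x$passes))
  invisible(x)
}

# Annotate a site data.frame with stimulatory-element columns. Only sites of
# the requested classes are folded (others get NA element fields and
# passes = FALSE), which keeps transcriptome-scale runs cheap.
annotate_prf_signals <- function(models, sites, config = scan_config(),
                                 classes = c("phe", "lys", "other")) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(sites)
  sites$spacer <- rep(NA_integer_, n)
  sites$window_start <- rep(NA_integer_, n)
  sites$window_end <- rep(NA_integer_, n)
  sites$pair_score <- rep(NA_integer_, n)
  sites$z <- rep(NA_real_, n); sites$p_perm <- rep(NA_real_, n)
  sites$degenerate <- rep(NA, n); sites$passes <- rep(FALSE, n)
  if (!n) return(sites)
  if (inherits(models, "transcript_model")) models <- list(models)
  cds_by_id <- setNames(vapply(models, `[[`, "", "cds"),
                        vapply(models, `[[`, "", "transcript_id"))
  todo <- which(sites$trna_class %in% classes)
  cds_v <- cds_by_id[sites$transcript_id[todo]]
  starts_v <- sites$start[todo]
  k <- length(todo)
  spacer <- rep(NA_integer_, k); wstart <- rep(NA_integer_, k)
  wend <- rep(NA_integer_, k); score <- rep(NA_integer_, k)
  z <- rep(NA_real_, k); p_perm <- rep(NA_real_, k)
  degen <- rep(NA, k); passes <- rep(FALSE, k)
  for (j in seq_len(k)) {
    sig <- fold_site(cds_v[[j]], starts_v[j], config)
    if (!is.null(sig$element)) {
      spacer[j] <- sig$element$spacer
      wstart[j] <- sig$element$window_start
      wend[j] <- sig$element$window_end
      score[j] <- sig$element$pair_score
      z[j] <- sig$element$z
      p_perm[j] <- sig$element$p_perm
      degen[j] <- sig$element$degenerate
    }
    passes[j] <- sig$passes
  }
  sites$spacer[todo] <- spacer
  sites$window_start[todo] <- wstart
  sites$window_end[todo] <- wend
  sites$pair_score[todo] <- score
  sites$z[todo] <- z
  sites$p_perm[todo] <- p_perm
  sites$degenerate[todo] <- degen
  sites$passes[todo] <- passes
  sites
}

#' Scan transcripts for slippery sites and -1 PRF signals
#'
#' Runs [find_slippery_sites()] over a list of transcript models and, when
#' `fold = TRUE`, annotates each site of the requested tRNA classes with its
#' downstream stimulatory element and pass verdict.
#'
#' @param models list of [transcript_model()] objects.
#' @param config a [scan_config()]; its `seed` (if any) seeds the
#'   permutation stage.
#' @param fold annotate sites with the structure stage?
#' @param classes tRNA classes to fold (default all).
#' @return data.frame of sites (possibly zero rows).
#' @export
scan_transcripts <- function(models, config = scan_config(), fold = TRUE,
                             classes = c("phe", "lys", "other")) {
  if (inherits(models, "transcript_model")) models <- list(models)
  cds_v <- vapply(models, `[[`, "", "cds")
  ids <- vapply(models, `[[`, "", "transcript_id")
  starts_list <- lapply(cds_v, find_slippery_starts_cpp)
  if (config$require_frame)
    starts_list <- lapply(starts_list, function(s) s[s %% 3L == 2L])
  nhits <- lengths(starts_list)
  starts <- unlist(starts_list, use.names = FALSE)
  if (!length(starts)) {
    sites <- empty_sites_df()
  } else {
    owner <- rep.int(seq_along(models), nhits)
    heptamer <- substr(cds_v[owner], starts + 1L, starts + 7L)
    cls <- classify_heptamers(heptamer, config$phe_mode)
    sites <- data.frame(transcript_id = ids[owner],
                        start = as.integer(starts),
                        heptamer = heptamer,
                        p_codon = substr(heptamer, 2L, 4L),
                        a_codon = substr(heptamer, 5L, 7L),
                        trna_class = cls$trna_class,
                        site_of_action = cls$site_of_action,
                        in_frame = starts %% 3L == 2L,
                        stringsAsFactors = FALSE)
  }
  if (fold) sites <- annotate_prf_signals(models, sites, config, classes)
  sites
}
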