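#' Scanning and structure-calling configuration
#'
#' Parameters controlling slippery-site detection and the downstream
#' stimulatory-structure stage. Defaults follow canonical -1 PRF geometry:
#' a 5-9 nt spacer between the heptamer and the stimulatory element, a 70 nt
#' folding window, and a permutation null on the maximal base-pair score.
#'
#' @param phe_mode how a heptamer is attributed to tRNA-Phe:
#'   `"a_site_suffix"` (the literal UUUU/C reading: positions N4-N7 are UUUU
#'   or UUUC) or `"any_codon"` (either post-slip codon is UUU/UUC, which also
#'   captures the HIV-type U UUU UUA heptamer slipping via the P-site Phe).
#' @param require_frame if `TRUE` (default), only sites whose N2 begins a
#'   zero-frame codon are reported (heptamer start at CDS position 2 mod 3).
#' @param min_spacer,max_spacer spacer range (nt) between heptamer end and
#'   the folded window.
#' @param window_len length (nt) of the downstream folding window.
#' @param min_pairs minimum base-pair score for a passing stimulatory element.
#' @param min_loop minimum unpaired hairpin-loop length (nt) for the fold.
#' @param n_perm number of mononucleotide shuffles for the permutation null.
#' @param z_cutoff minimum permutation z-score for a passing element (the
#'   observed pair score must exceed the shuffle mean by this many SDs).
#' @param seed integer seed used by stochastic stages; `NULL` leaves the RNG
#'   state untouched.
#' @return an object of class `scan_config`.
#' @examples
#' scan_config(n_perm = 50)
#' @export
scan_config <- function(phe_mode = c("a_site_suffix", "any_codon"),
                        require_frame = TRUE,
                        min_spacer = 5L, max_spacer = 9L,
                        window_len = 70L,
                        min_pairs = 15L, min_loop = 3L,
                        n_perm = 100L, z_cutoff = 1.64,
                        seed = NULL) {
  phe_mode <- match.arg(phe_mode)
  min_spacer <- as.integer(min_spacer); max_spacer <- as.integer(max_spacer)
  window_len <- as.integer(window_len); n_perm <- as.integer(n_perm)
  stopifnot(min_spacer <= max_spacer, min_spacer >= 0L,
            window_len > 0L, n_perm >= 1L, min_loop >= 0L, min_pairs >= 0L)
  structure(list(phe_mode = phe_mode, require_frame = isTRUE(require_frame),
                 min_spacer = min_spacer, max_spacer = max_spacer,
                 window_len = window_len, min_pairs = as.integer(min_pairs),
                 min_loop = as.integer(min_loop), n_perm = n_perm,
                 z_cutoff = as.numeric(z_cutoff),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("Slippery-site scan configuration\n")
  cat(sprintf("  phe_mode: %s; require_frame: %s\n", x$phe_mode, x$require_frame))
  cat(sprintf("  spacer: %d-%d nt; window: %d nt; min_loop: %d nt\n",
              x$min_spacer, x$max_spacer, x$window_len, x$min_loop))
  cat(sprintf("  pass rule: pair_score >= %d and z >= %.2f (%d shuffles)\n",
              x$min_pairs, x$z_cutoff, x$n_perm))
  invisible(x)
}

# Stable fingerprint of a configuration, recorded in output headers.
config_fingerprint <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
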