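#' Classify differential-expression status
#'
#' Down iff `log2fc < -lfc_threshold` and `padj < padj_threshold`; up iff
#' `log2fc > lfc_threshold` and `padj < padj_threshold`; otherwise
#' unchanged. Inequalities are strict, so values exactly at a threshold are
#' unchanged.
#'
#' @param log2fc numeric log2 fold changes.
#' @param padj adjusted p-values in \[0, 1\].
#' @param lfc_threshold absolute log2 fold-change threshold (default 1.0).
#' @param padj_threshold adjusted-p threshold (default 0.05).
#' @return character vector in \{down, up, unchanged\}.
#' @examples
#' classify_de_status(c(-1.5, -1.0, 2.0), c(0.01, 0.01, 0.20))
#' @export
classify_de_status <- function(log2fc, padj, lfc_threshold = 1.0,
                               padj_threshold = 0.05) {
  stopifnot(is.numeric(log2fc), is.numeric(padj))
  if (anyNA(log2fc) || anyNA(padj)) stop("NA in log2fc/padj", call. = FALSE)
  if (any(padj < 0 | padj > 1))
    stop("padj outside [0, 1]", call. = FALSE)
  sig <- padj < padj_threshold
  ifelse(sig & log2fc < -lfc_threshold, "down",
         ifelse(sig & log2fc > lfc_threshold, "up", "unchanged"))
}

# log factorial via lgamma
lfact <- function(n) lgamma(n + 1)
lchoose_lf <- function(n, k) lfact(n) - lfact(k) - lfact(n - k)

#' Exact hypergeometric tail probability for a 2x2 table
#'
#' Fisher's exact test computed from first principles via log-factorials.
#' With the table (a, b; c, d), the count a is hypergeometric with row
#' margin a + b and column margin a + c out of N = a + b + c + d.
#' `"one_greater"` sums P(X >= a) (enrichment direction); `"two"` sums the
#' probabilities of all tables whose point probability does not exceed that
#' of the observed table (with a 1e-7 relative tolerance on the comparison,
#' the standard convention for two-sided Fisher tests).
#'
#' @param a,b,c,d non-negative integer cell counts: a = down and
#'   signal-positive, b = down and signal-negative, c = comparator and
#'   signal-positive, d = comparator and signal-negative.
#' @param sided `"one_greater"` or `"two"`.
#' @return p-value in (0, 1]. A zero margin yields p = 1 with a warning.
#' @examples
#' hypergeom_tail(10, 0, 0, 10)          # 1 / choose(20, 10)
#' @export
hypergeom_tail <- function(a, b, c, d, sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  r1 <- a + b; k1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || k1 == 0 || r1 == N || k1 == N) {
    warning("degenerate margin in 2x2 table; p defined as 1")
    return(1)
  }
  lo <- max(0, r1 + k1 - N); hi <- min(r1, k1)
  x <- lo:hi
  logp <- lchoose_lf(r1, x) + lchoose_lf(N - r1, k1 - x) - lchoose_lf(N, k1)
  p_obs <- logp[x == a]
  if (sided == "one_greater") {
    p <- sum(exp(logp[x >= a]))
  } else {
    p <- sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
  }
  min(1, p)
}

#' Odds ratio of a 2x2 table
#' @inheritParams hypergeom_tail
#' @return `(a * d) / (b * c)`; `Inf` when `b * c == 0` and `a * d > 0`,
#'   `NaN` when both products are zero.
#' @export
odds_ratio <- function(a, b, c, d) (a * d) / (b * c)

#' Build the down-vs-comparator contingency table for a signal class
#'
#' Rows are down-regulated vs comparator transcripts; columns are
#' signal-positive vs signal-negative. Each transcript is counted once
#' (site-level results must be deduplicated to transcript level before this
#' step; `signal_positive_ids` is a set of transcript ids).
#'
#' @param de DE data.frame with columns `transcript_id` and `status`
#'   (see [read_de_table()]).
#' @param signal_positive_ids character vector of signal-positive
#'   transcript ids; must be a subset of the DE ids.
#' @param comparator `"up_regulated"` or `"prfdb_background"` (all scanned
#'   transcripts).
#' @return object of class `contingency_table`: list with a, b, c, d.
#' @export
build_contingency <- function(de, signal_positive_ids,
                              comparator = c("up_regulated",
                                             "prfdb_background")) {
  comparator <- match.arg(comparator)
  if (anyDuplicated(de$transcript_id))
    stop("duplicate transcript ids in DE table", call. = FALSE)
  signal_positive_ids <- unique(signal_positive_ids)
  missing <- setdiff(signal_positive_ids, de$transcript_id)
  if (length(missing))
    stop(sprintf("signal-positive id(s) absent from DE table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  down <- de$transcript_id[de$status == "down"]
  comp <- if (comparator == "up_regulated")
    de$transcript_id[de$status == "up"] else de$transcript_id
  if (!length(down)) stop("empty down-regulated class", call. = FALSE)
  if (!length(comp)) stop("empty comparator class", call. = FALSE)
  pos <- signal_positive_ids
  structure(list(a = sum(down %in% pos), b = sum(!(down %in% pos)),
                 c = sum(comp %in% pos), d = sum(!(comp %in% pos)),
                 comparator = comparator),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("down", x$comparator),
                              c("signal+", "signal-")))
  print(m)
  invisible(x)
}

# Transcript-level positive sets for the three-class control panel.
panel_positive_sets <- function(models, sites) {
  pass <- sites[sites$passes, , drop = FALSE]
  list(
    phe_uuuu_c = unique(pass$transcript_id[pass$trna_class == "phe"]),
    lys_aaaa_g = unique(pass$transcript_id[pass$trna_class == "lys"]),
    no_phe_codon = vapply(models, `[[`, "", "transcript_id")[
      !vapply(models, has_phe_codon, logical(1L))]
  )
}

#' Fit the slippery-signal enrichment panel
#'
#' The central analysis: scans the transcript models for slippery sites,
#' calls -1 PRF signals, and tests whether down-regulated transcripts are
#' enriched for Phe (UUUU/C) signal-positive transcripts relative to each
#' comparator, alongside two negative controls run with identical
#' machinery: Lys (AAAA/G) signal-positive transcripts and transcripts
#' lacking any in-frame UUU/UUC codon. Sidedness defaults to one-sided
#' enrichment; no multiple-testing correction is applied across the panel
#' unless `bonferroni = TRUE`.
#'
#' @param models list of [transcript_model()] objects.
#' @param de DE data.frame (see [read_de_table()]); ids must cover the
#'   scanned transcripts that enter the tables.
#' @param config a [scan_config()].
#' @param comparators comparator classes to test against.
#' @param sided `"one_greater"` or `"two"`.
#' @param bonferroni adjust p-values for the 3-class panel?
#' @param sites optional precomputed annotated site table (from
#'   [scan_transcripts()]); when supplied the scan is skipped.
#' @param fold_classes tRNA classes run through the structure stage when
#'   scanning internally (others cannot enter a positive set, so skipping
#'   them only saves time).
#' @return object of class `prf_enrichment` with methods [print()],
#'   [summary()], [coef()] (odds ratios) and [plot()].
#' @export
prf_enrichment <- function(models, de, config = scan_config(),
                           comparators = c("up_regulated",
                                           "prfdb_background"),
                           sided = c("one_greater", "two"),
                           bonferroni = FALSE, sites = NULL,
                           fold_classes = c("phe", "lys")) {
  sided <- match.arg(sided)
  comparators <- match.arg(comparators, several.ok = TRUE)
  if (is.null(sites))
    sites <- scan_transcripts(models, config, fold = TRUE,
                              classes = fold_classes)
  pos_sets <- panel_positive_sets(models, sites)
  rows <- list(); tables <- list()
  for (comp in comparators) {
    for (cls in names(pos_sets)) {
      tab <- build_contingency(de, pos_sets[[cls]], comp)
      p <- hypergeom_tail(tab$a, tab$b, tab$c, tab$d, sided)
      key <- paste(cls, comp, sep = ":")
      tables[[key]] <- tab
      rows[[key]] <- data.frame(
        signal_class = cls, comparator = comp,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        prop_down = tab$a / (tab$a + tab$b),
        prop_comparator = tab$c / (tab$c + tab$d),
        odds_ratio = odds_ratio(tab$a, tab$b, tab$c, tab$d),
        p = p, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (bonferroni)
    results$p_adj <- pmin(1, results$p * length(pos_sets))
  out <- list(results = results, tables = tables, sites = sites,
              positive_sets = pos_sets, config = config, sided = sided,
              n_down = sum(de$status == "down"),
              n_up = sum(de$status == "up"),
              n_total = nrow(de), call = match.call())
  class(out) <- "prf_enrichment"
  out
}

#' @export
print.prf_enrichment <- function(x, digits = 3, ...) {
  cat("Slippery-signal enrichment panel (-1 PRF)\n")
  cat(sprintf("  transcripts: %d (%d down, %d up); test: Fisher exact, %s\n",
              x$n_total, x$n_down, x$n_up,
              if (x$sided == "one_greater") "one-sided (greater)" else "two-sided"))
  df <- x$results
  df$prop_down <- round(df$prop_down, digits)
  df$prop_comparator <- round(df$prop_comparator, digits)
  df$odds_ratio <- signif(df$odds_ratio, digits)
  df$p <- signif(df$p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.prf_enrichment <- function(object, ...) {
  n_sites <- nrow(object$sites)
  n_pass <- sum(object$sites$passes)
  s <- list(results = object$results,
            n_sites = n_sites, n_pass = n_pass,
            n_positive = lengths(object$positive_sets),
            n_down = object$n_down, n_up = object$n_up,
            n_total = object$n_total, sided = object$sided)
  class(s) <- "summary.prf_enrichment"
  s
}

#' @export
print.summary.prf_enrichment <- function(x, ...) {
  cat("Slippery-signal enrichment panel (-1 PRF)\n")
  cat(sprintf("  %d transcripts (%d down, %d up); %d slippery sites, %d passing signals\n",
              x$n_total, x$n_down, x$n_up, x$n_sites, x$n_pass))
  cat("  signal-positive transcripts per class:\n")
  for (nm in names(x$n_positive))
    cat(sprintf("    %-14s %d\n", nm, x$n_positive[[nm]]))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' @export
coef.prf_enrichment <- function(object, ...) {
  setNames(object$results$odds_ratio,
           paste(object$results$signal_class, object$results$comparator,
                 sep = ":"))
}

#' @export
plot.prf_enrichment <- function(x, ...) {
  df <- x$results
  classes <- unique(df$signal_class)
  comps <- unique(df$comparator)
  height <- t(vapply(classes, function(cl) {
    r <- df[df$signal_class == cl & df$comparator == comps[1L], ]
    c(down = r$prop_down, comparator = r$prop_comparator)
  }, c(down = 0, comparator = 0)))
  graphics::barplot(t(height) * 100, beside = TRUE,
                    names.arg = classes,
                    legend.text = c("down-regulated", comps[1L]),
                    ylab = "signal-positive transcripts (%)",
                    main = "Slippery-signal enrichment", ...)
  invisible(x)
}
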