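# Independent brute-force oracles used to verify the implementation.

NUCS <- c("A", "C", "G", "U")

random_rna <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")

# --- slippery-site oracle: test the pattern predicate at every position ----
oracle_slippery_starts <- function(cds, require_frame = TRUE) {
  ch <- strsplit(cds, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  hits <- integer()
  for (i in seq_len(max(n - 6L, 0L))) { # 1-based start of the 7-mer
    if (ch[i] == ch[i + 1L] && ch[i + 1L] == ch[i + 2L] &&
        ch[i + 3L] == ch[i + 4L] && ch[i + 4L] == ch[i + 5L]) {
      s0 <- i - 1L # 0-based
      if (!require_frame || s0 %% 3L == 2L) hits <- c(hits, s0)
    }
  }
  hits
}

# --- folding oracle: exhaustive recursion over all nested pairings ---------
oracle_pairs_ok <- function(a, b) {
  (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "U") || (a == "U" && b == "G")
}

oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j) # i unpaired
    if (i + min_loop + 1L <= j) {
      for (k in (i + min_loop + 1L):j) {
        if (oracle_pairs_ok(ch[i], ch[k]))
          best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(ch))
}

# Parse a dot-bracket string into pair indices (1-based) and check validity
# against the sequence and the loop constraint.
check_structure <- function(seq, structure, min_loop = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  db <- strsplit(structure, "", fixed = TRUE)[[1L]]
  if (length(ch) != length(db)) return(FALSE)
  stack <- integer()
  for (i in seq_along(db)) {
    if (db[i] == "(") stack <- c(stack, i)
    else if (db[i] == ")") {
      if (!length(stack)) return(FALSE)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (i - j <= min_loop) return(FALSE)
      if (!oracle_pairs_ok(ch[j], ch[i])) return(FALSE)
    }
  }
  length(stack) == 0L
}

# --- hypergeometric oracle: full-table enumeration with choose() -----------
oracle_fisher_p <- function(a, b, c, d, sided = "one_greater") {
  r1 <- a + b; r2 <- c + d; k1 <- a + c; N <- r1 + r2
  lo <- max(0L, k1 - r2); hi <- min(r1, k1)
  xs <- lo:hi
  pmf <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, k1 - x) / choose(N, k1), numeric(1L))
  if (sided == "one_greater") sum(pmf[xs >= a])
  else sum(pmf[pmf <= pmf[xs == a] * (1 + 1e-7)])
}

# --- small fixture builders ------------------------------------------------
# A CDS of random non-stop codons (AUG first, terminal stop).
random_cds <- function(n_codons) {
  stops <- c("UAA", "UAG", "UGA")
  all_codons <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
  nonstop <- setdiff(all_codons, stops)
  paste0("AUG", paste(sample(nonstop, n_codons - 2L, replace = TRUE),
                      collapse = ""), sample(stops, 1L))
}
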