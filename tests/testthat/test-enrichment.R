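test_that("DE status uses strict inequalities at both thresholds", {
  expect_identical(classify_de_status(-1.5, 0.01), "down")
  expect_identical(classify_de_status(-1.0, 0.01), "unchanged")
  expect_identical(classify_de_status(1.2, 0.049), "up")
  expect_identical(classify_de_status(1.2, 0.05), "unchanged")
  expect_identical(classify_de_status(2.0, 0.20), "unchanged")
  expect_error(classify_de_status(1, 1.2), "padj")
})

test_that("hypergeometric tail matches the closed-form extreme table", {
  expect_equal(hypergeom_tail(10, 0, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
})

test_that("hypergeometric tail matches full-table enumeration", {
  set.seed(41)
  for (rep in 1:80) {
    cells <- as.integer(sample(0:20, 4, replace = TRUE))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    for (sided in c("one_greater", "two")) {
      p <- hypergeom_tail(a, b, c, d, sided)
      expect_equal(p, min(1, oracle_fisher_p(a, b, c, d, sided)),
                   tolerance = 1e-10,
                   info = sprintf("%d %d %d %d %s", a, b, c, d, sided))
    }
  }
})

test_that("hypergeometric tail agrees with fisher.test as a cross-check", {
  set.seed(42)
  for (rep in 1:30) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2, byrow = TRUE)
    expect_equal(hypergeom_tail(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(hypergeom_tail(m[1, 1], m[1, 2], m[2, 1], m[2, 2], "two"),
                 fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("p is invariant under simultaneous row and column swaps", {
  set.seed(43)
  for (rep in 1:25) {
    v <- sample(1:25, 4, replace = TRUE)
    expect_equal(hypergeom_tail(v[1], v[2], v[3], v[4]),
                 hypergeom_tail(v[4], v[3], v[2], v[1]))
    expect_equal(hypergeom_tail(v[1], v[2], v[3], v[4], "two"),
                 hypergeom_tail(v[4], v[3], v[2], v[1], "two"))
  }
})

test_that("one-sided p never increases when a grows at fixed margins", {
  set.seed(44)
  for (rep in 1:20) {
    r1 <- sample(5:25, 1); r2 <- sample(5:25, 1); k1 <- sample(3:20, 1)
    lo <- max(0, k1 - r2); hi <- min(r1, k1)
    ps <- vapply(lo:hi, function(a)
      hypergeom_tail(a, r1 - a, k1 - a, r2 - (k1 - a)), numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("degenerate margins warn and return p = 1", {
  expect_warning(p <- hypergeom_tail(0, 0, 5, 5), "degenerate")
  expect_equal(p, 1)
  expect_warning(hypergeom_tail(3, 0, 4, 0), "degenerate")
})

test_that("contingency construction counts transcripts once", {
  de <- data.frame(
    transcript_id = sprintf("t%d", 1:10),
    status = c(rep("down", 4), rep("up", 6)),
    stringsAsFactors = FALSE)
  tab <- build_contingency(de, c("t1", "t2", "t5"), "up_regulated")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 2L, b = 2L, c = 1L, d = 5L))

  expect_error(build_contingency(de, c("t1", "zz"), "up_regulated"),
               "zz")
  de_dup <- rbind(de, de[1, ])
  expect_error(build_contingency(de_dup, "t1", "up_regulated"), "duplicate")
  de_nodown <- transform(de, status = "up")
  expect_error(build_contingency(de_nodown, "t1", "up_regulated"),
               "empty down")
})

test_that("the enrichment panel detects planted Phe enrichment only", {
  cfg <- sim_config(n_transcripts = 600, p_plant_phe_signal = 0.25,
                    p_plant_lys_signal = 0.25, base_p_down = 0.15,
                    enrichment_odds_ratio = 8, p_up = 0.1, seed = 81)
  sim <- generate_transcriptome(cfg)
  de0 <- generate_de_table(sim$truth, cfg)
  de <- cbind(de0, status = classify_de_status(de0$log2fc, de0$padj))
  # the no-Phe-codon set can be empty at these CDS lengths, which the
  # machinery reports as a degenerate margin with p = 1
  fit <- suppressWarnings(
    prf_enrichment(sim$models, de, scan_config(n_perm = 25, seed = 82)))
  res <- fit$results
  phe <- res[res$signal_class == "phe_uuuu_c" &
               res$comparator == "prfdb_background", ]
  lys <- res[res$signal_class == "lys_aaaa_g" &
               res$comparator == "prfdb_background", ]
  expect_lt(phe$p, 0.01)
  expect_gt(phe$odds_ratio, 2)
  expect_gt(lys$p, 0.05)
  # methods on the fitted object
  expect_named(coef(fit))
  expect_s3_class(summary(fit), "summary.prf_enrichment")
  expect_output(print(fit), "enrichment panel")
})

test_that("an all-positive signal set hits the degenerate-margin path", {
  de <- data.frame(transcript_id = c("a", "b", "c", "d"),
                   status = c("down", "down", "up", "up"),
                   stringsAsFactors = FALSE)
  tab <- build_contingency(de, c("a", "b", "c", "d"), "up_regulated")
  expect_warning(p <- hypergeom_tail(tab$a, tab$b, tab$c, tab$d),
                 "degenerate")
  expect_equal(p, 1)
})
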