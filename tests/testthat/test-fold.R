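test_that("base-pair maximization handles boundary cases", {
  expect_equal(max_basepair_fold("AAAAAAAAAA")$pair_score, 0L)
  expect_identical(max_basepair_fold("AAAAAAAAAA")$structure, "..........")
  expect_equal(max_basepair_fold("GGGAAAACCC")$pair_score, 3L)
  # no pair satisfies j - i > min_loop
  expect_equal(max_basepair_fold("GCGC")$pair_score, 0L)
  expect_equal(max_basepair_fold("A")$pair_score, 0L)
})

test_that("fold equals the exhaustive nested-pairing oracle (n <= 12)", {
  set.seed(21)
  for (rep in 1:150) {
    n <- sample(1:12, 1)
    s <- random_rna(n)
    ml <- sample(0:4, 1)
    res <- max_basepair_fold(s, min_loop = ml)
    expect_equal(res$pair_score, oracle_max_pairs(s, ml),
                 info = sprintf("%s min_loop=%d", s, ml))
    expect_true(check_structure(s, res$structure, ml))
    expect_equal(lengths(regmatches(res$structure,
                                    gregexpr("(", res$structure, fixed = TRUE))),
                 res$pair_score)
  }
})

test_that("pair score is monotonically non-increasing in min_loop", {
  set.seed(22)
  for (rep in 1:30) {
    s <- random_rna(sample(10:60, 1))
    scores <- vapply(0:8, function(ml) max_basepair_fold(s, ml)$pair_score, 0L)
    expect_true(all(diff(scores) <= 0L))
  }
})

test_that("structure tracebacks are valid and deterministic", {
  set.seed(23)
  for (rep in 1:30) {
    s <- random_rna(sample(20:80, 1))
    r1 <- max_basepair_fold(s)
    r2 <- max_basepair_fold(s)
    expect_identical(r1, r2)
    expect_true(check_structure(s, r1$structure, 3L))
  }
})

test_that("permutation z-score is reproducible and flags degenerate windows", {
  hp <- permutation_zscore("AAAAAAAAAAAAAAA", n_perm = 20, seed = 5)
  expect_true(hp$degenerate)
  expect_equal(hp$z, 0)
  expect_equal(hp$p_perm, 1)

  w <- "GGGGGGGAAAACCCCCCCAUAUGCAUGCAUGC"
  a <- permutation_zscore(w, n_perm = 100, seed = 7)
  b <- permutation_zscore(w, n_perm = 100, seed = 7)
  expect_identical(a, b)
  c <- permutation_zscore(w, n_perm = 100, seed = 8)
  expect_false(identical(a$z, c$z))
  # p_perm is a valid permutation p-value
  expect_gte(a$p_perm, 1 / 101)
  expect_lte(a$p_perm, 1)
})

test_that("signal calling near the CDS end yields no element", {
  # heptamer ends 7 nt before the CDS end: no window of positive length
  cds <- paste0("AUG", "GC", "AAAUUUU", "UAA")
  m <- transcript_model("t", cds)
  sites <- find_slippery_sites(m)
  expect_equal(sites$start, 5L)
  sig <- call_prf_signal(m, sites[1, ], scan_config(n_perm = 10))
  expect_null(sig$element)
  expect_false(sig$passes)
})

test_that("a planted hairpin construct yields a high-scoring element", {
  set.seed(24)
  cfg <- sim_config(n_transcripts = 12, p_plant_phe_signal = 1,
                    p_plant_lys_signal = 0, hairpin_stem_len = 12L,
                    seed = 31)
  sim <- generate_transcriptome(cfg)
  sc <- scan_config(n_perm = 50, seed = 32)
  for (i in seq_along(sim$models)) {
    m <- sim$models[[i]]
    sites <- find_slippery_sites(m, sc)
    planted <- sites[sites$start == sim$truth$site_start[i], ]
    expect_equal(nrow(planted), 1L)
    sig <- call_prf_signal(m, planted, sc)
    expect_false(is.null(sig$element))
    # the 12-bp planted stem guarantees at least 12 pairs in the window
    expect_gte(sig$element$pair_score, 12L)
    # the selected window reaches into the planted hairpin region
    expect_lte(sig$element$window_start, planted$start + 7L + cfg$spacer + 4L)
  }
})

test_that("planted stimulatory elements separate from background signals", {
  # planted (default 24-bp stem) vs background Phe/Lys-free transcripts whose
  # incidental slippery sites face unstructured downstream sequence
  cfg <- sim_config(n_transcripts = 25, p_plant_phe_signal = 1,
                    p_plant_lys_signal = 0, seed = 41)
  sim <- generate_transcriptome(cfg)
  sc <- scan_config(n_perm = 50, seed = 42)
  sites <- scan_transcripts(sim$models, sc, classes = "phe")
  planted <- sites[sites$trna_class == "phe", ]
  expect_true(all(planted$passes))

  cfg0 <- sim_config(n_transcripts = 40, p_plant_phe_signal = 0,
                     p_plant_lys_signal = 0, seed = 43,
                     reject_accidental = FALSE)
  sim0 <- generate_transcriptome(cfg0)
  sites0 <- scan_transcripts(sim0$models, scan_config(n_perm = 50, seed = 44),
                             classes = c("phe", "lys"))
  bg <- sites0[sites0$trna_class %in% c("phe", "lys"), ]
  expect_gt(nrow(bg), 5L)
  # background windows pass only sporadically; planted ones always do
  expect_lt(mean(bg$passes), 0.5)
  expect_gt(mean(planted$z), mean(bg$z) + 2)
})
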