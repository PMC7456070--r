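test_that("-1 translation resumes at the YYZ codon and finds the first stop", {
  m1 <- transcript_model("a", "AUGCAAAAUUUUAAGUAA")
  o1 <- simulate_minus1(m1, 5L) # -1 frame: UUU then UAA at 11
  expect_true(o1$ptc_found)
  expect_equal(o1$ptc_start, 11L)

  m2 <- transcript_model("b", "AUGCAAAAUUUUGCGUAA")
  o2 <- simulate_minus1(m2, 5L) # -1 frame runs off the CDS end
  expect_false(o2$ptc_found)
  expect_true(is.na(o2$ptc_start))

  # the first decoded -1 codon is YYY (a homopolymer, never a stop), so the
  # earliest possible PTC is the very next codon, as in m1 above
  expect_equal(o1$ptc_start, o1$site_start + 6L)

  expect_error(simulate_minus1(m1, 6L), "frame")
})

test_that("junction distance reproduces the 52-nt case and its boundaries", {
  # PTC last base at transcript coordinate 13, next junction at 66 -> 52 nt
  m <- transcript_model("r", "AUGCAAAAUUUUAAGUAAGCAGCAGCAGCA",
                        cds_offset = 0L, junctions = 66L, tx_len = 100L)
  o <- frameshift_outcome(m, 5L)
  expect_equal(o$ptc_start, 11L)
  expect_equal(o$dist_to_next_junction, 52L)
  expect_true(o$nmd_predicted)

  # no junction downstream of the stop
  m2 <- transcript_model("r2", "AUGCAAAAUUUUAAGUAA", junctions = 3L,
                         tx_len = 40L)
  o2 <- frameshift_outcome(m2, 5L)
  expect_true(is.na(o2$dist_to_next_junction))
  expect_false(o2$nmd_predicted)

  # junction immediately after the stop codon -> distance 0
  m3 <- transcript_model("r3", "AUGCAAAAUUUUAAGUAA", junctions = 14L,
                         tx_len = 40L)
  expect_equal(frameshift_outcome(m3, 5L)$dist_to_next_junction, 0L)
})

test_that("the NMD rule is inclusive at the distance threshold", {
  base <- list(ptc_found = TRUE, dist_to_next_junction = 52L)
  expect_true(predict_nmd(base, threshold = 50L))
  expect_false(predict_nmd(list(ptc_found = TRUE,
                                dist_to_next_junction = 49L)))
  expect_true(predict_nmd(list(ptc_found = TRUE,
                               dist_to_next_junction = 50L)))
  expect_false(predict_nmd(list(ptc_found = FALSE,
                                dist_to_next_junction = NA_integer_)))
})

test_that("junction translation by +k shifts the distance by +k", {
  set.seed(31)
  cfg <- sim_config(n_transcripts = 15, p_plant_phe_signal = 1,
                    p_plant_lys_signal = 0, seed = 51)
  sim <- generate_transcriptome(cfg)
  for (i in seq_along(sim$models)) {
    m <- sim$models[[i]]
    o <- frameshift_outcome(m, sim$truth$site_start[i])
    k <- sample(1:25, 1)
    m2 <- transcript_model(m$transcript_id, m$cds, cds_offset = m$cds_offset,
                           junctions = m$junctions + k,
                           tx_len = m$tx_len + k)
    o2 <- frameshift_outcome(m2, sim$truth$site_start[i])
    expect_equal(o2$dist_to_next_junction, o$dist_to_next_junction + k)
  }
})

test_that("planted PTCs and junction distances are recovered exactly", {
  cfg <- sim_config(n_transcripts = 30, p_plant_phe_signal = 0.5,
                    p_plant_lys_signal = 0.5, seed = 61)
  sim <- generate_transcriptome(cfg)
  planted <- which(sim$truth$planted_class != "none")
  expect_gt(length(planted), 10L)
  for (i in planted) {
    o <- frameshift_outcome(sim$models[[i]], sim$truth$site_start[i])
    expect_true(o$ptc_found)
    expect_equal(o$ptc_start, sim$truth$ptc_start[i])
    expect_equal(o$dist_to_next_junction, sim$truth$junction_distance[i])
  }
})

test_that("transcript-level verdicts use the 5'-most passing Phe site", {
  cfg <- sim_config(n_transcripts = 10, p_plant_phe_signal = 1,
                    p_plant_lys_signal = 0, seed = 71)
  sim <- generate_transcriptome(cfg)
  sites <- scan_transcripts(sim$models, scan_config(n_perm = 30, seed = 72),
                            classes = "phe")
  nmd <- transcript_nmd(sim$models, sites)
  expect_equal(nrow(nmd), 10L)
  expect_identical(sort(nmd$transcript_id), sort(sim$truth$transcript_id))
  ord <- match(nmd$transcript_id, sim$truth$transcript_id)
  expect_equal(nmd$site_start, sim$truth$site_start[ord])
  expect_equal(nmd$ptc_start, sim$truth$ptc_start[ord])
  # planted junction distances are 20-150 nt, so NMD follows the >= 50 rule
  expect_identical(nmd$nmd_predicted,
                   sim$truth$junction_distance[ord] >= 50L)
})
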