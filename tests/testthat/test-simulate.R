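test_that("the generator is deterministic and respects n = 0", {
  cfg <- sim_config(n_transcripts = 0)
  sim <- generate_transcriptome(cfg)
  expect_length(sim$models, 0L)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(generate_de_table(sim$truth, cfg)), 0L)

  cfg2 <- sim_config(n_transcripts = 25, seed = 91)
  a <- generate_transcriptome(cfg2)
  b <- generate_transcriptome(cfg2)
  expect_identical(a, b)
  expect_identical(generate_de_table(a$truth, cfg2),
                   generate_de_table(b$truth, cfg2))
})

test_that("simulated fixture directories are byte-identical per seed", {
  cfg <- sim_config(n_transcripts = 8, seed = 92)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(cmd_simulate(d1, cfg))
  suppressMessages(cmd_simulate(d2, cfg))
  for (f in c("transcripts.fa", "models.tsv", "de.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("background sequence has no accidental Phe/Lys slippery heptamers", {
  cfg <- sim_config(n_transcripts = 40, p_plant_phe_signal = 0,
                    p_plant_lys_signal = 0, seed = 93)
  sim <- generate_transcriptome(cfg)
  sites <- scan_transcripts(sim$models, scan_config(require_frame = FALSE),
                            fold = FALSE)
  expect_false(any(sites$trna_class %in% c("phe", "lys")))
  # the rejection step can be disabled
  cfg2 <- sim_config(n_transcripts = 60, p_plant_phe_signal = 0,
                     p_plant_lys_signal = 0, seed = 93,
                     reject_accidental = FALSE)
  sim2 <- generate_transcriptome(cfg2)
  sites2 <- scan_transcripts(sim2$models, scan_config(require_frame = FALSE),
                             fold = FALSE)
  expect_true(any(sites2$trna_class %in% c("phe", "lys")))
})

test_that("planted signals are recovered at the planted coordinates", {
  cfg <- sim_config(n_transcripts = 30, p_plant_phe_signal = 1,
                    p_plant_lys_signal = 0, seed = 94)
  sim <- generate_transcriptome(cfg)
  sites <- scan_transcripts(sim$models, scan_config(n_perm = 30, seed = 95),
                            classes = "phe")
  phe <- sites[sites$trna_class == "phe", ]
  expect_equal(nrow(phe), 30L)
  ord <- match(phe$transcript_id, sim$truth$transcript_id)
  expect_equal(phe$start, sim$truth$site_start[ord])
  expect_true(all(phe$passes))
  # planted CDSs keep a single in-frame stop (the terminal one)
  for (m in sim$models[1:5]) {
    codons <- substring(m$cds, seq(1, nchar(m$cds) - 2, 3),
                        seq(3, nchar(m$cds), 3))
    expect_identical(which(codons %in% c("UAA", "UAG", "UGA")),
                     length(codons))
  }
})

test_that("infeasible planting configurations are rejected", {
  expect_error(sim_config(n_transcripts = 5, cds_len_range = c(60, 90),
                          p_plant_phe_signal = 1, p_plant_lys_signal = 0),
               "infeasible")
  # but fine when nothing is planted
  cfg <- sim_config(n_transcripts = 5, cds_len_range = c(60, 90),
                    p_plant_phe_signal = 0, p_plant_lys_signal = 0)
  expect_length(generate_transcriptome(cfg)$models, 5L)
})

test_that("DE emission satisfies the status thresholds deterministically", {
  cfg <- sim_config(n_transcripts = 400, seed = 96)
  sim <- generate_transcriptome(cfg)
  de <- generate_de_table(sim$truth, cfg)
  status <- classify_de_status(de$log2fc, de$padj)
  # every down row satisfies the strict thresholds by construction
  expect_true(all(de$log2fc[status == "down"] < -1 &
                    de$padj[status == "down"] < 0.05))
  expect_true(all(de$log2fc[status == "up"] > 1 &
                    de$padj[status == "up"] < 0.05))
  # Phe-planted transcripts are down more often (odds ratio 3 by default)
  phe <- sim$truth$planted_class == "phe"
  expect_gt(mean(status[phe] == "down"), mean(status[!phe] == "down"))
})

test_that("an empty down class propagates the defined enrichment error", {
  cfg <- sim_config(n_transcripts = 30, base_p_down = 0, p_up = 0,
                    seed = 97)
  sim <- generate_transcriptome(cfg)
  de0 <- generate_de_table(sim$truth, cfg)
  de <- cbind(de0, status = classify_de_status(de0$log2fc, de0$padj))
  expect_error(
    prf_enrichment(sim$models, de, scan_config(n_perm = 5, seed = 98)),
    "empty down")
})
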