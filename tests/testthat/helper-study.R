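# One full simulate -> scan -> enrich run, returning the panel results.
# Used by the acceptance suite; problem sizes are set by the caller.
run_enrichment_study <- function(seed, n_transcripts = 2000L,
                                 odds_ratio = 3, n_perm = 20L,
                                 fold_classes = c("phe", "lys")) {
  cfg <- sim_config(n_transcripts = n_transcripts,
                    enrichment_odds_ratio = odds_ratio, seed = seed)
  sim <- generate_transcriptome(cfg)
  de0 <- generate_de_table(sim$truth, cfg)
  de <- cbind(de0, status = classify_de_status(de0$log2fc, de0$padj))
  fit <- suppressWarnings(
    prf_enrichment(sim$models, de, scan_config(n_perm = n_perm, seed = seed),
                   fold_classes = fold_classes))
  res <- fit$results
  pick <- function(cls, comp)
    res[res$signal_class == cls & res$comparator == comp, ]
  list(or_phe_bg = pick("phe_uuuu_c", "prfdb_background")$odds_ratio,
       p_phe_bg = pick("phe_uuuu_c", "prfdb_background")$p,
       p_lys_bg = pick("lys_aaaa_g", "prfdb_background")$p,
       p_nophe_bg = pick("no_phe_codon", "prfdb_background")$p,
       or_phe_up = pick("phe_uuuu_c", "up_regulated")$odds_ratio,
       p_phe_up = pick("phe_uuuu_c", "up_regulated")$p,
       n_down = fit$n_down, n_up = fit$n_up)
}
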