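# prfscan

Detection of −1 programmed ribosomal frameshift (PRF) signals in coding
sequences, and the analysis chain linking them to transcript degradation.

## The problem

Loss of the hypermodified guanosine at position 37 of tRNA-Phe (wybutosine
and its derivatives) destabilizes codon–anticodon pairing at UUU/UUC and
makes ribosomes prone to −1 frameshifting at *slippery sequences* — a
heptamer `X XXY YYZ` (N1=N2=N3, N4=N5=N6) followed, after a short spacer,
by a stimulatory RNA structure. A −1 slip re-pairs the tRNAs onto
N1N2N3/N4N5N6, translation continues out of frame, a premature termination
codon (PTC) usually appears, and if the PTC sits ≥ ~50 nt upstream of the
next exon–exon junction the transcript is degraded by nonsense-mediated
decay (NMD). In colon cancer cells where the tRNA-modifying enzyme TYW2 is
epigenetically silenced, transcripts carrying tRNA-Phe–type (UUUU/C)
slippery signals are preferentially down-regulated, while tRNA-Lys–type
(AAAA/G) signals and transcripts lacking UUU/UUC codons are not.

`prfscan` implements that computational chain for anyone who wants to run
or stress-test it:

- **Scan**: find slippery heptamers in CDSs, frame-anchored
  (`start ≡ 2 (mod 3)`), and attribute them to their decoding tRNA
  (Phe UUUU/C vs Lys AAAA/G, with an `any_codon` mode for HIV-type
  P-site heptamers).
- **Structure**: score the downstream window by maximal nested base
  pairing (Nussinov dynamic programming, A·U/G·C/G·U pairs, loop ≥ 3 nt)
  and test it against a mononucleotide-shuffle permutation null
  (`z = (observed − mean)/sd`); a signal passes with pair score ≥ 15 and
  z ≥ 1.64.
- **Frameshift/NMD**: simulate the −1 slip (resume at `start + 3`), locate
  the first −1-frame stop, measure the distance to the next exon junction,
  and apply the inclusive 50-nt rule.
- **Enrichment**: 2×2 Fisher tests (exact hypergeometric tail via
  log-factorials, odds ratio `ad/bc`) of down-regulated vs comparator
  transcripts for three signal classes — Phe signals, Lys signals
  (negative control), and transcripts with no in-frame UUU/UUC codon
  (negative control) — against up-regulated transcripts and the scanned
  background.
- **Reporters**: dual-luciferase (`mean(firefly/renilla)` ratios) and
  dual-GST (`100·dual/(dual+single)`) frameshift quantification with the
  pooled-variance t test.
- **Synthetic data**: a transcriptome generator that plants slippery
  cassettes (heptamer + spacer + perfect hairpin + −1-frame stop +
  recorded junction) with known ground truth and a DE layer with a
  configurable down-regulation odds ratio, so every stage is testable
  without external data.

## Worked example

```r
library(prfscan)

m <- transcript_model("demo", "AUGCAAAAUUUUAAGUAAGCAGCAGCAGCA",
                      cds_offset = 0L, junctions = 66L, tx_len = 100L)
find_slippery_sites(m)
#>   transcript_id start heptamer p_codon a_codon trna_class site_of_action in_frame
#> 1          demo     5  AAAUUUU     AAU     UUU        phe              A     TRUE

frameshift_outcome(m, 5L)
#> $ptc_start             : int 11      # -1 frame reads UUU then UAA
#> $dist_to_next_junction : int 52      # stop ends at 13, junction at 66
#> $nmd_predicted         : logi TRUE   # 52 >= 50
```

The heptamer `AAAUUUU` starts at CDS position 5 (0-based), its A-site
codon UUU is decoded by tRNA-Phe, the simulated −1 slip hits `UAA` at
position 11, and the stop lies 52 nt upstream of the junction at 66 — an
NMD substrate.

A full synthetic run, with down-regulation planted at odds ratio 3 on
Phe-signal transcripts:

```r
cfg <- sim_config(n_transcripts = 800, seed = 42)
sim <- generate_transcriptome(cfg)
de0 <- generate_de_table(sim$truth, cfg)
de  <- cbind(de0, status = classify_de_status(de0$log2fc, de0$padj))
fit <- prf_enrichment(sim$models, de, scan_config(n_perm = 50, seed = 43))
fit
#> Slippery-signal enrichment panel (-1 PRF)
#>   transcripts: 800 (113 down, 5 up); test: Fisher exact, one-sided (greater)
#>  signal_class       comparator  a   b   c   d prop_down prop_comparator odds_ratio        p
#>    phe_uuuu_c prfdb_background 49  64 180 620     0.434           0.225      2.640 4.10e-06
#>    lys_aaaa_g prfdb_background 15  98 148 652     0.133           0.185      0.674 9.36e-01
#>  no_phe_codon prfdb_background  0 113   2 798     0.000           0.002      0.000 1.00e+00
```

43% of down-regulated transcripts carry a passing Phe signal versus 23% of
the background (odds ratio 2.6, one-sided p = 4e-06), while the Lys and
no-Phe-codon controls are flat — the planted contrast, recovered.
`coef(fit)` returns the odds ratios, `summary(fit)` adds site tallies, and
`plot(fit)` draws the proportion panel.

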