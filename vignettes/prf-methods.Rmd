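---
title: "Detecting -1 frameshift signals and frameshift-linked decay with prfscan"
author: "prfscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting -1 frameshift signals and frameshift-linked decay with prfscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfscan)
```

## The biological model

Position 37 of tRNA-Phe, adjacent to the anticodon, normally carries a
hypermodified guanosine (wybutosine and its hydroxylated/peroxydated
derivatives). The modification stabilizes codon–anticodon pairing when the
ribosome decodes UUU/UUC, and its loss makes the ribosome prone to -1
programmed ribosomal frameshifting (PRF) at *slippery sequences*. A -1 PRF
signal has two parts:

1. a **slippery heptamer** `X XXY YYZ` (positions N1–N7 with N1=N2=N3 and
   N4=N5=N6), on which the P- and A-site tRNAs can re-pair after slipping
   one nucleotide backwards; and
2. a **stimulatory secondary structure** a short spacer downstream, which
   pauses the ribosome over the heptamer.

After a -1 slip the next decoded codon is N4N5N6, so translation continues
in the -1 frame from CDS coordinate `start + 3`. A stop codon usually
appears early in the shifted frame; if this premature termination codon
(PTC) lies sufficiently far upstream (canonically ~50 nt) of a downstream
exon–exon junction, the transcript is a substrate for nonsense-mediated
decay (NMD). The package implements this chain — scan, structure call, -1
simulation, NMD call — plus the enrichment test asking whether
down-regulated transcripts are over-represented among those carrying
tRNA-Phe (UUUU/C) slippery signals, with tRNA-Lys (AAAA/G) signals and
transcripts lacking any in-frame UUU/UUC codon as negative controls, and
the arithmetic for dual-luciferase and dual-GST frameshift reporters.

All coordinates are 0-based and half-open. Sequences are held in the RNA
alphabet (T is mapped to U on ingest) because the motifs are defined on
mRNA. Ambiguity codes are rejected rather than skipped: scanning semantics
over ambiguous bases are undefined, and silently dropping them would bias
transcript-level counts.

## Slippery-site scanning and tRNA attribution

`find_slippery_sites()` reports every heptamer position matching the
pattern; `X = Y` is allowed (`UUUUUUU` is a valid slippery heptamer), and
overlapping sites in homopolymeric runs are all reported — deduplication to
transcript level happens in the enrichment stage, which is what the
transcript-counting analysis needs.

**Frame anchoring.** A biologically meaningful site needs N2 to begin a
zero-frame codon, i.e. `start %% 3 == 2`, so that the pre-slip codons are
N2N3N4/N5N6N7 and the post-slip codons N1N2N3/N4N5N6. `require_frame`
defaults to `TRUE`; it is exposed because database-style scans do not
always enforce frame.

**tRNA attribution** (`classify_trna()`) has two modes. The default
`a_site_suffix` is the literal reading of the UUUU/C and AAAA/G classes:
positions N4–N7 equal `UUUU`/`UUUC` (Phe) or `AAAA`/`AAAG` (Lys). The
`any_codon` mode attributes a site to Phe when either post-slip codon
(P-site N2N3N4 or A-site N5N6N7) is UUU/UUC; this captures the HIV-type
heptamer `U UUU UUA`, which slips via a P-site Phe but fails the strict
suffix reading. The strict mode's Phe set is always a subset of the loose
mode's, and the tests assert this.

## The stimulatory element: base-pair maximization with a permutation null

The structure stage scores candidate windows by **maximal nested base
pairing** (Nussinov-style dynamic programming over Watson–Crick A·U/G·C
plus G·U wobble pairs, hairpin loops at least `min_loop = 3` nt). No
thermodynamic energy model is applied: pair maximization is self-contained,
deterministic, and exactly verifiable against an exhaustive enumeration
oracle, which the test suite does for all window lengths up to 12. An
energy-model folder is a natural extension point; an optional rank
cross-check against such a folder is possible but is not a package
dependency. Tracebacks are deterministic (pair the smallest i, then the
largest j), so structures are reproducible byte for byte.

For each site, windows of `window_len = 70` nt are folded at every spacer
in 5–9 nt downstream of the heptamer; the best-scoring spacer is kept (ties
to the smallest). Significance uses a **mononucleotide-shuffle permutation
null**: the chosen window is shuffled `n_perm` times, each shuffle is
refolded, and `z = (observed - mean) / sd` of the shuffle scores. A signal
*passes* when the window exists, its pair score is at least
`min_pairs = 15`, and `z >= z_cutoff = 1.64` (the observed score exceeds
the null mean by at least 1.64 SD). Degenerate windows (shuffle SD of zero,
e.g. homopolymers) never pass.

Two numerical facts shape everything downstream and are worth stating
plainly:

- Maximal pairing of a random 70-nt window is already high (about 24–25
  pairs, SD ~1.2): composition alone fixes most of the attainable pairing,
  so `min_pairs = 15` is essentially never the binding constraint at this
  window size — the z-score is.
- Selecting the best of five overlapping spacer windows before computing z
  inflates it slightly; on background sites the empirical pass rate is
  ~10–15% rather than the nominal ~5%. This selection bias is symmetric
  across tRNA classes, so the Phe-vs-Lys contrast in the enrichment panel
  is unaffected, but absolute pass rates should not be read as calibrated
  false-positive rates.

## Frameshift simulation and the NMD rule

`simulate_minus1()` resumes translation at `start + 3` and reports the
first stop codon in the -1 frame; because the first decoded -1 codon is
the YYY homopolymer, the earliest possible PTC is `start + 6`.
`distance_to_next_junction()` measures from the base after the stop codon
to the nearest junction strictly downstream of the stop's last base
(junctions are stored as the transcript coordinate of the first base after
the junction, so the distance is a plain subtraction).
`predict_nmd()` calls a transcript an NMD substrate when that distance is
at least `threshold = 50` nt, inclusive; the canonical rule is quoted as
50–55 nt and the threshold is configurable. For transcript-level verdicts
the 5'-most passing Phe site is used — the first slip encountered by a
translating ribosome dominates — while per-site results remain available.

## Enrichment machinery

`classify_de_status()` applies strict thresholds (|log2FC| > 1, adjusted
p < 0.05 by default): values exactly at a threshold are *unchanged*. The
2x2 tables put down-regulated transcripts against a comparator — either
up-regulated transcripts or the full scanned background — and
signal-positive against signal-negative, each transcript counted once.
The exact hypergeometric tail (`hypergeom_tail()`) is computed from
log-factorials; one-sided enrichment is the default (the hypothesis has a
direction), two-sided summation of all tables at most as probable as the
observed one is available by flag, and the tests verify both against
full-table enumeration and against `fisher.test()`. No multiple-testing
correction is applied across the three-class panel by default (a
Bonferroni flag exists) — the panel is one hypothesis plus two controls,
not three exchangeable hypotheses.

## The synthetic transcriptome generator

`generate_transcriptome()` produces the ground truth every stage is tested
against. Background CDSs are uniform random non-stop codons (AUG first,
one terminal stop), with any accidental Phe/Lys-class slippery heptamer
rejected and resampled so that truth labels are unambiguous (a flag
disables this to stress-test deduplication). Planted transcripts receive,
at a random frame-anchored position, a cassette of: heptamer (random X,
class-determined YYYZ), a 6-nt spacer, a perfect reverse-complement
hairpin, a -1-frame `UAA` at the first -1 codon after the hairpin, and a
downstream exon junction at a recorded distance (20–150 nt); cassette
placement is validated (single in-frame stop, unique class heptamer, first
-1-frame stop at the recorded PTC) and resampled on violation.

Design choices that deserve justification:

- **Hairpin stem length defaults to 24 bp.** Under base-pair maximization
  with a composition-preserving shuffle null, short stems are weakly
  detectable — a 12-bp perfect stem raises the window score by only ~2
  pairs over a null whose SD is ~1.2, and passes the default threshold only
  ~70% of the time. Planted signals must be unambiguous for truth-recovery
  testing, so the default stem is 24 bp, which gives planted z-scores of
  ~4–6 and 100% recovery. Real stimulatory elements are often shorter but
  gain stability from pseudoknots and thermodynamics that a pair-counting
  score does not see; the stem length is a property of the *test bed*, not
  a claim about biology.
- **The DE layer emits labels, not counts.** Each transcript is
  down-regulated with probability q where
  `logit(q) = logit(base_p_down) + log(enrichment_odds_ratio)` if a Phe
  signal was planted; non-down transcripts are up-regulated with
  probability `p_up` independent of planting. log2FC/padj values are then
  drawn to satisfy the status thresholds deterministically. Simulating an
  RNA-seq count model and a DE caller would test someone else's software;
  only the downstream classification is under test here.
- **Defaults mirror the knockout study's shape at reduced scale**:
  `base_p_down = 0.1`, `enrichment_odds_ratio = 3`, and `p_up = 0.016`,
  chosen so the down:up ratio among DE calls (~86:14) matches the reported
  transcriptome-wide tally, with n = 2,000 transcripts, CDS lengths
  300–1,500 nt, and 2–8 exon junctions per transcript.

## What the validation runs use, and what passing them shows

The acceptance suite runs, per stage: the scanner against a
position-by-position brute-force predicate on 1,000 random CDSs (up to
3,000 nt); the folder against exhaustive enumeration on 1,000 sequences of
length up to 12; the hypergeometric tail against full-table enumeration on
500 tables with margins up to 40 (relative error < 1e-10); full planted
recovery at plant probability 1 (n = 300, default 100 shuffles);
odds-ratio recovery over 50 seeded replicates at the default conditions
(n = 2,000, planted odds ratio 3, 20 shuffles per site), requiring the
estimated Phe odds ratio in [2.0, 4.5] and a significant Phe p with
non-significant controls in at least 90% of replicates; and a null
calibration over 200 seeded replicates (odds ratio 1, n = 1,000, 10
shuffles, Phe-class folding only) whose Phe p-values must be uniform by a
Kolmogorov–Smirnov test at alpha 0.01. The replicate problem sizes
(transcript counts and shuffle counts per run) were set so the whole suite
runs in minutes on one CPU; the statistical properties under test do not
depend on them.

Passing these tests shows that the machinery does what it claims on data
matching its generative assumptions. It does **not** show that the scan
reproduces any database-derived signal set on real transcriptomes: real
UTRs, codon bias, alternative isoforms, pseudoknotted stimulators, and the
unpublished parameters of database-style -1 PRF prediction are all outside
the generator. In particular, the published set of 109 down-regulated
UUUU/C-signal transcripts depends on a specific annotation and prediction
database whose window, spacer, and significance settings are not stated,
and is therefore not exactly recomputable here; the package reproduces the
*method* — classification, structure calling, and the Fisher panel — not
that catalog.

## Known limitations

- Nested pairings only: pseudoknots, the canonical strong -1 PRF
  stimulators, are not predicted. This makes the structure stage
  conservative for real viral-type signals.
- Pair maximization ignores stacking energies and loop penalties; scores
  correlate with, but do not equal, thermodynamic stability.
- The max-over-spacers selection inflates the permutation z mildly (see
  above); treat `passes` as a ranked screen, not a calibrated test.
- The exon-junction rule is a distance threshold on annotated junctions;
  UTR introns, isoform choice, and the known leakiness of the 50-nt rule
  are not modeled.
- Reporter quantification consumes numbers (luminescence pairs, band
  intensities); plate/image processing is out of scope, and per-replicate
  Renilla normalization is assumed (a per-condition option exists).
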