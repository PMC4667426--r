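# tfpairs

Transcription factors (TFs) rarely act alone: functional promoters are
typically bound by pairs or higher-order combinations of factors whose
binding sites (TFBSs) sit close together on the DNA.  `tfpairs`
identifies potentially collaborating TF pairs from nothing but the
distribution of their predicted binding sites across a set of promoter
sequences, treating the promoter set like a document corpus: sequences
are sentences, binding sites are words, and a pair of motifs that
co-occurs at short range more often than chance is a collocation worth
reporting.

## The method

Given promoter sequences and per-sequence TFBS predictions (from any
scanner, or the built-in one), the pipeline runs six phases:

1. **TFBS–sequence matrix.**  Build the count matrix `f[i, j]` of sites
   of motif `j` in sequence `i`.  Remove stop-word-like columns whose
   total count exceeds `3σ` (σ = population SD of the column sums) and
   noise-like columns with more zero entries than the column average.
2. **Important sites.**  For each cell, the pointwise mutual
   information `PMI(s_i; t_j) = log2 [ p(s_i, t_j) / (p(s_i) p(t_j)) ]`
   with `p(s_i, t_j) = f_ij / Σf`.  Only strictly positive cells — motif
   `j` occurs in sequence `i` more often than chance — keep their sites.
3. **Same-type overlap resolution.**  Overlapping predictions of the
   same motif (palindromes, oversized matrices) are clustered and only
   the site closest to the TSS survives.
4. **Pair construction.**  Two sites form a pair when their midpoint
   distance `d = |C_A − C_B|` lies in `[d_min, d_max]` (defaults 5–20 bp)
   and their intervals overlap by at most 4 bp (different types only).
   Within homotypic clusters a greedy 5′→3′ disjoint matching ensures a
   site is counted once per pair type.
5. **Weighted cumulative PMI.**  From pooled pair counts `F(a, b)`:
   `p(a,b) = F/T`, slot marginals `p(a) = C(a)/2T`, and
   `PMI(a;b) = log2[p(a,b)/(p(a)p(b))]`.  Each pair's score is damped by
   its joint probability and accumulated over the sequences containing
   it with weights `w_s = N_s / ΣN_s`:
   `PMI_pc(a;b) = (Σ_{s ∋ (a,b)} w_s) · p(a,b) · PMI(a;b)`.
6. **Background correction and significance.**  The average product
   correction `APC(a,b) = PMI_pc(a;·) PMI_pc(b;·) / mean(PMI_pc)`
   estimates the score share caused by promiscuous (often false
   positive) motifs and is subtracted; corrected scores are transformed
   to z-scores and pairs with `z ≥ 3` are called significant.

A spike-in simulator generates the validation benchmark: background
promoters at human-like GC content with a known motif pair planted at
coupled positions, plus independently placed decoy motifs with
realistic heavy-tailed abundance, and full ground truth.

## Worked example

```r
library(tfpairs)

cfg <- spikein_config(seed = 1)            # 200 x 1000 bp, pair + 12 decoys
sim <- simulate_spikein(cfg)
hits <- scan_consensus(sim$promoters, spikein_motifs(cfg))
res <- tf_pair_analysis(sim$promoters, hits = hits)   # d_min 5, d_max 20

res
#> <tf_pair_result> 200 sequences, 7 TFBS types, 1411 pair instances,
#> 26 observed pair types, 1 significant (z >= 3)

head(tidy(res), 3)[, c("type_a", "type_b", "F", "pmi", "pmi_pc_apc", "zscore")]
#> # A tibble: 3 x 6
#>   type_a type_b     F   pmi pmi_pc_apc zscore
#> 1 IRF1   USF1     427 2.57      0.237   4.79
#> 2 STAT   STAT     105 0.923     0.0268  0.390
#> 3 OCT    STAT      66 1.48      0.0157  0.157
```

The planted IRF1–USF1 pair tops the table with `z = 4.79` — well past
the significance threshold of 3 — while the best chance pairing of the
decoys stays below z = 1.  `network_edges()` and `node_degrees()`
export the significant-pair collaboration graph;
`autoplot(res$scores)` and `plot_pair_network(res)` draw the ranked
scores and the network.  Real data enter through `read_promoters()`
(FASTA, with TSS sidecars), `read_hits()` (any scanner's output as TSV)
or `read_transfac_matrices()` + `scan_pwm()`, and
`deduplicate_promoters()` removes redundant promoter windows of
multi-TSS genes.  A command-line front end is installed as
`exec/tfpairs` (`simulate`, `scan`, `run`, `inspect-matrix`).

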