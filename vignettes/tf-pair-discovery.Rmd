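---
title: "Discovering collaborating TF pairs from binding-site co-occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering collaborating TF pairs from binding-site co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfpairs)
```

## The problem and the model

Transcriptional regulation in higher eukaryotes is combinatorial: most
promoters are driven not by a single transcription factor (TF) but by
combinations of factors whose binding sites (TFBSs) cluster within
short stretches of DNA (cis-regulatory modules).  Predicted binding
sites are abundant and noisy — position weight matrices (PWMs) match
the genome far more often than factors bind it — so the question this
package answers is statistical: *which pairs of TFBS types co-occur at
short range across a promoter set more often than their individual
abundances explain?*

The approach is borrowed from corpus linguistics.  A promoter set is a
document corpus, each sequence a sentence, each binding site a word.
Collocations — word pairs with idiosyncratically high joint frequency —
are found with pointwise mutual information (PMI), and the same
statistic applies verbatim to binding sites once "adjacency" is given a
genomic definition (a midpoint distance window).  Two corrections adapt
the raw statistic to genomic reality: a per-pair damping and sequence
weighting to tame PMI's low-count sensitivity, and the average product
correction (APC), originally devised for covariation analysis of
multiple sequence alignments, to strip the score share that promiscuous
(largely false positive) motifs contribute to every pair they touch.

## The six phases

**Phase 1 — TFBS–sequence matrix.**  `build_tsm()` counts sites of each
motif in each sequence.  Two column filters mirror stop-word removal:
`filter_overrepresented()` drops motifs whose column sum exceeds three
times the *population* standard deviation of all column sums computed
on the input matrix (one pass; removals do not trigger recomputation),
and `filter_sparse()` drops motifs with *strictly* more zero entries
than the per-column average.  Both filters assume a heterogeneous motif
repertoire; when every column sum is equal the 3σ rule would degenerate
to removing everything, so σ = 0 disables it.

**Phase 2 — important sites.**  `sequence_tfbs_pmi()` scores each
non-zero cell with `PMI(s_i; t_j) = log2[p(s_i,t_j) / (p(s_i) p(t_j))]`
where all probabilities are count shares of the filtered matrix.  Cells
with zero counts have no finite PMI and are simply excluded rather than
carried as −∞ sentinels.  `select_important()` keeps strictly positive
cells only — independence (PMI = 0) is not evidence — and
`restrict_hits()` drops every site not backed by an important cell.

**Phase 3 — same-type overlaps.**  PWM hits of one motif frequently
overlap themselves (palindromic motifs match both strands over the same
bases; long matrices overhang short footprints), which would double-count
that type.  `resolve_same_type_overlaps()` forms overlap clusters by
transitive closure of half-open interval overlap — pairwise elimination
would be order-dependent — and keeps the single site whose midpoint is
closest to the TSS, since functional sites concentrate near it.
Distance is measured from the site midpoint (the same anchor Phase 4
uses), in absolute sequence coordinates; ties break to the smaller
start, then the `+` strand, for bit-reproducibility.

**Phase 4 — pairs.**  The midpoint of a site `[start, end)` is
`start + floor(width/2)`; two sites pair when their midpoint distance
lies within `[d_min, d_max]` and their intervals overlap by at most
`max_overlap` bases (different types; same-type pairs must not overlap
at all, which Phase 3 already guarantees).  Homotypic clusters would
otherwise explode combinatorially, so `enumerate_pairs()` applies a
greedy 5′→3′ *disjoint* matching per sequence and pair type: scanning
candidates by left then right midpoint, a candidate counts only if
neither site was already used for that pair type.  A site may still be
counted once for each *other* pair type.  Four same-type sites at
midpoints 10/20/30/40 therefore yield exactly two homotypic pairs.
Chained matching (sharing the middle site) is a defensible alternative
reading of the homotypic rule; the disjoint version is the more
conservative one and is isolated in a single function.

**Phase 5 — weighted cumulative PMI.**  From pooled counts `F(a,b)`
with total `T`: joint `p(a,b) = F/T` and *slot* marginals
`p(a) = C(a)/2T`, where `C(a)` counts the pair slots occupied by type
`a` (homotypic pairs occupy two).  Slot marginals make `Σ p(a) = 1` and
reduce the definition to standard bigram PMI; under independent uniform
placement of sites the expected PMI of every pair is then zero, which is
the correct null.  Each pair's PMI is damped by its joint probability
and accumulated over the sequences that contain it, each contributing
its weight `w_s = N_s / ΣN_s` (`N_s` = counted pair instances in `s`):
`PMI_pc(a;b) = (Σ_{s ∋ (a,b)} w_s) · p(a,b) · PMI(a;b)`.  The joint
probability and the PMI in this product are the pooled, corpus-level
quantities; a variant with per-sequence joint probabilities would be a
one-line change but is not the default.

**Phase 6 — APC and z-scores.**  With `n` participating types, the
per-type mean `PMI_pc(a;·)` averages over the `n − 1` *other* types
(self excluded, unobserved pairs contributing zero), the overall mean
averages over all `n(n−1)/2` heterotypic type-pair slots, and
`APC(a,b)` is the product of the two per-type means over the overall
mean (homotypic pairs: the single type's mean squared).  The corrected
score is `PMI_pc − APC`.  This construction makes the correction exact
for rank-one structure: if every pair has the same score `c`, every
APC is `c` and every corrected score is exactly zero, so structureless
input can never look significant.  Corrected scores are standardized
(z-scores, sample SD) over the *full pair-slot universe* — all
heterotypic slots of the participating types, unobserved slots entering
at `PMI_pc = 0`, plus observed homotypic pairs — the same population the
APC means are taken over; this is the package's convention for what
counts as the comparison population, chosen so that the correction and
the standardization see the same world.  A pair is significant at
`z ≥ z_threshold` (default 3).  Zero variance means no significance,
and fewer than two slots is an error, not a silent pass.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d_min` | 5 bp | minimal midpoint distance; about half an average TFBS length, so partners are not the same footprint |
| `d_max` | 20 bp | maximal midpoint distance; 50 or 100 widen the search to loosely coupled modules |
| `max_overlap` | 4 bp | tolerated interval overlap between different-type partners |
| `z_threshold` | 3 | significance cut on the corrected-score z-scale |
| `min_score` | 0.85 | normalized log-odds threshold of the built-in scanner |

The built-in scanner (`scan_pwm()`) is a plain log-odds scorer with a
pseudocount of 1% of each column total, background base frequencies
estimated from the scanned set and symmetrized over strands (both
strands are scanned, so the background must be strand-neutral), and
min–max normalization so the best attainable window scores 1 and the
worst 0.  Any monotone scorer works here because the pipeline consumes
only hit *positions*; sites from an external scanner enter unchanged
through `read_hits()`.

## What the spike-in simulator emulates — and what it does not

`simulate_spikein()` reproduces the standard positive control for this
class of method: plant a known motif pair at coupled positions and ask
whether the pipeline recovers it.  Defaults (`spikein_config()`):

* 200 background sequences of 1000 bp, i.i.d. bases at GC 0.41
  (human-genome-like), TSS at the 3′ end;
* the pair — an IRF-like 10-mer and a USF-type E-box 8-mer, chosen
  non-palindromic so exact-consensus scanning sees each planted copy
  exactly once — inserted 2–12 times per sequence (uniform), each copy
  written as motif A, a gap of 5–20 bp of untouched background, then
  motif B, at uniformly chosen non-overlapping positions
  (length-preserving overwrite);
* twelve decoy motifs of varied length and GC, inserted independently
  (Poisson per sequence and type) with **heavy-tailed per-type
  abundance**: a fixed log-spaced profile with mean `decoy_rate = 3`.
  Real promoter scans give exactly this kind of skewed per-motif count
  distribution, and the 3σ column filter presupposes it — with
  near-equal column sums the filter removes everything.  Set
  `decoy_spread = 0` to see that degenerate behaviour.

Placement draws uniformly over the exactly feasible start positions;
the per-sequence decoy load is redrawn when a draw cannot physically
fit beside the planted pairs (a 1 kb promoter cannot hold more sites
than fit), so the realized counts are Poisson conditioned on
feasibility.

Because the two pair motifs span 10 + 8 bp, the planted midpoint
distance is `gap + 9`, so copies with gaps above 11 bp fall outside the
default `d_max = 20` window and are not counted — the benchmark signal
is deliberately attenuated, not saturated, by the distance constraint.

The background is i.i.d.: it has promoter-like GC but none of the
correlation structure of real promoters (CpG islands, repeats, real
cis-regulatory grammar, chromatin context).  Passing the spike-in
therefore shows the statistical machinery recovers coupled placement
against independent noise of realistic abundance; it does not show
performance on real genomes, where the TFBS scanner's error profile and
promoter redundancy (see `deduplicate_promoters()`) dominate.

## Numerical and edge-case choices

* σ in the over-representation filter is the population SD; the
  sample-SD variant differs by `sqrt(n/(n-1))` and would be a one-line
  change.
* All inequalities that the wording leaves open are strict: column sum
  `> 3σ`, zeros `> mean`, importance `PMI > 0`, significance `z ≥ 3`
  (the one stated inclusively).
* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at I/O boundaries.  Touching intervals do not overlap.
* The TSM is built from the raw hit list; Phase 3's overlap resolution
  runs after Phase 2, matching the phase order, so importance is judged
  on scanner output, not on thinned sites.
* Degenerate cases fail loudly and specifically: empty promoter set,
  empty hit list, no surviving matrix columns, no pairs under the
  distance constraints, and fewer than two pair slots each raise named
  errors; σ = 0 and zero score variance disable their filter/test with
  a message instead.

## Known limitations

* **Homotypic enrichment by the importance filter.**  Phase 2 keeps a
  type's sites only in sequences where that type is over-represented.
  This conditions the retained per-sequence density of a motif on
  itself, which inflates the homotypic pair count of the most abundant
  motif relative to the slot-marginal null: on decoy-only simulations
  (no planted coupling) the densest surviving decoy's homotypic pair
  reaches z ≈ 4 in most runs.  This is a property of the method, not of
  the implementation — disabling the importance step
  (`importance = FALSE`) returns homotypic PMIs to ≈ 0 — and it means
  homotypic calls should be treated with more caution than heterotypic
  ones.
* **z-score saturation.**  The z-score is self-normalized over the pair
  slots of a run, so once one pair dominates, its z approaches the
  algebraic ceiling `(N−1)/√N` for `N` slots (≈ 5.7 at N = 34) and
  stops growing with effect size; ranks and corrected scores remain
  informative beyond that point, the z-scale does not.
* The APC assumes the background factorizes per type (rank-one); motif
  families with many near-identical matrices violate this mildly, and
  such matrices are deliberately *not* merged.
* Verification in this package runs at desk scale — hundreds of
  sequences, tens of motif types, 20-seed replication for the
  stochastic properties (oracle sweeps use 200 random instances with up
  to 5 sequences, 6 types and 30 pair instances) — chosen to make every
  property checkable in minutes while leaving the asymptotic regime of
  genome-wide scans unexplored.
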