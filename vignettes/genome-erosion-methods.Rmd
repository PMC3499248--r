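---
title: "Methods: classifying pseudogenes and estimating cryptic gene decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying pseudogenes and estimating cryptic gene decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erosim)
```

## The model

`erosim` studies the earliest phase of genome reduction in host-restricted
bacteria.  Its central assumption is the standard one for young symbioses:
at the onset of obligate host association, purifying selection is lifted
*synchronously* from a subset of the gene inventory (the **neutral class**),
and disrupting mutations then accumulate in those genes at a rate
proportional to gene length, while the remaining genes stay constrained.
Under that model, after `M` mutational events a neutral gene of length
`L_i` has been visibly disrupted with probability

```
p_i = 1 - (1 - L_i / sum(L))^M
```

Three observable consequences drive the whole analysis:

1. the visible pseudogene count is `sum(p_i) < n_neutral`, so some neutral
   genes are still "intact" (cryptic pseudogenes);
2. disruption is length-biased, so the mean *ancestral* length of disrupted
   genes exceeds that of intact genes by a size difference `delta` that
   shrinks as the process saturates;
3. per-pseudogene mutation counts are Poisson-like per site but
   heterogeneous across genes (and large deletions erase events), so the
   observed counts are overdispersed relative to a single Poisson.

The cryptic-pseudogene estimator inverts (1) and (2): it simulates the
process for an increasing candidate `n_neutral` and accepts the smallest
class size whose simulated trajectory can simultaneously match the observed
pseudogene count and the observed `delta`.

## Classification rules

A derived locus is compared with its ancestral ORF by local
(Smith–Waterman) alignment with affine gap costs (match +1, mismatch −2,
gap open −5, gap extend −1; a gap of length *k* costs `5 + k`).  A single
local alignment silently clips anything it cannot afford to cross, so the
aligner chains segments: after the primary alignment, the unaligned flanks
of both sequences are re-aligned recursively.  A large insertion (an IS
element) then shows up *between* two collinear segments instead of
truncating the alignment, and reference coverage is computed over the union
of segment spans.

* **intact** — coverage > 0.99 (> 0.90 for ORFs under 300 nt), no
  frameshifting indel, no premature stop in the ancestral reading frame, no
  IS insertion;
* **absent** — no locus found, or coverage below `absent_threshold`
  (default 0.20), interpreted as loss by large deletion;
* **pseudogene** — everything else.

Nonsense changes are point substitutions creating an in-frame stop,
assessed *independently of frameshifts*: each ancestral codon whose three
positions align gap-free is translated from the aligned derived bases, so an
upstream indel does not block detection once the alignment re-synchronises.
Deletions touching the first/last ancestral codon, or abutting an unaligned
terminus, are terminal (5′/3′) deletions; unaligned termini of at least 6
bases are themselves reported as terminal deletions (shorter overhangs are
alignment clipping noise).  Insertions are matched against an IS catalog
(≥80% identity over ≥80% of the element length) and otherwise counted as
internal insertions.

Design choices made where the rules were genuinely open:

* Coverage is credited across chained collinear segments.  With
  single-segment coverage, a gene split in half by an IS element would be
  indistinguishable from a half-deleted gene; chaining keeps "interrupted"
  and "truncated" apart, and IS insertions are treated as disrupting in
  their own right (their lengths are often multiples of three, so the
  frameshift test alone would miss them).
* Ortholog pairing is by shared gene identifier.  The simulator guarantees
  identifier correspondence, which makes the pairing exact; alignment-driven
  best-hit pairing would add a failure mode the synthetic study cannot
  exercise.
* The absent threshold (0.20) separates vestigial fragments from absence.
  Any value below the smallest truncation remnant the generator can produce
  (25% of the gene, see below) gives identical results.

## The erosion simulator

`generate_ancestral()` builds a single-contig genome of codon-structured
ORFs: ATG start, stop-free body, terminal stop, lengths drawn from a gamma
distribution (default shape 2, mean 950 bases, floored at 90 and rounded to
codons — the right-skewed shape typical of bacterial gene inventories),
random strand, intergenic spacers (Poisson, mean 130 bases).  Per-position
G/C probabilities (defaults: 0.55 / 0.40 / 0.55 for codon positions 1–3,
0.50 intergenic) set the composition targets that the composition module
recovers.

`erode()` applies, in order:

1. **Whole-gene deletion** of `deletion_fraction` (default 10%) of the
   neutral class, drawn uniformly — size-unbiased, matching the observation
   that large deletions are not length-selective.
2. **Sequential disrupting events** (`mutation_budget`, default twice the
   neutral-class size): each event picks a surviving neutral gene with
   probability proportional to its current length and a category from
   `category_mix`.  The default mix (19/34/7/11/19/10% across internal
   insertions, internal deletions, 5′ deletions, 3′ deletions, nonsense,
   IS elements) is the allelic spectrum observed in the weevil symbiont.
   Realizations: indels of 1–10 bases with length not a multiple of three
   (frameshifting by construction, placed with ≥30-base flanks so the
   aligner can anchor both sides); nonsense events substitute one base of an
   interior codon to create a stop; terminal deletions remove a uniform
   10–50% of the ancestral gene end, with stacked truncations capped at 75%
   of the gene so a truncated gene never masquerades as an absent one;
   IS insertions splice a catalog element into the central 20–80% of the
   surviving span, where the disruption is unambiguous.
3. **Background substitutions** on every surviving gene: per-site Bernoulli
   at `point_sub_rate_gc4` on fourfold-degenerate third positions (default
   0.043, the silent-site divergence scale of a young symbiosis) and
   `point_sub_rate_gc2` elsewhere (default 0.008), plus `relaxed_gc2_extra`
   (default 0.008) at second positions of neutral genes — the minimal
   two-rate model that reproduces both `dGC4 > dGC2` and
   `dGC2_psi > dGC2`.  Substitutions at degenerate and intergenic sites move
   toward A/T with probability `at_bias` (default 0.85), emulating the
   AT-drift of endosymbiont genomes.  Substitutions that would create an
   in-frame stop are suppressed: in constrained genes that is purifying
   selection, and in neutral genes it keeps the logged event list the only
   source of frame disruptions, so the truth table stays exact.

What the generator deliberately does **not** emulate: rearrangements and
inversions (G+C-skew perturbations), IS proliferation dynamics,
selection intensities between "fully neutral" and "fully constrained",
paralogy, and real phylogenetic covariance between genes.  Passing the
closed-loop tests therefore demonstrates that the pipeline's rules are
internally consistent and invertible under the stated model — not that the
model captures every feature of real symbiont genomes.

## The Monte Carlo estimator

`mc_run()` tracks, at every `record_interval` cycles, the disrupted-gene
count, the size difference (disrupted mean minus intact mean, the intact
side pooling constrained genes and not-yet-hit neutral genes), and the
cumulative mutation density per kb of total neutral-class length (repeated
hits still count: erased and stacked mutations are exactly what the
correction is for).  One cycle places one mutation; the implementation draws
all cycle outcomes in a single vectorized pass, which is distributionally
identical to the literal loop and is cross-checked against the closed forms
`sum(p_i)` and the `p_i`-weighted class means in the test suite.

`estimate_neutral_count()` scans a grid of class sizes (default: steps of 10
genes from the observed pseudogene count to twice that count), averages
`replicates` (default 25) trajectories per grid point, finds the first
recorded cycle at which the mean count reaches the observed count, and
accepts the smallest class size whose mean size difference at that cycle is
within `match_tolerance_delta` (default ±10 bases) of the observed value.
The replicate mean, not a single run, is matched — the mean is the quantity
the closed form predicts, and matching a single run would make the answer an
accident of one trajectory.  Because the size difference grows monotonically
with the class size at a fixed matched count, the smallest-match rule is a
well-defined root-finder; the whole grid is scanned rather than stopping at
the first overshoot so that replicate noise cannot end the search early.
Deleted ("absent") genes are excluded from the estimator's length pool: the
estimator addresses genes under relaxed selection *among retained
orthologs*, which is also why parameter-recovery experiments run the
generator without whole-gene deletion when the recovery target is the full
neutral-class size.

The estimator's reported spread is the replicate standard deviation of the
matched size difference at the accepted grid point; re-estimating a
per-replicate class size would require one full grid search per replicate
for little diagnostic gain.

## Composition metrics

Site classes are assigned from the *ancestral* codon only: second positions
(GC2), third positions of the eight fourfold families CTN, GTN, TCN, CCN,
ACN, GCN, CGN, GGN (GC4; stop codons and two-fold families never
contribute), and intergenic positions (GCI).  Divergence is an uncorrected
p-distance over class sites projected through gap-free alignment columns —
the quantity the per-site simulation rates directly parameterize — with a
Jukes–Cantor correction available behind a flag.  At the default rates the
distinction is negligible (JC inflates 0.05 by ~3.5%).

The divergence-time conversion `t = d4 / (2 mu_s g)` exposes a
generations-per-year scaling `g` with default 1 and no claim of
correctness: with the published clock rate `mu_s = 2.2e-7` per site per
year and a silent-site divergence of 4.3%, unit scaling gives ≈ 97,700
years, and `g ≈ 3.5` would be needed to reach a ~28,000-year estimate; the
package computes, and the caller chooses the biology.

## Numerical and scale choices

Tests and the acceptance script exercise the full study conditions — a
4,000-gene ancestor with a 1,500-gene neutral class and a 3,000-event
budget — for the closed-loop classification, spectrum-recovery and
parameter-recovery experiments, and smaller genomes (200–1,000 genes) where
many replicates are needed (size-difference direction: 100 replicates at
400 genes; divergence recovery: 3 replicates at 500 genes, where the
~8 × 10^4 pooled fourfold sites still give a 99% binomial CI of ±0.002 on a
0.05 rate).  Parameter recovery uses one ancestral inventory — as a real
study would — with twenty independent erosion and estimation seeds.
Estimator runs cap trajectories at 30,000–60,000 cycles with 100-cycle
recording; the matched cycles in practice fall an order of magnitude below
the cap, and a candidate class size whose trajectory cannot reach the
observed count within the cap is treated as a non-match.  All simulation
entry points take an explicit seed
and are byte-reproducible; catalog IS sequences are fixed independently of
the seed so that changing the simulation seed never changes the reference
elements.

## Known limitations

* Event extraction undercounts when events stack on one gene (two 5′
  truncations collapse into one larger one; a later deletion can swallow an
  earlier nonsense codon).  At the default density (~2 events per disrupted
  gene) the spectrum bias is under one percentage point per category, well
  inside sampling noise at 2,000+ events.
* With background substitution enabled, a substitution in the last one or
  two bases of a gene can be clipped by the local aligner; for genes of
  exactly 300 bases this can shave coverage to the intact threshold.  The
  effect is a per-run handful of borderline genes and only arises when
  composition noise is on.
* The estimator's match tolerance is expressed in bases of size difference;
  at small genome scales (a few hundred genes) replicate noise approaches
  the default ±10, and a wider tolerance (with correspondingly coarser
  resolution) is appropriate — the package exposes it.
* Absolute mutation densities from the estimator depend on the tail of the
  ancestral length distribution, not only on the matched count and size
  difference; with a stand-in length list they should be read as
  order-of-magnitude.
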