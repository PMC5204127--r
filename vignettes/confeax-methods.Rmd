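---
title: "Methods: conserved-feature discovery and coevolution profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved-feature discovery and coevolution profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Divergent protein families — the MadBub spindle-assembly-checkpoint family
is the motivating case — carry their function in short linear motifs
(KEN-boxes, D-boxes, ABBA motifs, ...) and small domains scattered over
long, poorly alignable sequences. Full-length multiple alignment fails for
such families, so conserved features have to be found de novo, region by
region. When the family has also undergone repeated independent gene
duplications, the *pattern* of feature retention across the duplicate
copies is itself informative: features that subfunctionalized together are
co-retained in one paralogue class and co-lost in the other, so their
binary presence/absence profiles across gene copies correlate positively
with each other and negatively with the opposite set.

`confeax` implements this whole chain: EM-based motif discovery, iterative
profile-HMM refinement of each feature, and Pearson-distance clustering of
the feature retention profiles.

# Stage 1: EM motif discovery

## Site model

Each candidate width-$w$ window of every sequence is treated as a potential
motif site with a shared Bernoulli prior $\pi$ (initialised at one over the
mean sequence length, re-estimated each M-step, capped at 0.5). This
"repeats-allowed" mixture permits any number of occurrences per sequence,
including zero. The observed-data objective is the sum over windows of
$\log\{(1-\pi)\,f_{bg}(x) + \pi\,f_{pwm}(x)\}$. Because the M-step uses
pseudocounts it is a MAP update, and the quantity EM actually ascends is
the *penalized* objective — mixture log likelihood plus the Dirichlet
pseudocount prior term on the PWM; that is what `loglik` reports (minus
the additive background constant, which affects neither monotonicity nor
any ranking). The prior update $\hat\pi = \bar z$ is the exact maximizer,
deliberately unclipped, for the same reason. The alphabet is the 20 canonical amino acids
plus `X`; `X` is pinned to its background frequency in every PWM column, so
it contributes exactly zero log-odds wherever it appears (masked regions
are encoded as `X`).

## Seeding and screening

Seeding is deterministic: every distinct width-$w$ subsequence of the data
becomes a candidate start (probability 0.7 on the observed letter, the
remainder spread uniformly over the other 19 canonical letters). Candidates
are screened by the mixture log likelihood of the seed model — the E-step
objective of the first EM step — and the best 50 are refined to
convergence ($|\Delta \log L| < 10^{-6}$ or 200 iterations, pseudocount
0.01 per letter per column). Sites are the windows with posterior
$\ge 0.5$, selected greedily without overlap by descending posterior.

## Significance and width selection

The acceptance gate is an empirical shuffle test. A *fixed-effort* search
(seeds at every 5th position, best 5 refined, capped iterations) is run on
the observed data and on 20 datasets in which each sequence is shuffled
residue-wise (composition preserved); the significance is the fraction of
shuffles whose best refined motif LLR reaches the observed statistic.
Running the identical search on both sides is essential: the statistic is
then exchangeable under the null, so pure-background input yields roughly
uniform significances and the gate (strictly below 0.05; with 20 shuffles
only significance 0 passes) rejects it. Comparing the *full* discovery's
LLR against a cheaper null would be anti-conservative — the harder search
systematically overfits more — which we verified empirically before
settling on this design.

Discovery runs at every width in `width_range` (default 8–12, a typical
SLiM-to-short-domain span) and keeps the width with the best significance,
ties broken by LLR. Since no candidate can beat significance 0, nulls are
evaluated lazily in LLR order and stop at the first 0. The motif's LLR is
the counts-based log likelihood ratio of its site alignment versus
background ($n \times$ KL divergence per column, hence non-negative).

Accepted motifs are masked (`X`) before the next motif is sought, so the
training sites of successive motifs cannot overlap; up to 50 motifs are
reported.

# Stage 2: hit extension, alignment, logos

Accepted hits are extended by 5 residues on each side (clamped at the
sequence ends) to recover conserved flanks that the rigid window model
truncates. Extended instances are aligned with an internal progressive
aligner: all pairwise global alignments under BLOSUM62 with affine gaps
(open 11, extend 1; a length-$g$ gap costs $11 + (g-1)$), pairwise distance
$1 - \text{identity}$, average-linkage guide tree, then profile–profile
merges with the same scoring (column score = frequency-weighted expected
substitution score; gap–residue pairs contribute 0; ties in the DP prefer
match, then gap-in-second, deterministically). Instances are short
(≤ ~60 columns), where progressive alignment is adequate; the
consistency-based objective of heavier aligners is deliberately not
reproduced.

Column occupancy filtering (used in alignment post-processing) keeps a
column iff its non-gap fraction is **at least** the threshold — 4 residues
over 5 rows pass at 0.8. Logo matrices report per-column frequencies over
non-gap residues and information content $IC = \log_2 20 - H$ in bits,
clamped to $[0, \log_2 20]$; no small-sample correction is applied by
default.

# Stage 3: profile HMM, calibration, iterated search

## Model

Columns with occupancy $\ge 0.5$ become match states (this threshold is
distinct from the 0.8 occupancy rule above, which belongs to alignment
curation); the rest are insert states. Emissions and transitions
(M→M/I/D, I→M/I, D→M/D) are estimated from Henikoff position-weighted
counts with Laplace (+1) pseudocounts. The model is local in the
Smith–Waterman sense: uniform entry into and exit from any match state
(probability $1/L$ each, applied as explicit entry/exit terms), insert
states emit background (zero log-odds), `X` scores zero in match states,
and flanking residues outside the alignment are free under the log-odds
null. Constant entry/exit penalties shift all scores equally and are
absorbed by calibration.

## Calibration and search

Viterbi scores of 200 random background-composition sequences (lengths
resampled from the family) are fitted with a maximum-likelihood Gumbel
$(\mu, \lambda)$; $E(S) = n \cdot e^{-\lambda (S - \mu)}$, clipped to
$[0, n]$. Search takes the best local hit per sequence, masks it, and
repeats until the threshold fails; equal-scoring overlapping alignments
resolve to the leftmost start.

## Iteration to convergence

Each round: extend the current inclusion set's hit cores, realign, rebuild,
recalibrate, re-search. Two design choices keep this loop well behaved:

* **Inclusion vs reporting thresholds.** The search *reports* hits at a
  permissive E ≤ 10 (to capture degenerate sites), but only hits at
  E ≤ 0.1 are *included* in the next round's alignment — the standard
  split of iterated homology searches. A permissive threshold by
  construction admits ~10 expected-false hits per round; feeding them into
  the model makes it churn indefinitely. Inspection of score distributions
  on the degenerate benchmark shows a clean gap between true sites
  (E ≲ 0.06) and noise (E ≳ 0.1), so 0.1 is a natural default (all three
  thresholds are configurable).
* **A deterministic map.** Calibration reuses the same seed every round,
  so one iteration is a deterministic function of the inclusion set and an
  exact fixed point is reachable. Convergence is declared at Jaccard 1
  between consecutive inclusion sets (hits matched within a sequence when
  they overlap by ≥ 50% of the shorter interval, so one-residue boundary
  jitter does not read as change) or Jaccard ≥ 0.99 twice in a row, with
  a hard cap of 20 rounds. A deterministic map can land in a 2-cycle of
  borderline hits; when the current set matches the one from two rounds
  earlier, the flickering hits are dropped once and iteration continues.

Reported per feature: the converged permissive hit set (the iteration's own
result), the subset at the stricter acceptance E ≤ 0.01 (used downstream),
the final calibrated model, and the full per-round trace.

# Stage 4: phylogenetic profiles and coevolution

Presence is binary per feature and gene copy (≥ 1 accepted hit, regardless
of copy number). Profile rows are the duplicated copies only by default —
unduplicated proteins carry everything and would dilute the contrast
(configurable). Pearson correlation across copies gives $r$; constant
(all-0/all-1) columns have undefined $r$ and are excluded from clustering
with a warning rather than silently coerced, which would fabricate signal.
Average-linkage (UPGMA) clustering runs on $d = 1 - r$: repeatedly merge
the cluster pair with the smallest size-weighted average distance; the
merge height is that average divided by 2 (ultrametric convention,
recorded as such in the outputs); exact ties break by the
lexicographically smallest pair of cluster representatives. Heights are
monotone for average linkage, so the dendrogram has no inversions. The
headline report cuts at $k = 2$ — the expected subfunctionalized split —
and tabulates mean presence per paralogue class per cluster; the full
dendrogram (newick, branch lengths from height differences) is always
emitted.

# The synthetic generator

`simulate_family()` emulates the study conditions: a family across species,
a subset of species carrying an independent duplication (a MAD and a BUB
copy each; default 16 duplicated among 24 species, i.e. 40 proteins),
sequence lengths uniform on 300–1200, i.i.d. background residues, and ~10
short features (widths 6–17, per-column conservation 0.8–0.95) planted at
random non-overlapping positions. Each feature is drawn per column:
consensus letter with probability equal to the conservation, otherwise
background renormalized over the remaining letters. A retention map assigns
each feature to MAD, BUB or both after duplication; ABBA1/KEN2/ABBA2 share
the MAD retention class, mimicking a symmetric co-retained cassette.
`prevalence` (fraction of copies carrying a feature before retention and
noise) extends the retention scheme so benchmarks like "present in 80% of
proteins" are expressible; `flip_noise` inverts retention bits with a small
probability.

Three presets pin the benchmark conditions: `sim_config_recovery()` (40
proteins of length 300, one fully conserved 10-mer in 80% of them),
`sim_config_degenerate()` (conservation 0.7, 60% carriers — the regime
where iterated HMM search matters), and `sim_config_subfunc()` (16
duplicated pairs, MAD/BUB retention split, 5% flip noise). Length 300 was
chosen for the two motif benchmarks as the short end of the default range,
which keeps the discovery tests comfortably sized; the generator itself
defaults to the full 300–1200 span.

Deliberate simplifications, and what they imply: columns are independent
(no covariation), duplicated copies are generated independently (no shared
mutational history beyond retention, no tree-structured simulation), and
there are no indels inside features. Passing the benchmarks therefore
demonstrates correct recovery under i.i.d. noise at realistic sizes, not
robustness to phylogenetic correlation or alignment-breaking indels in real
families.

# Numerical choices

* EM: pseudocount 0.01; convergence $|\Delta \log L| < 10^{-6}$ or 200
  iterations; log-sum-exp uses an exact-to-double fast path (skipping
  `log1p` when the terms differ by > 40 nats).
* HMM: Laplace +1 pseudocounts; degenerate calibration score variance is an
  error, not a silent fallback; Gumbel ML via a bracketed root of the
  profile likelihood equation.
* Tie-breaks are deterministic everywhere (DP state preference, leftmost
  hit start, lexicographic UPGMA pairs), and every stochastic step flows
  from a single user seed, so identical seed + input gives byte-identical
  outputs.
* Degenerate inputs error early with specific messages: empty FASTA,
  illegal residues (with sequence id and 0-based offset), all columns
  removed by the occupancy filter, fewer than 2 match columns, collapsed
  hit sets during iteration, features that cannot be placed in a sequence.

# Limitations

No gapped or palindromic motif models; no nucleotide support; no
phylogeny-aware correction of the coevolution signal (features shared by
descent inflate correlations); no bootstrap support values on the feature
dendrogram; duplication events are taken from user labels, not inferred
from trees. The E-value calibration is empirical, not the analytic
calibration of dedicated HMM packages, so absolute E-values are comparable
within a run rather than across tools.
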